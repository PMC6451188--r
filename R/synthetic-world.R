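#' Configuration for the synthetic world
#'
#' Returns the configuration list consumed by [generateWorld()]. Defaults
#' define a desk-scale world (4 chromosomes x 5 Mb, 100 kb compartment bins,
#' 10 kb contact resolution) whose statistical structure mirrors the
#' analysis assumptions: DNase peaks denser in A compartments with a
#' TF-occupied subset, spontaneous DSBs co-localizing with TF-occupied DNase
#' sites, meiotic DSBs weakly biased toward B1, Alu-like homologous repeat
#' pairs enriched in A compartments, per-mechanism SV sets with planted
#' compartment biases, NAHR deletions between repeat-pair members with a
#' planted minority fraction at meiotic DSBs, contact matrices with
#' power-law distance decay plus compartment and NAHR-pair boosts, and
#' compartment-dependent replication-timing / periodic nucleosome tracks.
#'
#' @param nChrom,chromLength genome shape.
#' @param binSize compartment bin size (bp).
#' @param compartmentProps label proportions (must sum to 1).
#' @param dnaseDensity DNase peaks per Mb per compartment.
#' @param dnaseLength,tfbsFraction,tfbsLength DNase/TFBS geometry.
#' @param spontCount,spontColocRate,spontLength spontaneous DSB peaks and
#'   their co-localization rate with TF-occupied DNase sites.
#' @param meioticCount,meioticB1Bias,meioticLength meiotic DSB peaks and
#'   their B1 density bias factor.
#' @param repeatPairCount,repeatCompartmentWeights homologous repeat pairs:
#'   count and per-compartment placement weights.
#' @param repeatLength,repeatIdentity,pairSeparation repeat geometry:
#'   length (bp), pair identity, separation range (bp).
#' @param svCounts named per-mechanism SV counts.
#' @param svEnrichment named list of per-compartment density factors
#'   (NULL = uniform); NAHR placement is via repeat pairs instead.
#' @param svLengthRange named list of length ranges (bp); `default` used
#'   when a mechanism has no entry.
#' @param xTrue planted fraction of NAHR deletions of meiotic origin.
#' @param spontAtNahrRate probability that a non-meiotic NAHR breakpoint
#'   gets a spontaneous DSB peak planted on it.
#' @param tadSpacing,loopCount TAD boundary spacing and loop anchor count.
#' @param contactResolution,decayAlpha,contactDepth contact-matrix model:
#'   bin size (bp), distance-decay exponent, count scale.
#' @param compartmentBoost,nahrBoost,unmappableRate,contactNoise
#'   contact-matrix structure: same-compartment and NAHR-pair boosts,
#'   masked-bin rate, Poisson noise toggle.
#' @param rtMeans,rtSd per-compartment replication-timing means and noise sd.
#' @param trackStep,nucleosomePeriod track step (bp) and nucleosome period (bp).
#' @param withContacts,withTracks stage toggles (skip expensive parts).
#' @param seed integer seed; the world is deterministic given the seed.
#' @return named list of class `svcWorldConfig`.
#' @export
worldConfig <- function(
    nChrom = 4L, chromLength = 5e6, binSize = 1e5,
    compartmentProps = c(A1 = 0.15, A2 = 0.25, B1 = 0.20, B2 = 0.20, B3 = 0.20),
    dnaseDensity = c(A1 = 80, A2 = 60, B1 = 20, B2 = 15, B3 = 10),
    dnaseLength = 300, tfbsFraction = 0.4, tfbsLength = 20,
    spontCount = 1200, spontColocRate = 0.7, spontLength = 400,
    meioticCount = 400, meioticB1Bias = 2, meioticLength = 1400,
    repeatPairCount = 400,
    repeatCompartmentWeights = c(A1 = 3, A2 = 2, B1 = 1, B2 = 1, B3 = 1),
    repeatLength = 300, repeatIdentity = 0.95,
    pairSeparation = c(2e4, 5e5),
    svCounts = c(NAHR = 150, NHEJ = 300, NHrepl = 300, `MEI-Alu` = 200,
                 `MEI-L1` = 100, TDUP = 150, VNTR = 150, `MTE-del` = 80,
                 `AluL1-del` = 150),
    svEnrichment = list(
      NHEJ = c(A1 = 0.5, A2 = 0.8, B1 = 1.5, B2 = 1.5, B3 = 1.5),
      NHrepl = c(A1 = 0.5, A2 = 0.8, B1 = 1.5, B2 = 1.5, B3 = 1.5),
      `MEI-Alu` = c(B1 = 1.5, B2 = 1.5, B3 = 1.5),
      `MEI-L1` = c(B2 = 2, B3 = 2),
      VNTR = c(B2 = 1.5, B3 = 1.5),
      `MTE-del` = c(A1 = 2, A2 = 1.5)),
    svLengthRange = list(default = c(500, 5000), TDUP = c(1e3, 5e4),
                         `MEI-Alu` = c(280, 340), `MEI-L1` = c(5e3, 6e3),
                         `AluL1-del` = c(250, 450), VNTR = c(100, 2000),
                         `MTE-del` = c(1e3, 2e4)),
    xTrue = 0.10, spontAtNahrRate = 0.8,
    tadSpacing = 4e5, loopCount = 60,
    contactResolution = 1e4, decayAlpha = 1, contactDepth = 5000,
    compartmentBoost = 1.5, nahrBoost = 2, unmappableRate = 0.02,
    contactNoise = TRUE,
    rtMeans = c(A1 = 1.5, A2 = 1.0, B1 = 0.0, B2 = -0.8, B3 = -1.2),
    rtSd = 0.3, trackStep = 10L, nucleosomePeriod = 150,
    withContacts = TRUE, withTracks = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$compartmentProps) - 1) > 1e-8)
    stop("compartment proportions must sum to 1")
  if (cfg$xTrue < 0 || cfg$xTrue > 1) stop("xTrue must be in [0, 1]")
  if (any(cfg$dnaseDensity < 0) || cfg$spontCount < 0 || cfg$meioticCount < 0)
    stop("densities and counts must be >= 0")
  class(cfg) <- "svcWorldConfig"
  cfg
}

# Sample n positions with per-bin weight = bin length * factor(label);
# factors is a named vector (missing labels get 1) or NULL for uniform.
.samplePositions <- function(n, compartments, factors = NULL) {
  if (n == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  w <- as.numeric(width(compartments))
  if (!is.null(factors)) {
    f <- factors[as.character(mcols(compartments)$label)]
    f[is.na(f)] <- 1
    w <- w * f
  }
  idx <- sample.int(length(compartments), n, replace = TRUE, prob = w)
  data.frame(chrom = as.character(seqnames(compartments))[idx],
             pos = start(compartments)[idx] +
               floor(runif(n) * width(compartments)[idx]),
             stringsAsFactors = FALSE)
}

.peaksAt <- function(centers, len, layout) {
  if (nrow(centers) == 0L)
    return(GRanges())
  s <- pmax(1, centers$pos - len %/% 2)
  e <- pmin(chromLengths(layout)[centers$chrom], s + len - 1)
  GRanges(centers$chrom, IRanges(s, pmax(e, s)))
}

.randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutateDNA <- function(seqStr, nMut) {
  if (nMut == 0L) return(seqStr)
  x <- strsplit(seqStr, "")[[1]]
  pos <- sample.int(length(x), min(nMut, length(x)))
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1L)
  paste(x, collapse = "")
}

#' Generate a synthetic world
#'
#' Builds the full synthetic dataset described by [worldConfig()]:
#' deterministic given the configuration seed, with a truth record of all
#' planted parameters alongside the data. The truth record is for
#' evaluation only and is never consumed by analysis functions.
#'
#' @param config a [worldConfig()] list.
#' @return [SyntheticWorld-class].
#' @export
generateWorld <- function(config = worldConfig()) {
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$nChrom))
  layout <- GenomeLayout(setNames(rep(config$chromLength, config$nChrom), chroms))
  binSize <- config$binSize
  nbPer <- ceiling(config$chromLength / binSize)
  s <- rep(seq(1, by = binSize, length.out = nbPer), config$nChrom)
  comp <- GRanges(rep(chroms, each = nbPer),
                  IRanges(s, pmin(s + binSize - 1, config$chromLength)))
  mcols(comp)$label <- sample(names(config$compartmentProps), length(comp),
                              replace = TRUE, prob = config$compartmentProps)

  # DNase peaks: Poisson count per bin at the compartment's density
  lam <- config$dnaseDensity[as.character(mcols(comp)$label)] *
    as.numeric(width(comp)) / 1e6
  nPerBin <- rpois(length(comp), lam)
  binIdx <- rep(seq_along(comp), nPerBin)
  dnaseCenters <- data.frame(
    chrom = as.character(seqnames(comp))[binIdx],
    pos = start(comp)[binIdx] + floor(runif(sum(nPerBin)) * width(comp)[binIdx]),
    stringsAsFactors = FALSE)
  dnase <- .peaksAt(dnaseCenters, config$dnaseLength, layout)

  # TF-occupied subset of DNase sites
  nTF <- round(config$tfbsFraction * length(dnase))
  tfIdx <- if (nTF > 0) sample.int(length(dnase), nTF) else integer()
  tfbs <- .peaksAt(data.frame(chrom = as.character(seqnames(dnase))[tfIdx],
                              pos = (start(dnase)[tfIdx] + end(dnase)[tfIdx]) %/% 2),
                   config$tfbsLength, layout)

  # Spontaneous DSBs: a fraction at TF-occupied DNase sites, rest uniform
  nColoc <- if (length(tfbs)) round(config$spontColocRate * config$spontCount) else 0L
  pick <- if (nColoc > 0) sample.int(length(tfbs), nColoc, replace = TRUE) else integer()
  colocCenters <- data.frame(
    chrom = as.character(seqnames(tfbs))[pick],
    pos = (start(tfbs)[pick] + end(tfbs)[pick]) %/% 2 +
      round(runif(nColoc, -100, 100)),
    stringsAsFactors = FALSE)
  unifCenters <- .samplePositions(config$spontCount - nColoc, comp)
  spont <- .peaksAt(rbind(colocCenters, unifCenters), config$spontLength, layout)

  # Meiotic DSBs with a (weak) B1 bias
  meiotic <- .peaksAt(
    .samplePositions(config$meioticCount, comp,
                     factors = c(B1 = config$meioticB1Bias)),
    config$meioticLength, layout)

  # Homologous repeat pairs (Alu-like), enriched in A compartments
  pairs <- .plantRepeatPairs(config, comp, layout)

  # SV sets
  svParts <- list()
  truthNahr <- NULL
  mechs <- names(config$svCounts)[config$svCounts > 0]
  for (m in setdiff(mechs, "NAHR")) {
    nm <- config$svCounts[[m]]
    fac <- config$svEnrichment[[m]]
    rng <- config$svLengthRange[[m]]
    if (is.null(rng)) rng <- config$svLengthRange$default
    centers <- .samplePositions(nm, comp, factors = fac)
    len <- round(runif(nm, rng[1], rng[2]))
    maxLen <- chromLengths(layout)[centers$chrom]
    s <- pmin(centers$pos, maxLen - len)
    s <- pmax(s, 1)
    gr <- GRanges(centers$chrom, IRanges(s, s + len))
    mh <- mi <- rep(NA_integer_, nm)
    if (m == "NHEJ") { mh <- rep(0L, nm); mi <- rep(0L, nm) }
    if (m == "NHrepl") {
      viaMH <- runif(nm) < 0.5
      mh <- ifelse(viaMH, sample(3:15, nm, replace = TRUE), 0L)
      mi <- ifelse(viaMH, 0L, sample(11:30, nm, replace = TRUE))
    }
    svParts[[m]] <- makeSVSet(gr, m,
                              allele_frequency = round(runif(nm), 4),
                              micro_homology_bp = mh, micro_insertion_bp = mi)
  }
  if ("NAHR" %in% mechs) {
    nNahr <- config$svCounts[["NAHR"]]
    if (nNahr > nrow(pairs))
      stop("more requested NAHR deletions (", nNahr,
           ") than available repeat pairs (", nrow(pairs), ")")
    usedIdx <- sample.int(nrow(pairs), nNahr)
    up <- pairs[usedIdx, , drop = FALSE]
    s <- pmin(up$origin_start, up$target_start)
    e <- pmax(up$origin_start, up$target_start)
    gr <- GRanges(up$chrom, IRanges(s, e))
    meioticFlag <- runif(nNahr) < config$xTrue
    # plant meiotic peaks on both breakpoints of meiotic-origin deletions
    if (any(meioticFlag)) {
      bpC <- data.frame(chrom = rep(up$chrom[meioticFlag], 2L),
                        pos = c(s[meioticFlag], e[meioticFlag]))
      meiotic <- suppressWarnings(
        c(meiotic, .peaksAt(bpC, config$meioticLength, layout)))
    }
    # plant spontaneous peaks on breakpoints of HDR-origin deletions
    hdr <- which(!meioticFlag & runif(nNahr) < config$spontAtNahrRate)
    if (length(hdr)) {
      bpC <- data.frame(chrom = rep(up$chrom[hdr], 2L),
                        pos = c(s[hdr], e[hdr]))
      spont <- suppressWarnings(
        c(spont, .peaksAt(bpC, config$spontLength, layout)))
    }
    svParts[["NAHR"]] <- makeSVSet(gr, "NAHR",
                                   allele_frequency = round(runif(nNahr), 4))
    truthNahr <- list(usedPairIdx = usedIdx, meioticFlag = meioticFlag)
  }
  svs <- if (length(svParts))
    suppressWarnings(do.call(c, unname(svParts))) else
    makeSVSet(GRanges(), character())

  # TAD boundaries and loop anchors
  tads <- do.call(rbind, lapply(chroms, function(ch) {
    if (config$chromLength < 2 * config$tadSpacing)
      return(data.frame(chrom = character(), pos = numeric()))
    p <- seq(config$tadSpacing, config$chromLength - config$tadSpacing,
             by = config$tadSpacing)
    data.frame(chrom = ch,
               pos = pmax(1, pmin(config$chromLength,
                                  p + round(runif(length(p), -2e4, 2e4)))),
               stringsAsFactors = FALSE)
  }))
  la1 <- .samplePositions(config$loopCount, comp)
  la2pos <- pmin(chromLengths(layout)[la1$chrom],
                 la1$pos + round(runif(config$loopCount, 5e4, 3e5)))
  loops <- data.frame(chrom = rep(la1$chrom, 2L), pos = c(la1$pos, la2pos),
                      loop = rep(seq_len(config$loopCount), 2L),
                      stringsAsFactors = FALSE)

  # Signal tracks
  rt <- nuc <- NULL
  if (config$withTracks) {
    step <- config$trackStep
    labByChrom <- split(as.character(mcols(comp)$label),
                        as.character(seqnames(comp)))
    rtVals <- nucVals <- list()
    meiSites <- svs[mcols(svs)$mechanism %in% c("MEI-Alu", "MEI-L1")]
    for (ch in chroms) {
      nc <- ceiling(config$chromLength / step)
      mids <- (seq_len(nc) - 0.5) * step
      lab <- labByChrom[[ch]][pmin(ceiling(mids / binSize),
                                   length(labByChrom[[ch]]))]
      rtVals[[ch]] <- config$rtMeans[lab] + rnorm(nc, 0, config$rtSd)
      phase <- runif(1, 0, config$nucleosomePeriod)
      v <- 1 + 0.4 * sin(2 * pi * (mids + phase) / config$nucleosomePeriod)
      sites <- start(meiSites)[as.character(seqnames(meiSites)) == ch]
      for (sp in sites) {
        cells <- which(abs(mids - sp) <= 150)
        v[cells] <- v[cells] * 0.4
      }
      nucVals[[ch]] <- unname(v)
      rtVals[[ch]] <- unname(rtVals[[ch]])
    }
    rt <- SignalTrack(rtVals, step)
    nuc <- SignalTrack(nucVals, step)
  }

  # Contact matrices
  contacts <- list()
  if (config$withContacts) {
    nahrSvs <- svs[mcols(svs)$mechanism == "NAHR"]
    for (ch in chroms)
      contacts[[ch]] <- .makeContactMatrix(ch, config, comp, nahrSvs, layout)
  }

  truth <- list(xTrue = config$xTrue, nahr = truthNahr,
                svEnrichment = config$svEnrichment,
                nahrBoost = config$nahrBoost,
                compartmentBoost = config$compartmentBoost,
                seed = config$seed)

  new("SyntheticWorld", layout = layout, compartments = comp,
      peaks = list(dnase = dnase, tfbs = tfbs, spontDSB = spont,
                   meioticDSB = meiotic),
      repeatPairs = pairs, repeatSeqs = pairs$origin_seq,
      svs = svs, tadBoundaries = tads, loopAnchors = loops,
      rtTrack = rt, nucTrack = nuc, contacts = contacts,
      truth = truth, config = unclass(config))
}

.plantRepeatPairs <- function(config, comp, layout) {
  n <- config$repeatPairCount
  if (n == 0L) {
    out <- .emptyPairs(); out$origin_seq <- character(); out$target_seq <- character()
    return(out)
  }
  L <- config$repeatLength
  origins <- .samplePositions(n, comp, factors = config$repeatCompartmentWeights)
  maxPos <- chromLengths(layout)[origins$chrom] - L
  origins$pos <- pmax(1, pmin(origins$pos, maxPos))
  sep <- round(runif(n, config$pairSeparation[1], config$pairSeparation[2]))
  sign <- sample(c(-1, 1), n, replace = TRUE)
  tpos <- origins$pos + sign * sep
  flip <- tpos < 1 | tpos > maxPos
  tpos[flip] <- origins$pos[flip] - sign[flip] * sep[flip]
  tpos <- pmax(1, pmin(tpos, maxPos))
  originSeq <- vapply(seq_len(n), function(i) .randomDNA(L), character(1))
  nMut <- round((1 - config$repeatIdentity) * L)
  targetSeq <- vapply(originSeq, .mutateDNA, character(1), nMut = nMut,
                      USE.NAMES = FALSE)
  data.frame(chrom = origins$chrom,
             origin_start = origins$pos, origin_end = origins$pos + L - 1L,
             target_start = tpos, target_end = tpos + L - 1L,
             orientation = "same", alignment_length = L,
             identity = config$repeatIdentity,
             separation = abs(tpos - origins$pos),
             origin_seq = originSeq, target_seq = targetSeq,
             stringsAsFactors = FALSE)
}

.makeContactMatrix <- function(chrom, config, comp, nahrSvs, layout) {
  res <- config$contactResolution
  len <- chromLengths(layout)[[chrom]]
  nb <- as.integer(ceiling(len / res))
  i <- seq_len(nb)
  E <- config$contactDepth / (abs(outer(i, i, "-")) + 1)^config$decayAlpha
  lab <- .binLabels(nb, chrom, res, comp[seqnames(comp) == chrom])
  same <- outer(lab, lab, "==") & lab != "unassigned"
  E[same] <- E[same] * config$compartmentBoost
  onCh <- as.character(seqnames(nahrSvs)) == chrom
  if (any(onCh)) {
    bi <- (start(nahrSvs)[onCh] - 1) %/% res + 1
    bj <- (end(nahrSvs)[onCh] - 1) %/% res + 1
    ok <- bi != bj & bj <= nb
    E[cbind(bi[ok], bj[ok])] <- E[cbind(bi[ok], bj[ok])] * config$nahrBoost
    E[cbind(bj[ok], bi[ok])] <- E[cbind(bj[ok], bi[ok])] * config$nahrBoost
  }
  if (config$contactNoise) {
    up <- upper.tri(E, diag = TRUE)
    M <- matrix(0, nb, nb)
    M[up] <- rpois(sum(up), E[up])
    M <- M + t(M) - diag(diag(M))
  } else {
    M <- E
  }
  nMask <- round(config$unmappableRate * nb)
  maskIdx <- if (nMask > 0) sample.int(nb, nMask) else integer()
  M[maskIdx, ] <- 0
  M[, maskIdx] <- 0
  ContactMatrix(M, chrom, res)
}

#' Regenerate the contact matrix for one chromosome
#'
#' Rebuilds a chromosome's contact matrix from the world's planted
#' structure under a fresh seed (the world's own matrices are generated at
#' construction time).
#' @param world [SyntheticWorld-class].
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return [ContactMatrix-class].
#' @export
generateContactMatrix <- function(world, chrom, seed = 1L) {
  set.seed(seed)
  cfg <- world@config
  nahrSvs <- world@svs[mcols(world@svs)$mechanism == "NAHR"]
  .makeContactMatrix(chrom, cfg, world@compartments, nahrSvs, world@layout)
}

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld:", length(chromNames(object@layout)), "chromosomes,",
      format(totalLength(object@layout), big.mark = ","), "bp\n")
  cat("  compartment bins:", length(object@compartments), "\n")
  cat("  peaks:", paste(names(object@peaks), lengths(object@peaks),
                        collapse = ", "), "\n")
  cat("  repeat pairs:", nrow(object@repeatPairs), "| SVs:",
      length(object@svs), "\n")
  cat("  contacts:", length(object@contacts), "chromosome(s); tracks:",
      if (is.null(object@rtTrack)) "none" else "RT + nucleosome", "\n")
})

#' Full genome sequence of a synthetic world
#'
#' Materializes the genome: random background sequence (deterministic in
#' the world seed) with the repeat-pair sequences planted at their
#' coordinates. The RNG state of the session is left untouched.
#' @param world [SyntheticWorld-class].
#' @return `DNAStringSet`, one sequence per chromosome.
#' @export
worldGenome <- function(world) {
  hasSeed <- exists(".Random.seed", envir = globalenv())
  if (hasSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit(if (hasSeed) assign(".Random.seed", oldSeed, envir = globalenv()))
  cfg <- world@config
  chroms <- chromNames(world@layout)
  lens <- chromLengths(world@layout)
  pairs <- world@repeatPairs
  seqs <- lapply(seq_along(chroms), function(ci) {
    set.seed((cfg$seed + 104729 * ci) %% .Machine$integer.max)
    x <- sample(c("A", "C", "G", "T"), lens[[ci]], replace = TRUE)
    onCh <- which(pairs$chrom == chroms[ci])
    for (k in onCh) {
      x[pairs$origin_start[k]:pairs$origin_end[k]] <-
        strsplit(pairs$origin_seq[k], "")[[1]]
      x[pairs$target_start[k]:pairs$target_end[k]] <-
        strsplit(pairs$target_seq[k], "")[[1]]
    }
    paste(x, collapse = "")
  })
  out <- DNAStringSet(unlist(seqs))
  names(out) <- chroms
  out
}

#' Write a synthetic world to disk
#'
#' Emits the world as pipeline-readable plain-text files: `chrom.sizes`,
#' BED files for compartments (label in the name column), peak sets, TAD
#' boundaries and loop anchors, the tab-separated SV table, a tab-separated
#' repeat-pair table, bedGraph signal tracks, sparse-triple contact
#' matrices, and the truth record as key-value text (analysis stages never
#' read the truth file).
#' @param world [SyntheticWorld-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  writeChromSizes(world@layout, fp("chrom.sizes"))
  comp <- world@compartments
  mcols(comp)$name <- mcols(comp)$label
  mcols(comp)$label <- NULL
  writeBed(comp, fp("compartments.bed"))
  for (nm in names(world@peaks)) {
    if (!length(world@peaks[[nm]])) {
      message("empty peak set omitted: ", nm)
      next
    }
    writeBed(world@peaks[[nm]], fp(paste0(nm, ".bed")))
  }
  writeSVTable(world@svs, fp("svs.tsv"))
  rp <- world@repeatPairs
  rp$origin_seq <- rp$target_seq <- NULL
  write.table(rp, fp("repeat_pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(world@tadBoundaries))
    writeBed(GRanges(world@tadBoundaries$chrom,
                     IRanges(world@tadBoundaries$pos, world@tadBoundaries$pos)),
             fp("tad_boundaries.bed"))
  if (nrow(world@loopAnchors))
    writeBed(GRanges(world@loopAnchors$chrom,
                     IRanges(world@loopAnchors$pos, world@loopAnchors$pos)),
             fp("loop_anchors.bed"))
  if (!is.null(world@rtTrack))
    writeBedGraphTrack(world@rtTrack, fp("replication_timing.bedgraph"))
  if (!is.null(world@nucTrack))
    writeBedGraphTrack(world@nucTrack, fp("nucleosome.bedgraph"))
  if (length(world@contacts)) {
    dir.create(fp("contacts"), showWarnings = FALSE)
    for (ch in names(world@contacts))
      writeContactMatrixFile(world@contacts[[ch]],
                             fp("contacts", paste0(ch, ".tsv")))
  }
  tr <- world@truth
  lines <- c(paste0("xTrue=", tr$xTrue),
             paste0("seed=", tr$seed),
             paste0("nahrBoost=", tr$nahrBoost),
             paste0("compartmentBoost=", tr$compartmentBoost))
  if (!is.null(tr$nahr)) {
    lines <- c(lines,
               paste0("nahrUsedPairIdx=", paste(tr$nahr$usedPairIdx, collapse = ",")),
               paste0("nahrMeioticFlag=",
                      paste(as.integer(tr$nahr$meioticFlag), collapse = ",")))
  }
  writeLines(lines, fp("truth.txt"))
  invisible(dir)
}

#' Read synthetic-world (or user) inputs from a directory
#'
#' Reads the files emitted by [writeWorld()] back into analysis-ready
#' objects. The truth record is deliberately not read.
#' @param dir directory written by [writeWorld()].
#' @param step track step in bp (must match the written tracks).
#' @return list with `layout`, `compartments`, `peaks`, `svs`,
#'   `tadBoundaries`, `loopAnchors`, `rtTrack`, `nucTrack`, `contacts`.
#' @export
readWorldInputs <- function(dir, step = 10L) {
  fp <- function(...) file.path(dir, ...)
  layout <- readChromSizes(fp("chrom.sizes"))
  comp <- readBed(fp("compartments.bed"), layout)
  mcols(comp)$label <- mcols(comp)$name
  mcols(comp)$name <- NULL
  mcols(comp)$score <- NULL
  peaks <- list()
  for (nm in c("dnase", "tfbs", "spontDSB", "meioticDSB")) {
    f <- fp(paste0(nm, ".bed"))
    if (file.exists(f)) peaks[[nm]] <- readBed(f, layout)
  }
  readPoints <- function(f) {
    if (!file.exists(f)) return(data.frame(chrom = character(), pos = integer()))
    gr <- readBed(f, layout)
    data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
               stringsAsFactors = FALSE)
  }
  rt <- if (file.exists(fp("replication_timing.bedgraph")))
    readBedGraphTrack(fp("replication_timing.bedgraph"), layout, step) else NULL
  nuc <- if (file.exists(fp("nucleosome.bedgraph")))
    readBedGraphTrack(fp("nucleosome.bedgraph"), layout, step) else NULL
  contacts <- list()
  if (dir.exists(fp("contacts"))) {
    for (f in list.files(fp("contacts"), full.names = TRUE)) {
      cm <- readContactMatrixFile(f)
      contacts[[cm@chrom]] <- cm
    }
  }
  list(layout = layout, compartments = comp, peaks = peaks,
       svs = readSVTable(fp("svs.tsv"), layout),
       repeatPairs = if (file.exists(fp("repeat_pairs.tsv")))
         read.table(fp("repeat_pairs.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE) else NULL,
       tadBoundaries = readPoints(fp("tad_boundaries.bed")),
       loopAnchors = readPoints(fp("loop_anchors.bed")),
       rtTrack = rt, nucTrack = nuc, contacts = contacts)
}
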