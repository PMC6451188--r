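#' @importFrom Biostrings DNAStringSet DNAString subseq reverseComplement
#'   matchPDict PDict letterFrequency
#' @importFrom IRanges start end width
NULL

#' Sample seed loci from a genome
#'
#' Draws `n` loci of `seedLen` bp uniformly from the genome (chromosomes
#' weighted by length), resampling any locus whose sequence contains an
#' ambiguous base (assembly gap).
#'
#' @param genome `DNAStringSet` (one sequence per chromosome, named).
#' @param n number of loci.
#' @param seed integer seed.
#' @param seedLen locus length in bp (default 100).
#' @return GRanges of seed loci.
#' @export
sampleSeedLoci <- function(genome, n, seed = 1L, seedLen = 100L) {
  if (n < 1) stop("n must be >= 1")
  lens <- width(genome)
  if (all(lens < seedLen)) stop("genome shorter than the seed length")
  set.seed(seed)
  ok <- lens >= seedLen
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      ci <- sample(which(ok), 1L, prob = lens[ok])
      s <- sample.int(lens[ci] - seedLen + 1L, 1L)
      sq <- subseq(genome[[ci]], s, s + seedLen - 1L)
      if (sum(letterFrequency(sq, c("A", "C", "G", "T"))) == seedLen) break
    }
    out[[i]] <- c(names(genome)[ci], s)
  }
  ch <- vapply(out, `[[`, character(1), 1L)
  st <- as.integer(vapply(out, `[[`, character(1), 2L))
  GRanges(ch, IRanges(st, st + seedLen - 1L))
}

# Best ungapped local segment of a match/mismatch vector (Kadane with
# +1/-penalty scoring); returns NULL or list(start, end, len, ident).
.bestSegment <- function(isMatch, penalty = 5) {
  sc <- ifelse(isMatch, 1, -penalty)
  best <- 0; bestI <- 0L; bestJ <- -1L
  cur <- 0; curI <- 1L
  for (t in seq_along(sc)) {
    if (cur <= 0) { cur <- sc[t]; curI <- t } else cur <- cur + sc[t]
    if (cur > best) { best <- cur; bestI <- curI; bestJ <- t }
  }
  if (bestJ < bestI) return(NULL)
  len <- bestJ - bestI + 1L
  list(start = bestI, end = bestJ, len = len,
       ident = sum(isMatch[bestI:bestJ]) / len)
}

# Candidate ungapped alignments of seedSeq within windowSeq from exact
# k-mer diagonals. Returns data.frame(t_start, t_end, len, ident) in
# window-local coordinates.
.alignSeedInWindow <- function(seedSeq, windowSeq, k = 12L,
                               minLen = 50L, minIdent = 0.85) {
  sl <- length(seedSeq)
  if (sl < k) return(NULL)
  starts <- seq_len(sl - k + 1L)
  kmers <- DNAStringSet(lapply(starts, function(s) subseq(seedSeq, s, s + k - 1L)))
  clean <- rowSums(as.matrix(letterFrequency(kmers, c("A", "C", "G", "T")))) == k
  if (!any(clean)) return(NULL)
  kmers <- kmers[clean]; starts <- starts[clean]
  pd <- PDict(kmers)
  hits <- matchPDict(pd, windowSeq)
  diags <- unique(unlist(lapply(seq_along(hits), function(i) {
    start(hits[[i]]) - (starts[i] - 1L)
  })))
  if (!length(diags)) return(NULL)
  seedChars <- strsplit(as.character(seedSeq), "")[[1]]
  wl <- length(windowSeq)
  res <- list()
  for (d in diags) {
    q1 <- max(1L, 2L - d)            # query index whose target index >= 1
    q2 <- min(sl, wl - d + 1L)
    if (q2 - q1 + 1L < minLen) next
    tg <- as.character(subseq(windowSeq, d + q1 - 1L, d + q2 - 1L))
    tgChars <- strsplit(tg, "")[[1]]
    seg <- .bestSegment(seedChars[q1:q2] == tgChars)
    if (is.null(seg) || seg$len <= minLen || seg$ident <= minIdent) next
    res[[length(res) + 1L]] <- data.frame(
      t_start = d + q1 - 1L + seg$start - 1L,
      t_end = d + q1 - 1L + seg$end - 1L,
      len = seg$len, ident = seg$ident)
  }
  if (!length(res)) return(NULL)
  unique(do.call(rbind, res))
}

#' Find a homologous target for a seed locus
#'
#' Seed-and-extend homology search: exact 12-mer seeds anchor ungapped
#' extensions of the 100 bp query against the genomic window within
#' `maxSep` of the origin (both strands). Retained alignments must be in
#' the same orientation, longer than `minLen` bp, above `minIdent`
#' identity, non-self, and separated from the origin by `[minSep, maxSep]`
#' bp (start-to-start). Among survivors one target is chosen uniformly at
#' random (caller seeds the RNG); `NULL` when none survives.
#'
#' @param seedLocus single-range GRanges (from [sampleSeedLoci()]).
#' @param genome `DNAStringSet`.
#' @param k k-mer size for seeding (default 12).
#' @param minSep,maxSep separation bounds in bp (defaults 100 and 1e6).
#' @param minLen minimum alignment length, exclusive (default 50).
#' @param minIdent minimum identity, exclusive (default 0.85).
#' @return one-row data.frame (`chrom`, `origin_start`, `origin_end`,
#'   `target_start`, `target_end`, `orientation`, `alignment_length`,
#'   `identity`, `separation`) or `NULL`.
#' @export
findHomologousTarget <- function(seedLocus, genome, k = 12L,
                                 minSep = 100L, maxSep = 1e6,
                                 minLen = 50L, minIdent = 0.85) {
  ch <- as.character(seqnames(seedLocus))[1]
  oStart <- start(seedLocus)[1]
  oEnd <- end(seedLocus)[1]
  chromSeq <- genome[[ch]]
  seedSeq <- subseq(chromSeq, oStart, oEnd)
  winStart <- max(1L, oStart - as.integer(maxSep))
  winEnd <- min(length(chromSeq), oEnd + as.integer(maxSep))
  windowSeq <- subseq(chromSeq, winStart, winEnd)
  fwd <- .alignSeedInWindow(seedSeq, windowSeq, k, minLen, minIdent)
  cand <- NULL
  if (!is.null(fwd)) {
    fwd$orientation <- "same"
    fwd$g_start <- winStart - 1L + fwd$t_start
    fwd$g_end <- winStart - 1L + fwd$t_end
    cand <- fwd
  }
  rev <- .alignSeedInWindow(seedSeq, reverseComplement(windowSeq),
                            k, minLen, minIdent)
  if (!is.null(rev)) {
    wl <- winEnd - winStart + 1L
    rev$orientation <- "opposite"
    rev$g_start <- winStart - 1L + (wl - rev$t_end + 1L)
    rev$g_end <- winStart - 1L + (wl - rev$t_start + 1L)
    cand <- rbind(cand, rev)
  }
  if (is.null(cand)) return(NULL)
  cand$separation <- abs(cand$g_start - oStart)
  keep <- cand$orientation == "same" &
    cand$separation >= minSep & cand$separation <= maxSep &
    !(cand$g_start <= oEnd & cand$g_end >= oStart)
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand <- cand[!duplicated(cand$g_start), , drop = FALSE]
  pick <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
  data.frame(chrom = ch, origin_start = oStart, origin_end = oEnd,
             target_start = pick$g_start, target_end = pick$g_end,
             orientation = pick$orientation, alignment_length = pick$len,
             identity = pick$ident, separation = pick$separation,
             stringsAsFactors = FALSE)
}

#' Simulate homologous breakpoint pairs genome-wide
#'
#' Stage one of the NAHR simulation: sample seed loci and search each for a
#' homologous target; seeds without a surviving target are dropped.
#' @param genome `DNAStringSet`.
#' @param nSeeds number of seed loci.
#' @param seed integer seed.
#' @param ... passed to [findHomologousTarget()].
#' @return data.frame of homologous pairs (possibly 0 rows).
#' @export
simulateHomologousBreakpoints <- function(genome, nSeeds, seed = 1L, ...) {
  loci <- sampleSeedLoci(genome, nSeeds, seed = seed)
  out <- list()
  for (i in seq_along(loci)) {
    p <- findHomologousTarget(loci[i], genome, ...)
    if (!is.null(p)) out[[length(out) + 1L]] <- p
  }
  if (!length(out)) return(.emptyPairs())
  do.call(rbind, out)
}

.emptyPairs <- function() {
  data.frame(chrom = character(), origin_start = integer(),
             origin_end = integer(), target_start = integer(),
             target_end = integer(), orientation = character(),
             alignment_length = integer(), identity = numeric(),
             separation = numeric(), stringsAsFactors = FALSE)
}

#' Empirical length distribution of NAHR deletions
#'
#' Binned probability density over deletion lengths on a log-spaced grid,
#' used as the target for rejection sampling.
#' @param lengths numeric vector of real NAHR deletion lengths (bp).
#' @param nBins number of log-spaced bins (default 25).
#' @return object of class `svcLengthPDF`: list with `breaks`, `density`
#'   (integrates to 1 over the bins), and `maxDensity`.
#' @export
lengthPDF <- function(lengths, nBins = 25L) {
  lengths <- lengths[is.finite(lengths) & lengths > 0]
  if (length(lengths) < 2L) stop("need at least two lengths")
  r <- range(lengths)
  if (r[1] == r[2]) r <- r * c(0.99, 1.01)
  breaks <- exp(seq(log(r[1]), log(r[2]), length.out = nBins + 1L))
  breaks[1] <- breaks[1] * (1 - 1e-9)
  cnt <- as.numeric(table(cut(lengths, breaks, include.lowest = TRUE)))
  dens <- cnt / (length(lengths) * diff(breaks))
  structure(list(breaks = breaks, density = dens, maxDensity = max(dens)),
            class = "svcLengthPDF")
}

#' @rdname lengthPDF
#' @param pdf an `svcLengthPDF`.
#' @param at lengths at which to evaluate the density.
#' @export
lengthDensity <- function(pdf, at) {
  idx <- findInterval(at, pdf$breaks, rightmost.closed = TRUE)
  out <- numeric(length(at))
  ok <- idx >= 1L & idx <= length(pdf$density)
  out[ok] <- pdf$density[idx[ok]]
  out
}

#' Rejection-sample simulated pairs to a target length distribution
#'
#' Stage two of the NAHR simulation: each pair's implied deletion length
#' (origin-start to target-start separation) is accepted with probability
#' `density(L) / maxDensity`, so accepted lengths converge to the target
#' distribution restricted to attainable lengths.
#' @param pairs data.frame of homologous pairs.
#' @param pdf [lengthPDF()] of real NAHR deletion lengths.
#' @param seed integer seed.
#' @return accepted subset of `pairs`.
#' @export
lengthRejectionSample <- function(pairs, pdf, seed = 1L) {
  if (pdf$maxDensity <= 0) stop("degenerate length distribution")
  if (!nrow(pairs)) return(pairs)
  set.seed(seed)
  L <- abs(pairs$target_start - pairs$origin_start)
  acc <- runif(nrow(pairs)) < lengthDensity(pdf, L) / pdf$maxDensity
  pairs[acc, , drop = FALSE]
}

# Largest-remainder apportionment of `size` among proportions.
.largestRemainder <- function(props, size) {
  raw <- props * size
  base <- floor(raw)
  need <- size - sum(base)
  if (need > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(need)]] <- base[ord[seq_len(need)]] + 1
  }
  as.integer(base)
}

#' Match simulated pairs to real compartment proportions
#'
#' Stage three of the NAHR simulation ("advanced simulated NAHR"): pairs
#' are labeled by the compartment of their origin breakpoint, and sampled
#' per compartment (uniformly within) in the proportions observed for real
#' NAHR breakpoints; the per-compartment quota is the largest-remainder
#' rounding of `proportion * size`.
#'
#' @param pairs data.frame of homologous pairs.
#' @param realNahr GRanges of real NAHR deletions.
#' @param track compartment segmentation GRanges with `label`.
#' @param size output size; default the largest size the per-compartment
#'   pools can honor.
#' @param seed integer seed.
#' @return subset of `pairs` of exactly `size` rows.
#' @export
matchCompartmentProportions <- function(pairs, realNahr, track,
                                        size = NULL, seed = 1L) {
  bp <- svBreakpoints(realNahr)
  lab <- assignLabel(bp[, c("chrom", "pos")], track)
  props <- table(lab) / length(lab)
  pairLab <- assignLabel(data.frame(chrom = pairs$chrom,
                                    pos = pairs$origin_start), track)
  pool <- table(factor(pairLab, levels = names(props)))
  if (is.null(size)) {
    pos <- props > 0
    size <- floor(min(as.numeric(pool[pos]) / as.numeric(props[pos])))
    if (size < 1) size <- 0L
  }
  quota <- .largestRemainder(as.numeric(props), size)
  names(quota) <- names(props)
  deficit <- quota - as.numeric(pool)
  if (any(deficit > 0))
    stop("insufficient simulated pairs per compartment: ",
         paste(sprintf("%s needs %d more", names(props)[deficit > 0],
                       deficit[deficit > 0]), collapse = "; "))
  set.seed(seed)
  idx <- unlist(lapply(names(quota), function(l) {
    cand <- which(pairLab == l)
    if (quota[[l]] == 0L) return(integer())
    cand[sample.int(length(cand), quota[[l]])]
  }))
  pairs[sort(idx), , drop = FALSE]
}

#' Breakpoints of homologous pairs
#' @param pairs data.frame of homologous pairs.
#' @return data.frame with `chrom`, `pos` (origin and target starts).
#' @export
pairBreakpoints <- function(pairs) {
  data.frame(chrom = rep(pairs$chrom, 2L),
             pos = c(pairs$origin_start, pairs$target_start),
             stringsAsFactors = FALSE)
}

#' Convert homologous pairs to simulated deletion intervals
#' @param pairs data.frame of homologous pairs.
#' @param mechanism label stored in the `mechanism` column (default
#'   `"NAHR"`; use e.g. `"simulated"` for control sets).
#' @return GRanges spanning origin start to target start.
#' @export
pairsToSV <- function(pairs, mechanism = "NAHR") {
  s <- pmin(pairs$origin_start, pairs$target_start)
  e <- pmax(pairs$origin_start, pairs$target_start)
  gr <- GRanges(pairs$chrom, IRanges(s, e))
  mcols(gr)$mechanism <- mechanism
  gr
}

#' Fold enrichment of breakpoints in repeat elements
#'
#' Fold = (fraction of breakpoints inside repeats) / (fraction of the
#' genome covered by repeats), with a chi-square test of the observed
#' in/out counts against the coverage expectation.
#' @param points data.frame with `chrom`, `pos` (e.g. [pairBreakpoints()]).
#' @param repeats GRanges of repeat elements.
#' @param layout [GenomeLayout-class].
#' @return list with `fold`, `p`, `nIn`, `n`, `coverage`.
#' @export
repeatEnrichment <- function(points, repeats, layout) {
  red <- reduce(repeats)
  cov <- sum(as.numeric(width(red))) / totalLength(layout)
  if (cov <= 0) stop("repeat set covers zero bases")
  pts <- GRanges(points$chrom, IRanges(points$pos, points$pos))
  nIn <- sum(suppressWarnings(overlapsAny(pts, red)))
  n <- nrow(points)
  fold <- (nIn / n) / cov
  p <- suppressWarnings(chisq.test(c(nIn, n - nIn), p = c(cov, 1 - cov))$p.value)
  list(fold = fold, p = p, nIn = nIn, n = n, coverage = cov)
}
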