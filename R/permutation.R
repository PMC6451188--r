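#' Circularly permute an SV set
#'
#' The genome is treated as a circle of sequentially arranged chromosomes
#' (layout order). A single shared offset is added to the linear coordinate
#' of every SV, wrapping around the genome end; SV lengths are unchanged.
#' Because a shifted SV can straddle a chromosome junction, the permuted set
#' is returned as a table of breakpoint pairs rather than a `GRanges`.
#'
#' @param svs SV GRanges (see [makeSVSet()]).
#' @param layout [GenomeLayout-class].
#' @param offset shift in bp, `0 <= offset < totalLength(layout)`.
#' @return data.frame with columns `mechanism`, `length` (bp between the two
#'   breakpoints), `lin_bp1`, `lin_bp2` (linear coordinates), and the mapped
#'   `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @export
circularPermute <- function(svs, layout, offset) {
  L <- totalLength(layout)
  if (offset < 0 || offset >= L)
    stop("offset must be in [0, totalLength(layout) - 1]")
  ch <- as.character(seqnames(svs))
  lin1 <- shiftCircular(linearCoordinate(layout, ch, start(svs)), offset, L)
  len <- end(svs) - start(svs)
  lin2 <- shiftCircular(lin1, len, L)
  m1 <- linearInverse(layout, lin1)
  m2 <- linearInverse(layout, lin2)
  data.frame(mechanism = as.character(mcols(svs)$mechanism),
             length = len, lin_bp1 = lin1, lin_bp2 = lin2,
             chrom1 = m1$chrom, pos1 = m1$pos,
             chrom2 = m2$chrom, pos2 = m2$pos,
             stringsAsFactors = FALSE)
}

#' Draw the offsets of a circular-permutation background ensemble
#'
#' Draws `n` independent uniform offsets in `[1, totalLength - 1]`;
#' offset `i` defines permuted set `i` via [circularPermute()].
#'
#' @param layout [GenomeLayout-class].
#' @param n number of permutations (>= 1); 1000 in typical use.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return numeric vector of `n` offsets.
#' @export
backgroundEnsemble <- function(layout, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  L <- totalLength(layout)
  set.seed(seed)
  sample(L - 1, n, replace = TRUE)
}

#' Fraction of points per segmentation label
#'
#' Fraction of points residing in each label of the segmentation; points in
#' gaps count toward the denominator but no label, so fractions sum to <= 1.
#' @param points data.frame with `chrom`, `pos`.
#' @param track segmentation GRanges with `label` column.
#' @return named numeric vector over the track's label set.
#' @export
categoryFractions <- function(points, track) {
  if (nrow(points) == 0L) stop("empty point list")
  lab <- assignLabel(points, track)
  lev <- sort(unique(as.character(mcols(track)$label)))
  counts <- table(factor(lab, levels = lev))
  as.numeric(counts) / nrow(points) -> fr
  setNames(fr, lev)
}

# Shared Z-score assembly: observed and a (nPerm x nStat) background matrix.
.zTable <- function(observed, bg, nPerm) {
  bgMean <- colMeans(bg)
  bgSd <- apply(bg, 2L, sd)
  z <- ifelse(bgSd > 0, (observed - bgMean) / bgSd, NA_real_)
  p <- 2 * pnorm(-abs(z))
  m <- sum(!is.na(p))
  padj <- pmin(1, p * max(m, 1L))
  data.frame(observed = observed, bg_mean = bgMean, bg_sd = bgSd,
             z = z, p = p, p_adj = padj, n_perm = nPerm)
}

# Per-permutation label counts for a set of linear positions, fully
# vectorized across permutations (processed in memory-bounded chunks).
# Returns array [nLabels, nGroups, nPerm] of counts.
.permLabelCounts <- function(linpos, group, nGroups, offsets, L, seg) {
  nLab <- length(seg$levels)
  np <- length(linpos)
  out <- array(0L, dim = c(nLab, nGroups, length(offsets)))
  chunk <- max(1L, floor(4e6 / np))
  starts <- seq(1L, length(offsets), by = chunk)
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1L, length(offsets))
    shifted <- ((rep(linpos - 1, length(idx)) +
                 rep(offsets[idx], each = np)) %% L) + 1
    code <- .labelAtLinear(shifted, seg)
    keep <- code > 0L
    if (any(keep)) {
      permIdx <- rep(seq_along(idx), each = np)[keep]
      flat <- code[keep] + nLab * (rep(group, length(idx))[keep] - 1L) +
        nLab * nGroups * (permIdx - 1L)
      tab <- tabulate(flat, nbins = nLab * nGroups * length(idx))
      out[, , idx] <- out[, , idx, drop = FALSE] +
        array(tab, dim = c(nLab, nGroups, length(idx)))
    }
  }
  out
}

#' Z-score enrichment of SV classes across a segmentation
#'
#' For each mechanism, the observed fraction of breakpoints (two per SV) in
#' each segmentation label is compared with a background of `nPerm`
#' circularly permuted SV sets; `Z = (observed - mean) / sd` with a
#' two-sided normal p-value and Bonferroni adjustment over all
#' (mechanism x label) tests in the family. With `unit = "region"` the
#' statistic is instead the fraction of affected (e.g. deleted) bases per
#' label.
#'
#' @param svs SV GRanges.
#' @param track segmentation GRanges with `label`.
#' @param layout [GenomeLayout-class].
#' @param nPerm number of permutations (>= 2); default 1000.
#' @param seed integer seed for the offset draw.
#' @param unit `"breakpoint"` (default) or `"region"`.
#' @return data.frame with one row per (mechanism, label): `observed`,
#'   `bg_mean`, `bg_sd`, `z` (NA when the background sd is 0), `p`, `p_adj`,
#'   `n_perm`.
#' @export
enrichmentZscores <- function(svs, track, layout, nPerm = 1000L, seed = 1L,
                              unit = c("breakpoint", "region")) {
  unit <- match.arg(unit)
  if (nPerm < 2) stop("nPerm must be >= 2")
  seg <- .segLinear(track, layout)
  L <- totalLength(layout)
  offsets <- backgroundEnsemble(layout, nPerm, seed)
  mech <- as.character(mcols(svs)$mechanism)
  mechs <- sort(unique(mech))
  nG <- length(mechs)
  nLab <- length(seg$levels)
  if (unit == "breakpoint") {
    bp <- svBreakpoints(svs)
    lin <- linearCoordinate(layout, bp$chrom, bp$pos)
    group <- match(bp$mechanism, mechs)
    gSize <- as.numeric(table(factor(bp$mechanism, levels = mechs)))
    obsCounts <- .permLabelCounts(lin, group, nG, 0, L, seg)[, , 1, drop = FALSE]
    bgCounts <- .permLabelCounts(lin, group, nG, offsets, L, seg)
    observed <- sweep(matrix(obsCounts, nLab, nG), 2L, gSize, "/")
    bg <- array(bgCounts, dim = c(nLab * nG, nPerm))
    bg <- t(bg / rep(gSize, each = nLab))
  } else {
    ch <- as.character(seqnames(svs))
    a <- linearCoordinate(layout, ch, start(svs))
    len <- end(svs) - start(svs)
    group <- match(mech, mechs)
    gBases <- as.numeric(tapply(len + 1, factor(mech, levels = mechs), sum))
    segIR <- IRanges(seg$start, seg$end)
    regionCounts <- function(aShift) {
      b <- aShift + len
      wrap <- b > L
      ir <- IRanges(c(aShift, rep(1, sum(wrap))),
                    c(pmin(b, L), b[wrap] - L))
      grp <- c(group, group[wrap])
      h <- findOverlaps(ir, segIR)
      w <- width(pintersect(ir[queryHits(h)], segIR[subjectHits(h)]))
      codes <- seg$code[subjectHits(h)]
      m <- matrix(0, nLab, nG)
      if (length(h)) {
        flat <- codes + nLab * (grp[queryHits(h)] - 1L)
        tt <- tapply(w, flat, sum)
        m[as.integer(names(tt))] <- as.numeric(tt)
      }
      sweep(m, 2L, gBases, "/")
    }
    observed <- regionCounts(a)
    bgRaw <- vapply(offsets, function(off)
      as.numeric(regionCounts(shiftCircular(a, off, L))),
      numeric(nLab * nG))
    bg <- if (is.matrix(bgRaw)) t(bgRaw) else matrix(bgRaw, ncol = 1L)
  }
  res <- .zTable(as.numeric(observed), bg, nPerm)
  cbind(data.frame(mechanism = rep(mechs, each = nLab),
                   label = rep(seg$levels, nG),
                   stringsAsFactors = FALSE), res)
}

# Number of points strictly inside each circular arc (a, a + len), where
# sortedP are sorted linear point coordinates. Vectorized over arcs.
.pointsInsideArc <- function(a, len, sortedP, L) {
  fi <- function(x) findInterval(x, sortedP)
  b <- a + len
  noWrap <- b <= L
  cnt <- numeric(length(a))
  cnt[noWrap] <- fi(b[noWrap] - 1) - fi(a[noWrap])
  if (any(!noWrap)) {
    w <- !noWrap
    cnt[w] <- (length(sortedP) - fi(a[w])) + fi(b[w] - L - 1)
  }
  cnt
}

#' Z-score enrichment of SVs encompassing genomic points
#'
#' The observed statistic per mechanism is the number of SVs whose open
#' interval strictly contains at least one of the supplied points (TAD
#' boundaries, loop anchors); each SV counts once regardless of how many
#' points it contains. Background from circular permutations; an SV shifted
#' across the genome end is scored on its circular arc.
#'
#' @param svs SV GRanges.
#' @param points data.frame with `chrom`, `pos`.
#' @inheritParams enrichmentZscores
#' @return data.frame with one row per mechanism (label column carries the
#'   statistic name `"encompassing"`).
#' @export
encompassingZscores <- function(svs, points, layout, nPerm = 1000L, seed = 1L) {
  if (nPerm < 2) stop("nPerm must be >= 2")
  L <- totalLength(layout)
  offsets <- backgroundEnsemble(layout, nPerm, seed)
  sortedP <- sort(linearCoordinate(layout, points$chrom, points$pos))
  ch <- as.character(seqnames(svs))
  a <- linearCoordinate(layout, ch, start(svs))
  len <- end(svs) - start(svs)
  mech <- as.character(mcols(svs)$mechanism)
  mechs <- sort(unique(mech))
  grp <- factor(mech, levels = mechs)
  countStat <- function(aShift) {
    hit <- .pointsInsideArc(aShift, len, sortedP, L) >= 1
    as.numeric(tapply(hit, grp, sum))
  }
  observed <- countStat(a)
  bgRaw <- vapply(offsets, function(off) countStat(shiftCircular(a, off, L)),
                  numeric(length(mechs)))
  bg <- if (is.matrix(bgRaw)) t(bgRaw) else matrix(bgRaw, ncol = 1L)
  res <- .zTable(observed, bg, nPerm)
  cbind(data.frame(mechanism = mechs, label = "encompassing",
                   stringsAsFactors = FALSE), res)
}

#' Cluster SV mechanisms by enrichment profile
#'
#' Agglomerative clustering (Euclidean distance, average linkage by default)
#' of mechanisms by their Z-score vectors across labels. Rows containing
#' undefined Z values are excluded with a warning.
#'
#' @param z numeric matrix, mechanisms x labels (rownames = mechanisms).
#' @param method linkage passed to [stats::hclust()].
#' @return list with `order` (leaf order, mechanism names), `height`
#'   (merge heights) and the `hclust` object.
#' @export
zscoreCluster <- function(z, method = "average") {
  z <- as.matrix(z)
  bad <- !complete.cases(z)
  if (any(bad)) {
    warning("excluding rows with undefined Z: ",
            paste(rownames(z)[bad], collapse = ", "))
    z <- z[!bad, , drop = FALSE]
  }
  if (nrow(z) < 2L) stop("need at least two mechanisms to cluster")
  hc <- hclust(dist(z), method = method)
  list(order = rownames(z)[hc$order], height = hc$height, hclust = hc)
}
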