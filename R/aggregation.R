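#' Construct an AggregationProfile
#' @param offsets integer bin left edges (bp, relative to anchor).
#' @param values numeric per-bin values.
#' @param nAnchors anchor count.
#' @param mode "peak-fraction" or "signal".
#' @param binWidth bin width in bp.
#' @export
AggregationProfile <- function(offsets, values, nAnchors, mode, binWidth) {
  new("AggregationProfile", offsets = as.integer(offsets),
      values = as.numeric(values), nAnchors = as.integer(nAnchors),
      mode = mode, binWidth = as.integer(binWidth))
}

setMethod("show", "AggregationProfile", function(object) {
  cat("AggregationProfile (", object@mode, "): ", length(object@values),
      " bins of ", object@binWidth, " bp, ", object@nAnchors, " anchors\n",
      sep = "")
})

#' @rdname AggregationProfile
#' @param object an AggregationProfile.
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))

#' @rdname AggregationProfile
#' @export
setMethod("profileValues", "AggregationProfile", function(object)
  setNames(object@values, object@offsets))

#' @rdname AggregationProfile
#' @export
setGeneric("profileOffsets", function(object) standardGeneric("profileOffsets"))

#' @rdname AggregationProfile
#' @export
setMethod("profileOffsets", "AggregationProfile", function(object) object@offsets)

#' Value of a profile at the anchor (offset zero)
#'
#' The half-open bin grid has no bin centered at 0, so the anchor-level
#' value is the mean of the two bins flanking offset 0 (left edges `-bin`
#' and `0`).
#' @param object an [AggregationProfile-class].
#' @return numeric scalar.
#' @export
offsetZeroValue <- function(object) {
  i <- match(c(-object@binWidth, 0L), object@offsets)
  if (anyNA(i)) stop("profile has no bins flanking offset 0")
  mean(object@values[i])
}

# Bin grid around anchors: bin k covers anchor-relative offsets
# [k*bin, (k+1)*bin), k in [-window/bin, window/bin).
.binOffsets <- function(window, bin) {
  k <- seq.int(-window %/% bin, window %/% bin - 1L)
  as.integer(k * bin)
}

#' Peak aggregation around anchor points
#'
#' For every `bin`-bp bin within `window` bp of each anchor, the fraction of
#' the bin's bases covered by at least one peak is computed, summed over
#' anchors and divided by the anchor count. Bins truncated by a chromosome
#' end contribute their available covered bases over the full bin width.
#'
#' @param anchors data.frame with `chrom`, `pos` (1-based anchor positions;
#'   the anchor base is the first base of the offset-0 bin).
#' @param peaks GRanges of peaks.
#' @param layout optional [GenomeLayout-class] used to clip bins at
#'   chromosome ends.
#' @param window half-window in bp (default 2500).
#' @param bin bin width in bp (default 100).
#' @return [AggregationProfile-class] in peak-fraction mode.
#' @export
peakAggregation <- function(anchors, peaks, layout = NULL,
                            window = 2500L, bin = 100L) {
  if (nrow(anchors) == 0L) stop("empty anchor set")
  offs <- .binOffsets(window, bin)
  nb <- length(offs)
  n <- nrow(anchors)
  binStart <- rep(anchors$pos, each = nb) + rep(offs, n)
  binEnd <- binStart + bin - 1
  binChrom <- rep(anchors$chrom, each = nb)
  if (!is.null(layout)) {
    len <- chromLengths(layout)[binChrom]
    binEnd <- pmin(binEnd, len)
  }
  binStart <- pmax(binStart, 1)
  keep <- binStart <= binEnd
  covered <- numeric(n * nb)
  if (any(keep) && length(peaks)) {
    bins <- GRanges(binChrom[keep], IRanges(binStart[keep], binEnd[keep]))
    red <- reduce(peaks)
    h <- suppressWarnings(findOverlaps(bins, red))
    if (length(h)) {
      w <- width(pintersect(bins[queryHits(h)], red[subjectHits(h)]))
      cv <- tapply(w, queryHits(h), sum)
      covered[keep][as.integer(names(cv))] <- as.numeric(cv)
    }
  }
  perBin <- rowsum(covered, rep(seq_len(nb), n))
  AggregationProfile(offs, as.numeric(perBin) / (n * bin), n,
                     "peak-fraction", bin)
}

#' Peak aggregation around regulatory-site midpoints
#'
#' As [peakAggregation()] but anchored at interval midpoints
#' (`start + floor(width/2)`) with a finer default bin of 10 bp.
#' @param sites GRanges of regulatory sites.
#' @inheritParams peakAggregation
#' @export
regulatoryAggregation <- function(sites, peaks, layout = NULL,
                                  window = 2500L, bin = 10L) {
  anchors <- data.frame(chrom = as.character(seqnames(sites)),
                        pos = start(sites) + width(sites) %/% 2L,
                        stringsAsFactors = FALSE)
  peakAggregation(anchors, peaks, layout, window = window, bin = bin)
}

#' Signal aggregation around anchor points
#'
#' Per anchor and bin, the mean of available (non-missing) per-base track
#' values; summed over anchors and divided by the number of anchors with any
#' available signal; finally divided by the profile mean over the
#' `normWindow`-bp region around the anchor, so a flat track yields 1.0 in
#' every bin.
#'
#' @param anchors data.frame with `chrom`, `pos`.
#' @param track [SignalTrack-class].
#' @param window half-window in bp (default 1000).
#' @param bin bin width in bp (default 10).
#' @param normWindow width (bp) of the centered normalization region
#'   (default 2000).
#' @return [AggregationProfile-class] in signal mode.
#' @export
signalAggregation <- function(anchors, track, window = 1000L, bin = 10L,
                              normWindow = 2000L) {
  prof <- .signalBins(anchors, track, window, bin)
  if (prof$nUsed == 0L) stop("no anchor has available signal")
  vals <- prof$sums / prof$nUsed
  offs <- prof$offsets
  normIdx <- offs >= -normWindow / 2 & offs + bin <= normWindow / 2
  if (!any(normIdx)) normIdx <- rep(TRUE, length(offs))
  nm <- mean(vals[normIdx], na.rm = TRUE)
  if (!is.finite(nm) || nm == 0) stop("normalization region has no signal")
  AggregationProfile(offs, vals / nm, prof$nUsed, "signal", bin)
}

# Raw binned signal sums over anchors, optionally restricted by side.
# side: "both", "left" (negative offsets only), "right" (non-negative only).
.signalBins <- function(anchors, track, window, bin, side = "both") {
  offs <- .binOffsets(window, bin)
  if (side == "left") offs <- offs[offs < 0L]
  if (side == "right") offs <- offs[offs >= 0L]
  nb <- length(offs)
  baseOff <- rep(offs, each = bin) + seq_len(bin) - 1L
  sums <- numeric(nb)
  nUsed <- 0L
  for (i in seq_len(nrow(anchors))) {
    v <- trackValuesAt(track, anchors$chrom[i], anchors$pos[i] + baseOff)
    if (all(is.na(v))) next
    nUsed <- nUsed + 1L
    m <- matrix(v, nrow = bin)
    bm <- colMeans(m, na.rm = TRUE)
    bm[is.nan(bm)] <- 0
    sums <- sums + bm
  }
  list(offsets = offs, sums = sums, nUsed = nUsed)
}

#' Element-boundary anchor sets
#'
#' For length-conserved elements (retrotransposons, pseudogenes) aggregation
#' is anchored at element boundaries: upstream of the start and downstream
#' of the end, so the element interior does not smear the flanks.
#' @param elements GRanges.
#' @return list with data.frames `start` and `end` (columns `chrom`, `pos`).
#' @export
elementBoundaryAnchors <- function(elements) {
  ch <- as.character(seqnames(elements))
  list(start = data.frame(chrom = ch, pos = start(elements),
                          stringsAsFactors = FALSE),
       end = data.frame(chrom = ch, pos = end(elements),
                        stringsAsFactors = FALSE))
}

#' Boundary-anchored signal profile for length-conserved elements
#'
#' Aggregates signal over negative offsets relative to element starts and
#' positive offsets relative to element ends; the element interior is
#' summarized as a single mean value. All values are normalized by the mean
#' of the flanking profile, so a flat track yields 1.0 everywhere including
#' the interior.
#'
#' @param elements GRanges.
#' @param track [SignalTrack-class].
#' @inheritParams signalAggregation
#' @return list with `profile` (an [AggregationProfile-class]; negative
#'   offsets flank the start, non-negative the end) and `interiorMean`.
#' @export
boundarySignalProfile <- function(elements, track, window = 1000L, bin = 10L) {
  anch <- elementBoundaryAnchors(elements)
  left <- .signalBins(anch$start, track, window, bin, side = "left")
  right <- .signalBins(anch$end, track, window, bin, side = "right")
  nUsed <- max(left$nUsed, right$nUsed)
  if (nUsed == 0L) stop("no element has available signal")
  vals <- c(left$sums / max(left$nUsed, 1L), right$sums / max(right$nUsed, 1L))
  interior <- vapply(seq_along(elements), function(i) {
    v <- trackValuesAt(track, as.character(seqnames(elements))[i],
                       seq(start(elements)[i], end(elements)[i]))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  interiorMean <- mean(interior, na.rm = TRUE)
  nm <- mean(vals)
  if (!is.finite(nm) || nm == 0) stop("flanking region has no signal")
  prof <- AggregationProfile(c(left$offsets, right$offsets), vals / nm,
                             nUsed, "signal", bin)
  list(profile = prof, interiorMean = interiorMean / nm)
}

#' Mean replication time around breakpoints
#'
#' Mean of available per-base replication-time values over the 1000 bases
#' centered on each point (`flank` on each side, `[pos - flank, pos + flank)`).
#' @param points data.frame with `chrom`, `pos`.
#' @param rt [SignalTrack-class] replication-timing track.
#' @param flank bp on each side (default 500).
#' @return numeric vector (NA where no data in the window).
#' @export
meanReplicationTime <- function(points, rt, flank = 500L) {
  vapply(seq_len(nrow(points)), function(i) {
    v <- trackValuesAt(rt, points$chrom[i],
                       seq(points$pos[i] - flank, points$pos[i] + flank - 1L))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS test: `D` is the supremum of the absolute ECDF difference,
#' with the asymptotic p-value.
#' @param x,y numeric samples (non-empty).
#' @return list with `D` and `p`.
#' @export
ksTwoSample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Cluster mechanisms by replication-time distributions
#'
#' Pairwise distance between mechanisms is the two-sample KS `D` statistic
#' between their replication-time samples; average-linkage agglomerative
#' clustering.
#' @param samples named list of numeric vectors (one per mechanism).
#' @param method linkage for [stats::hclust()].
#' @return list with `order`, `height`, `D` (distance matrix), and `hclust`.
#' @export
ksCluster <- function(samples, method = "average") {
  if (length(samples) < 2L) stop("need at least two mechanisms to cluster")
  n <- length(samples)
  D <- matrix(0, n, n, dimnames = list(names(samples), names(samples)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- ksTwoSample(samples[[i]], samples[[j]])$D
  }
  hc <- hclust(as.dist(D), method = method)
  list(order = names(samples)[hc$order], height = hc$height, D = D, hclust = hc)
}

#' Classify non-homologous deletions by junction signatures
#'
#' Micro-homology greater than 2 bp or micro-insertion longer than 10 bp is
#' evidence of replication-related errors (`NHrepl`); absence of both
#' (0 bp each) indicates non-homologous end joining (`NHEJ`); anything in
#' between is `ambiguous` and is conventionally excluded from analysis.
#' @param micro_homology_bp,micro_insertion_bp non-negative integers
#'   (vectorized).
#' @return character vector of `"NHrepl"`, `"NHEJ"`, `"ambiguous"`.
#' @export
classifyNonhomologous <- function(micro_homology_bp, micro_insertion_bp) {
  mh <- as.numeric(micro_homology_bp)
  mi <- as.numeric(micro_insertion_bp)
  if (any(mh < 0 | mi < 0, na.rm = TRUE))
    stop("micro-homology/insertion lengths must be non-negative")
  out <- rep("ambiguous", length(mh))
  out[mh > 2 | mi > 10] <- "NHrepl"
  out[mh == 0 & mi == 0] <- "NHEJ"
  out
}

#' Classify pseudogene length by nucleosome periodicity
#'
#' A processed pseudogene is `"close"` to nucleosome periodicity if its
#' length modulo 150 falls in `[0, 50]` or `[100, 150)`, else `"away"`.
#' Upstream filters (identity > 0.95 to the parent gene, length > 250 bp)
#' are the caller's responsibility.
#' @param length_bp positive integer length(s).
#' @return character vector of `"close"` / `"away"`.
#' @export
classifyPseudogenePeriodicity <- function(length_bp) {
  if (any(length_bp <= 0)) stop("length must be positive")
  r <- length_bp %% 150
  ifelse(r <= 50 | r >= 100, "close", "away")
}

#' Compare interaction value distributions
#'
#' Two-sample KS comparison of normalized Hi-C interaction values with the
#' ECDF curves for plotting.
#' @param a,b numeric vectors of interaction values.
#' @return list with `D`, `p`, and `ecdf_a`, `ecdf_b` (functions).
#' @export
compareInteractions <- function(a, b) {
  kt <- ksTwoSample(a, b)
  list(D = kt$D, p = kt$p, ecdf_a = stats::ecdf(a), ecdf_b = stats::ecdf(b))
}
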