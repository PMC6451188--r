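#' Assign points to segmentation labels
#'
#' A segmentation track is a `GRanges` with a `label` metadata column and
#' non-overlapping segments per chromosome. A point at position `p` belongs
#' to the segment whose interval contains it (segment boundaries are
#' inclusive on both ends in the 1-based closed convention); points in gaps
#' get `"unassigned"`.
#'
#' @param points data.frame with columns `chrom`, `pos` (1-based).
#' @param track GRanges segmentation with metadata column `label`.
#' @return character vector of labels.
#' @export
assignLabel <- function(points, track) {
  stopifnot(!is.null(mcols(track)$label))
  pts <- GRanges(points$chrom, IRanges(points$pos, points$pos))
  hits <- suppressWarnings(findOverlaps(pts, track, select = "first"))
  lab <- rep("unassigned", nrow(points))
  ok <- !is.na(hits)
  lab[ok] <- as.character(mcols(track)$label[hits[ok]])
  lab
}

#' Overlap in bases between two intervals
#'
#' `max(0, min(ends) - max(starts) + 1)` in the 1-based closed convention
#' when chromosomes match, else 0. Vectorized with recycling.
#' @param chromA,startA,endA first interval(s).
#' @param chromB,startB,endB second interval(s).
#' @return integer vector of overlapping base counts.
#' @export
overlapBases <- function(chromA, startA, endA, chromB, startB, endB) {
  ov <- pmin(endA, endB) - pmax(startA, startB) + 1
  ov <- pmax(0, ov)
  ov[as.character(chromA) != as.character(chromB)] <- 0
  ov
}

#' Select non-variable Alu elements
#'
#' Keeps Alu intervals with length in `[280, 350]` bp (inclusive) that have
#' zero overlap with any SV interval; such elements are taken to be fixed in
#' the population.
#' @param alus GRanges of Alu elements.
#' @param svs GRanges of SVs.
#' @return GRanges subset of `alus`.
#' @export
selectNonvariableAlus <- function(alus, svs) {
  lenOK <- width(alus) >= 280 & width(alus) <= 350
  noSV <- !suppressWarnings(overlapsAny(alus, svs))
  alus[lenOK & noSV]
}

# Segmentation in linear coordinates: fast lookup used by the permutation
# machinery. Returns sorted segment starts/ends (linear, 1-based closed)
# and integer label codes; code 0 = unassigned gap.
.segLinear <- function(track, layout) {
  ch <- as.character(seqnames(track))
  s <- linearCoordinate(layout, ch, start(track))
  e <- s + width(track) - 1
  o <- order(s)
  labels <- as.character(mcols(track)$label)
  lev <- sort(unique(labels))
  list(start = s[o], end = e[o], code = match(labels, lev)[o], levels = lev)
}

# Label codes (0 = unassigned) for linear positions against .segLinear output.
.labelAtLinear <- function(pos, seg) {
  idx <- findInterval(pos, seg$start)
  code <- integer(length(pos))
  ok <- idx >= 1L
  okIdx <- idx[ok]
  inside <- pos[ok] <= seg$end[okIdx]
  code[ok][inside] <- seg$code[okIdx][inside]
  code
}

#' Breakpoints of an SV set
#'
#' Each SV contributes two breakpoints: its interval start and end.
#' @param svs SV GRanges.
#' @return data.frame with columns `chrom`, `pos`, `mechanism`, `sv` (index).
#' @export
svBreakpoints <- function(svs) {
  mech <- as.character(mcols(svs)$mechanism)
  data.frame(chrom = rep(as.character(seqnames(svs)), 2L),
             pos = c(start(svs), end(svs)),
             mechanism = rep(mech, 2L),
             sv = rep(seq_along(svs), 2L),
             stringsAsFactors = FALSE)
}
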