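#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats rnorm rpois runif rbinom sd pnorm ks.test hclust dist
#'   chisq.test lm complete.cases setNames quantile median as.dist
#' @importFrom utils read.table write.table head tail
NULL

#' GenomeLayout: ordered chromosomes with lengths
#'
#' A `GenomeLayout` fixes the chromosome order and lengths and thereby a
#' linearized coordinate system in which the whole genome is laid out as one
#' circle of sequentially arranged chromosomes. All circular-permutation
#' machinery operates in this linear space.
#'
#' @slot chroms character vector of unique chromosome names, in order.
#' @slot lengths numeric vector of chromosome lengths in bp (> 0).
#' @export
setClass("GenomeLayout",
  representation(chroms = "character", lengths = "numeric"))

setValidity("GenomeLayout", function(object) {
  msg <- character()
  if (length(object@chroms) != length(object@lengths))
    msg <- c(msg, "chroms and lengths differ in length")
  if (anyDuplicated(object@chroms))
    msg <- c(msg, "chromosome names must be unique")
  if (length(object@lengths) && any(!is.finite(object@lengths) | object@lengths <= 0))
    msg <- c(msg, "chromosome lengths must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' SignalTrack: fixed-step numeric genome track
#'
#' Per-chromosome numeric values sampled on a fixed step grid (bp); `NA`
#' marks missing data. Base `b` (1-based) falls in cell
#' `floor((b - 1) / step) + 1`.
#'
#' @slot values named list (one numeric vector per chromosome).
#' @slot step integer step size in bp (>= 1).
#' @export
setClass("SignalTrack",
  representation(values = "list", step = "integer"))

setValidity("SignalTrack", function(object) {
  msg <- character()
  if (length(object@step) != 1L || is.na(object@step) || object@step < 1L)
    msg <- c(msg, "step must be a single integer >= 1")
  if (is.null(names(object@values)) && length(object@values))
    msg <- c(msg, "values must be a named list (chromosome names)")
  if (!all(vapply(object@values, is.numeric, logical(1))))
    msg <- c(msg, "values must be numeric vectors")
  if (length(msg)) msg else TRUE
})

#' ContactMatrix: symmetric intra-chromosomal Hi-C contact counts
#'
#' Dense symmetric matrix of contact counts at fixed resolution for one
#' chromosome. `mask` flags bins excluded from balancing and downstream
#' statistics (e.g. unmappable, all-zero rows).
#'
#' @slot chrom chromosome name.
#' @slot resolution bin size in bp.
#' @slot counts symmetric non-negative numeric matrix (bins x bins).
#' @slot mask logical vector, TRUE for excluded bins.
#' @export
setClass("ContactMatrix",
  representation(chrom = "character", resolution = "numeric",
                 counts = "matrix", mask = "logical"))

setValidity("ContactMatrix", function(object) {
  msg <- character()
  m <- object@counts
  if (nrow(m) != ncol(m)) msg <- c(msg, "counts must be square")
  if (length(object@mask) != nrow(m)) msg <- c(msg, "mask length must equal bin count")
  if (any(m < 0, na.rm = TRUE)) msg <- c(msg, "counts must be non-negative")
  if (nrow(m) && max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
    msg <- c(msg, "counts must be symmetric")
  if (length(object@resolution) != 1L || object@resolution < 1)
    msg <- c(msg, "resolution must be a single value >= 1")
  if (length(msg)) msg else TRUE
})

#' AggregationProfile: offset-binned values around anchor points
#'
#' @slot offsets integer vector of bin left edges in bp relative to the
#'   anchor position (bin k covers offsets `[k*bin, (k+1)*bin)`).
#' @slot values numeric vector, one normalized value per bin.
#' @slot nAnchors number of anchors that contributed.
#' @slot mode "peak-fraction" or "signal".
#' @slot binWidth bin width in bp.
#' @export
setClass("AggregationProfile",
  representation(offsets = "integer", values = "numeric",
                 nAnchors = "integer", mode = "character",
                 binWidth = "integer"))

setValidity("AggregationProfile", function(object) {
  msg <- character()
  if (length(object@offsets) != length(object@values))
    msg <- c(msg, "offsets and values differ in length")
  if (length(object@offsets) > 1L &&
      !all(diff(object@offsets) == object@binWidth))
    msg <- c(msg, "bins must be contiguous and uniform")
  if (object@mode == "peak-fraction" && any(object@values < -1e-12, na.rm = TRUE))
    msg <- c(msg, "peak-fraction values must be >= 0")
  if (!object@mode %in% c("peak-fraction", "signal"))
    msg <- c(msg, "mode must be 'peak-fraction' or 'signal'")
  if (length(msg)) msg else TRUE
})

setClassUnion("SignalTrackOrNULL", c("SignalTrack", "NULL"))

#' SyntheticWorld: a self-contained synthetic genome with planted truth
#'
#' Holds a genome layout, compartment segmentation, peak sets, homologous
#' repeat pairs, SV sets per mechanism, TAD boundary / loop anchor points,
#' signal tracks, contact matrices, and the planted-truth record. The truth
#' record is carried for evaluation only; no analysis stage reads it.
#'
#' @slot layout a [GenomeLayout-class].
#' @slot compartments GRanges with metadata column `label`.
#' @slot peaks named list of GRanges (dnase, tfbs, spontDSB, meioticDSB).
#' @slot repeatPairs data.frame of homologous pair coordinates.
#' @slot repeatSeqs character vector of pair origin sequences (may be empty).
#' @slot svs GRanges with metadata columns `mechanism`, `allele_frequency`,
#'   `micro_homology_bp`, `micro_insertion_bp`.
#' @slot tadBoundaries data.frame (chrom, pos).
#' @slot loopAnchors data.frame (chrom, pos).
#' @slot rtTrack,nucTrack [SignalTrack-class] or NULL.
#' @slot contacts named list of [ContactMatrix-class] (may be empty).
#' @slot truth list: planted parameters and provenance.
#' @slot config the generating configuration list.
#' @export
setClass("SyntheticWorld",
  representation(layout = "GenomeLayout", compartments = "GRanges",
                 peaks = "list", repeatPairs = "data.frame",
                 repeatSeqs = "character", svs = "GRanges",
                 tadBoundaries = "data.frame", loopAnchors = "data.frame",
                 rtTrack = "SignalTrackOrNULL", nucTrack = "SignalTrackOrNULL",
                 contacts = "list", truth = "list", config = "list"))
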