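#' Construct a GenomeLayout
#'
#' @param chroms character vector of chromosome names (ordered).
#' @param lengths numeric vector of chromosome lengths in bp; may be named,
#'   in which case `chroms` defaults to its names.
#' @return a [GenomeLayout-class] object.
#' @examples
#' gl <- GenomeLayout(c(A = 100, B = 50))
#' totalLength(gl)
#' @export
GenomeLayout <- function(lengths, chroms = names(lengths)) {
  if (is.null(chroms)) stop("chromosome names required")
  new("GenomeLayout", chroms = as.character(chroms),
      lengths = unname(as.numeric(lengths)))
}

#' @rdname GenomeLayout
#' @param object,layout a GenomeLayout.
#' @export
setGeneric("chromNames", function(object) standardGeneric("chromNames"))

#' @rdname GenomeLayout
#' @export
setMethod("chromNames", "GenomeLayout", function(object) object@chroms)

#' @rdname GenomeLayout
#' @export
setGeneric("chromLengths", function(object) standardGeneric("chromLengths"))

#' @rdname GenomeLayout
#' @export
setMethod("chromLengths", "GenomeLayout", function(object)
  setNames(object@lengths, object@chroms))

#' @rdname GenomeLayout
#' @export
setGeneric("chromOffsets", function(object) standardGeneric("chromOffsets"))

#' @rdname GenomeLayout
#' @export
setMethod("chromOffsets", "GenomeLayout", function(object)
  setNames(cumsum(c(0, object@lengths[-length(object@lengths)])), object@chroms))

#' @rdname GenomeLayout
#' @export
setGeneric("totalLength", function(object) standardGeneric("totalLength"))

#' @rdname GenomeLayout
#' @export
setMethod("totalLength", "GenomeLayout", function(object) sum(object@lengths))

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout with", length(object@chroms), "chromosomes,",
      format(sum(object@lengths), big.mark = ","), "bp total\n")
  n <- min(6L, length(object@chroms))
  for (i in seq_len(n))
    cat(" ", object@chroms[i], format(object@lengths[i], big.mark = ","), "bp\n")
  if (length(object@chroms) > n) cat("  ...\n")
})

#' Linearized genome coordinates
#'
#' Maps `(chrom, pos)` pairs (1-based positions) to the linear coordinate on
#' the circularized genome, where chromosomes are laid end to end in layout
#' order; `linearInverse()` is its exact inverse. Linear coordinates lie in
#' `[1, totalLength(layout)]`.
#'
#' @param layout a [GenomeLayout-class].
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s) within the chromosome.
#' @return `linearCoordinate`: numeric vector of linear coordinates.
#'   `linearInverse`: data.frame with columns `chrom`, `pos`.
#' @examples
#' gl <- GenomeLayout(c(A = 100, B = 50))
#' linearCoordinate(gl, "B", 10)  # 110
#' linearInverse(gl, 110)
#' @export
linearCoordinate <- function(layout, chrom, pos) {
  stopifnot(is(layout, "GenomeLayout"))
  idx <- match(chrom, layout@chroms)
  if (anyNA(idx))
    stop("unknown chromosome(s): ", paste(unique(chrom[is.na(idx)]), collapse = ", "))
  pos <- as.numeric(pos)
  bad <- pos < 1 | pos > layout@lengths[idx]
  if (any(bad)) stop("position out of range for its chromosome")
  unname(chromOffsets(layout)[idx] + pos)
}

#' @rdname linearCoordinate
#' @param linpos linear coordinate(s) in `[1, totalLength(layout)]`.
#' @export
linearInverse <- function(layout, linpos) {
  stopifnot(is(layout, "GenomeLayout"))
  L <- totalLength(layout)
  linpos <- as.numeric(linpos)
  if (any(linpos < 1 | linpos > L)) stop("linear coordinate out of range")
  # chromosome i holds linear coordinates (offset[i], offset[i] + len[i]]
  offs <- chromOffsets(layout)
  idx <- findInterval(linpos, c(unname(offs), L + 1), left.open = TRUE)
  data.frame(chrom = layout@chroms[idx], pos = linpos - unname(offs)[idx],
             stringsAsFactors = FALSE)
}

#' Shift a linear coordinate around the circular genome
#'
#' @param linpos linear coordinate(s) in `[1, L]`.
#' @param offset shift in bp.
#' @param L total genome length.
#' @return shifted linear coordinate(s) in `[1, L]`.
#' @keywords internal
shiftCircular <- function(linpos, offset, L) {
  ((linpos - 1 + offset) %% L) + 1
}
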