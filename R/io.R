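#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps pintersect reduce mcols mcols<-
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits DataFrame
NULL

.layoutCheckChroms <- function(gr_chrom, layout) {
  if (is.null(layout)) return(invisible(NULL))
  unknown <- setdiff(unique(as.character(gr_chrom)), chromNames(layout))
  if (length(unknown))
    stop("unknown chromosome(s) for supplied layout: ",
         paste(unknown, collapse = ", "))
}

#' Read a BED file of intervals
#'
#' Reads BED3+ (tab-separated, 0-based half-open) into a `GRanges`
#' (1-based closed, the internal convention). Optional columns 4 and 5 are
#' kept as `name` and `score`, column 6 as strand. Malformed lines are
#' reported with their line numbers.
#'
#' @param path file path.
#' @param layout optional [GenomeLayout-class]; if given, chromosome names
#'   are validated against it.
#' @param oneBased set TRUE if the file uses 1-based inclusive starts
#'   (non-standard BED); default FALSE.
#' @return `GRanges`.
#' @export
readBed <- function(path, layout = NULL, oneBased = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lnum <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED format error: fewer than 3 columns at line(s) ",
         paste(lnum[nf < 3L], collapse = ", "))
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad))
    stop("BED format error: non-numeric coordinates at line(s) ",
         paste(lnum[bad], collapse = ", "))
  if (oneBased) start0 <- start0 - 1
  empty <- start0 >= end0
  if (any(empty))
    stop("empty or inverted interval(s) (start >= end) at line(s) ",
         paste(lnum[empty], collapse = ", "))
  .layoutCheckChroms(chrom, layout)
  strand <- rep("*", length(chrom))
  if (all(nf >= 6L)) {
    s <- vapply(fields, `[[`, character(1), 6L)
    strand[s %in% c("+", "-")] <- s[s %in% c("+", "-")]
  }
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), strand = strand)
  if (all(nf >= 4L)) mcols(gr)$name <- vapply(fields, `[[`, character(1), 4L)
  if (all(nf >= 5L))
    mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, character(1), 5L)))
  if (!is.null(layout)) {
    len <- chromLengths(layout)[as.character(seqnames(gr))]
    if (any(end(gr) > len)) stop("interval(s) extend past chromosome end")
  }
  gr
}

#' Write intervals as BED
#'
#' Inverse of [readBed()]: writes `GRanges` as BED (0-based half-open).
#' `name`/`score` metadata columns, when present, become columns 4-5 (and
#' strand column 6 when any strand is set).
#' @param gr GRanges.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1, end = end(gr))
  mc <- mcols(gr)
  hasStrand <- any(as.character(strand(gr)) != "*")
  if ("name" %in% colnames(mc) || "score" %in% colnames(mc) || hasStrand) {
    df$name <- if ("name" %in% colnames(mc)) mc$name else "."
    df$score <- if ("score" %in% colnames(mc)) mc$score else 0
  }
  if (hasStrand) {
    s <- as.character(strand(gr)); s[s == "*"] <- "."
    df$strand <- s
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Read / write a two-column chromosome sizes file
#' @param path file path.
#' @return [GenomeLayout-class].
#' @export
readChromSizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  GenomeLayout(setNames(df$length, df$chrom))
}

#' @rdname readChromSizes
#' @param layout a GenomeLayout.
#' @export
writeChromSizes <- function(layout, path) {
  write.table(data.frame(chromNames(layout), unname(chromLengths(layout))),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' The SV mechanism vocabulary
#'
#' Fixed labels for SV mechanistic origin: non-allelic homologous
#' recombination (NAHR), non-homologous end joining (NHEJ), replication-error
#' deletions (NHrepl), mobile element insertions (MEI-Alu, MEI-L1), tandem
#' duplications (TDUP), variable number of tandem repeats (VNTR), deletions
#' with multiple transposable elements (MTE-del), and single retrotransposons
#' detected as deletions (AluL1-del).
#' @return character vector of labels.
#' @export
svMechanisms <- function() {
  c("NAHR", "NHEJ", "NHrepl", "MEI-Alu", "MEI-L1",
    "TDUP", "VNTR", "MTE-del", "AluL1-del")
}

#' Build an SV set
#'
#' Creates the internal SV representation: a `GRanges` whose two breakpoints
#' are the interval start and end, carrying mechanism labels and optional
#' junction annotations.
#'
#' @param gr GRanges of SV intervals.
#' @param mechanism character vector of labels from [svMechanisms()].
#' @param allele_frequency optional numeric in `[0, 1]`.
#' @param micro_homology_bp,micro_insertion_bp optional non-negative integers.
#' @return GRanges with validated metadata columns.
#' @export
makeSVSet <- function(gr, mechanism, allele_frequency = NA_real_,
                      micro_homology_bp = NA_integer_,
                      micro_insertion_bp = NA_integer_) {
  bad <- !mechanism %in% svMechanisms()
  if (any(bad))
    stop("unknown mechanism label(s): ", paste(unique(mechanism[bad]), collapse = ", "))
  af <- rep_len(allele_frequency, length(gr))
  if (any(!is.na(af) & (af < 0 | af > 1)))
    stop("allele_frequency must be in [0, 1]")
  mh <- rep_len(as.integer(micro_homology_bp), length(gr))
  mi <- rep_len(as.integer(micro_insertion_bp), length(gr))
  if (any(!is.na(mh) & mh < 0) || any(!is.na(mi) & mi < 0))
    stop("micro-homology/insertion lengths must be non-negative")
  mcols(gr)$mechanism <- rep_len(mechanism, length(gr))
  mcols(gr)$allele_frequency <- af
  mcols(gr)$micro_homology_bp <- mh
  mcols(gr)$micro_insertion_bp <- mi
  gr
}

#' Read / write the tab-separated SV table
#'
#' Schema (tab-separated, with header): `chrom`, `start`, `end` (0-based
#' half-open unless `oneBased`), `mechanism`, and optional
#' `allele_frequency`, `micro_homology_bp`, `micro_insertion_bp`
#' (`NA` allowed).
#'
#' @inheritParams readBed
#' @return GRanges as from [makeSVSet()].
#' @export
readSVTable <- function(path, layout = NULL, oneBased = FALSE) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "mechanism")
  if (!all(need %in% colnames(df)))
    stop("SV table must have columns: ", paste(need, collapse = ", "))
  start1 <- df$start + ifelse(oneBased, 0, 1)
  if (any(start1 > df$end)) stop("SV table has empty/inverted interval(s)")
  .layoutCheckChroms(df$chrom, layout)
  gr <- GRanges(df$chrom, IRanges(start1, df$end))
  makeSVSet(gr, df$mechanism,
            allele_frequency = if ("allele_frequency" %in% colnames(df))
              df$allele_frequency else NA_real_,
            micro_homology_bp = if ("micro_homology_bp" %in% colnames(df))
              df$micro_homology_bp else NA_integer_,
            micro_insertion_bp = if ("micro_insertion_bp" %in% colnames(df))
              df$micro_insertion_bp else NA_integer_)
}

#' @rdname readSVTable
#' @param svs SV GRanges.
#' @export
writeSVTable <- function(svs, path) {
  mc <- mcols(svs)
  df <- data.frame(chrom = as.character(seqnames(svs)),
                   start = start(svs) - 1, end = end(svs),
                   mechanism = mc$mechanism,
                   allele_frequency = mc$allele_frequency,
                   micro_homology_bp = mc$micro_homology_bp,
                   micro_insertion_bp = mc$micro_insertion_bp)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Construct a SignalTrack
#' @param values named list of numeric vectors (one per chromosome), sampled
#'   on a fixed step grid; `NA` marks missing data.
#' @param step step size in bp.
#' @return [SignalTrack-class].
#' @export
SignalTrack <- function(values, step = 1L) {
  new("SignalTrack", values = values, step = as.integer(step))
}

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack:", length(object@values), "chromosome(s), step",
      object@step, "bp\n")
})

#' Look up per-base track values
#'
#' Returns the track value at each 1-based base position (the value of the
#' step cell containing the base); `NA` outside the track or where data are
#' missing.
#' @param track [SignalTrack-class].
#' @param chrom single chromosome name.
#' @param pos integer vector of base positions.
#' @export
trackValuesAt <- function(track, chrom, pos) {
  v <- track@values[[chrom]]
  if (is.null(v)) return(rep(NA_real_, length(pos)))
  cell <- (as.numeric(pos) - 1) %/% track@step + 1
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 1 & cell <= length(v)
  out[ok] <- v[cell[ok]]
  out
}

#' Read / write a SignalTrack as bedGraph
#'
#' bedGraph intervals are 0-based half-open; on write, runs of equal
#' adjacent cells are merged. On read, intervals must align to the step
#' grid; uncovered cells are `NA`.
#'
#' @param path file path.
#' @param layout [GenomeLayout-class] (sizes the per-chromosome vectors).
#' @param step track step in bp.
#' @return [SignalTrack-class].
#' @export
readBedGraphTrack <- function(path, layout, step = 1L) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "numeric", "numeric", "numeric"))
  .layoutCheckChroms(df$chrom, layout)
  step <- as.integer(step)
  if (any(df$start %% step != 0))
    stop("bedGraph intervals must align to the step grid")
  values <- lapply(chromNames(layout), function(ch) {
    n <- ceiling(chromLengths(layout)[[ch]] / step)
    v <- rep(NA_real_, n)
    d <- df[df$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      c1 <- d$start[i] %/% step + 1
      c2 <- min(n, ceiling(d$end[i] / step))
      v[c1:c2] <- d$value[i]
    }
    v
  })
  names(values) <- chromNames(layout)
  SignalTrack(values, step)
}

#' @rdname readBedGraphTrack
#' @param track [SignalTrack-class].
#' @export
writeBedGraphTrack <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  step <- track@step
  for (ch in names(track@values)) {
    v <- track@values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0, ends[-length(ends)])
    keep <- !is.na(r$values)
    if (!any(keep)) next
    writeLines(paste(ch, starts[keep] * step, ends[keep] * step,
                     format(r$values[keep], digits = 10, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Construct a ContactMatrix
#' @param counts symmetric non-negative matrix.
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @param mask logical vector of excluded bins; by default all-zero rows.
#' @return [ContactMatrix-class].
#' @export
ContactMatrix <- function(counts, chrom, resolution, mask = NULL) {
  if (is.null(mask)) mask <- rowSums(counts) == 0
  new("ContactMatrix", chrom = chrom, resolution = as.numeric(resolution),
      counts = counts, mask = mask)
}

setMethod("show", "ContactMatrix", function(object) {
  cat("ContactMatrix:", object@chrom, "-", nrow(object@counts), "bins at",
      object@resolution, "bp;", sum(object@mask), "masked\n")
})

#' Read / write a sparse-triple contact matrix file
#'
#' Format: header line `# chrom=<name> resolution=<bp> nbins=<n>`, then
#' tab-separated `bin_i  bin_j  count` (1-based bins, upper triangle).
#' @param path file path.
#' @return [ContactMatrix-class].
#' @export
readContactMatrixFile <- function(path) {
  hdr <- readLines(path, n = 1L)
  get <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))[[1]]
    if (length(m) < 2) stop("contact matrix header missing ", key)
    m[2]
  }
  chrom <- get("chrom")
  res <- as.numeric(get("resolution"))
  nb <- as.integer(get("nbins"))
  df <- read.table(path, sep = "\t", header = FALSE, skip = 1L,
                   col.names = c("i", "j", "count"))
  m <- matrix(0, nb, nb)
  m[cbind(df$i, df$j)] <- df$count
  m[cbind(df$j, df$i)] <- df$count
  ContactMatrix(m, chrom, res)
}

#' @rdname readContactMatrixFile
#' @param cm [ContactMatrix-class].
#' @export
writeContactMatrixFile <- function(cm, path) {
  m <- cm@counts
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chrom=%s resolution=%g nbins=%d",
                     cm@chrom, cm@resolution, nrow(m)), con)
  if (nrow(idx))
    writeLines(paste(idx[, 1], idx[, 2],
                     format(m[idx], digits = 10, trim = TRUE), sep = "\t"), con)
  invisible(path)
}
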