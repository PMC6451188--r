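#' Fraction of a point set per compartment bin
#'
#' For bin-level regression: the fraction of points residing in each bin of
#' the segmentation (bins keep their order/identity). Points outside every
#' bin are excluded from numerators but counted in the denominator. Peak
#' sets conventionally enter as interval midpoints; SV sets as both
#' breakpoints ([svBreakpoints()]).
#'
#' @param points data.frame with `chrom`, `pos`.
#' @param bins GRanges of (non-overlapping) bins.
#' @return numeric vector, one fraction per bin.
#' @export
binFractions <- function(points, bins) {
  if (nrow(points) == 0L) stop("empty point set")
  pts <- GRanges(points$chrom, IRanges(points$pos, points$pos))
  hit <- suppressWarnings(findOverlaps(pts, bins, select = "first"))
  counts <- tabulate(hit[!is.na(hit)], nbins = length(bins))
  counts / nrow(points)
}

#' Midpoints of intervals as points
#' @param gr GRanges.
#' @return data.frame with `chrom`, `pos`.
#' @export
intervalMidpoints <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             pos = start(gr) + width(gr) %/% 2L,
             stringsAsFactors = FALSE)
}

#' Ordinary least-squares fit of bin fractions
#'
#' Fits `Y ~ X` by OLS (via [stats::lm()]) for one or more predictors, with
#' R-squared, adjusted R-squared and residuals. Perfectly collinear
#' predictors raise an error naming the dependent columns.
#'
#' @param Y numeric outcome vector (e.g. NAHR bin fractions).
#' @param X numeric vector or matrix of predictors (columns named).
#' @return object of class `svcRegressionFit`: list with `coefficients`,
#'   `r_squared`, `adj_r_squared`, `residuals`, `residual_sd`, `n`, `p`,
#'   and the underlying `lm` fit.
#' @export
fitLinear <- function(Y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  n <- length(Y)
  if (n != nrow(X)) stop("Y and X differ in length")
  if (n <= ncol(X) + 1L) stop("need n > p + 1 observations")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    dep <- qrX$pivot[seq(qrX$rank + 1L, ncol(X) + 1L)]
    dep <- dep[dep > 1L]
    stop("perfectly collinear predictor(s): ",
         paste(colnames(X)[dep - 1L], collapse = ", "))
  }
  df <- data.frame(Y = Y, X)
  fit <- lm(Y ~ ., data = df)
  sm <- suppressWarnings(summary(fit))  # silence the perfect-fit notice
  structure(list(coefficients = stats::coef(fit),
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 residuals = stats::resid(fit),
                 residual_sd = sd(stats::resid(fit)),
                 n = n, p = ncol(X), lm = fit),
            class = "svcRegressionFit")
}

#' @export
print.svcRegressionFit <- function(x, ...) {
  cat("OLS fit:", x$p, "predictor(s),", x$n, "bins\n")
  print(round(x$coefficients, 6))
  cat(sprintf("R^2 = %.4f, adjusted R^2 = %.4f\n",
              x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Bins with discordant predictions
#'
#' Bins where the residual (observed - predicted) deviates from the mean
#' residual by more than `k` residual standard deviations; the sign records
#' whether the bin was under- (`+`) or over- (`-`) predicted relative to
#' the observation.
#' @param fit an `svcRegressionFit`.
#' @param k standard-deviation threshold (default 3).
#' @return data.frame with `bin` (index), `residual`, `sign`.
#' @export
discordantBins <- function(fit, k = 3) {
  r <- fit$residuals
  # residual sd at floating-point noise level counts as a perfect fit
  scale0 <- sd(stats::fitted(fit$lm)) + abs(mean(stats::fitted(fit$lm)))
  if (fit$residual_sd <= 1e-10 * max(scale0, .Machine$double.xmin)) {
    sel <- if (k == 0) seq_along(r) else integer()
  } else {
    dev <- abs(r - mean(r))
    sel <- which(dev > k * fit$residual_sd)
  }
  data.frame(bin = sel, residual = r[sel],
             sign = ifelse(r[sel] >= mean(r), "under-predicted",
                           "over-predicted"))
}
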