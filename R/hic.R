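#' Knight-Ruiz balancing of a symmetric contact matrix
#'
#' Finds a positive scaling vector `x` such that `diag(x) %*% M %*% diag(x)`
#' has all unmasked row sums equal to 1 (within tolerance), using the
#' Knight-Ruiz Newton-type inner-outer iteration with a conjugate-gradient
#' inner solve. Fully-zero rows are masked automatically; additional bins
#' can be masked via the `mask` slot / argument.
#'
#' @param m a [ContactMatrix-class] or symmetric non-negative matrix.
#' @param mask logical vector of bins to exclude (matrix method only;
#'   all-zero rows are always excluded).
#' @param tol convergence tolerance on the L2 norm of the row-sum residual
#'   (default 1e-6).
#' @param maxIter maximum outer iterations before an error (default 100).
#' @return list with `balanced` (full-size matrix, `NA` on masked bins) and
#'   `scaling` (vector, `NA` on masked bins). For a `ContactMatrix` input the
#'   balanced matrix keeps the input's mask.
#' @export
setGeneric("krBalance", function(m, ...) standardGeneric("krBalance"))

#' @rdname krBalance
#' @param ... passed through to the matrix method.
#' @export
setMethod("krBalance", "matrix", function(m, mask = NULL, tol = 1e-6,
                                          maxIter = 100L) {
  n <- nrow(m)
  if (n != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("matrix must be square and symmetric")
  if (any(m < 0)) stop("matrix must be non-negative")
  if (is.null(mask)) mask <- rep(FALSE, n)
  mask <- mask | rowSums(m) == 0
  A <- m[!mask, !mask, drop = FALSE]
  if (!nrow(A)) stop("all bins masked")
  x <- .krNewton(A, tol = tol, maxIter = maxIter)
  scaling <- rep(NA_real_, n)
  scaling[!mask] <- x
  balanced <- matrix(NA_real_, n, n)
  balanced[!mask, !mask] <- A * outer(x, x)
  list(balanced = balanced, scaling = scaling, mask = mask)
})

#' @rdname krBalance
#' @export
setMethod("krBalance", "ContactMatrix", function(m, tol = 1e-6,
                                                 maxIter = 100L) {
  krBalance(m@counts, mask = m@mask, tol = tol, maxIter = maxIter)
})

# Knight-Ruiz (2013) balancing for a symmetric non-negative matrix with
# support; returns x with x * (A x) = 1 within tol (L2).
.krNewton <- function(A, tol = 1e-6, maxIter = 100L,
                      delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9
  etamax <- 0.1
  eta <- etamax
  rt <- tol^2
  v <- x * as.numeric(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1
  rold <- rout
  outer <- 0L
  while (rout > rt) {
    outer <- outer + 1L
    if (outer > maxIter)
      stop("KR balancing did not converge in ", maxIter,
           " iterations; consider masking sparse bins")
    k <- 0L
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.numeric(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k >= 200L) break
    }
    x <- x * y
    v <- x * as.numeric(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold
    rold <- rout
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), 0.5 * tol / sqrt(rout))
  }
  x
}

#' Observed/expected transform of a balanced matrix
#'
#' Expected value at bin distance `d` is the mean of balanced entries over
#' all unmasked pairs at that distance; each entry is divided by the
#' expected value at its distance. Distances with no unmasked pairs yield
#' `NA`.
#'
#' @param balanced full-size balanced matrix (`NA` on masked bins), as
#'   returned by [krBalance()].
#' @return list with `oe` (obs/exp matrix), `expected` (per-distance means,
#'   index `d + 1`), and `nPairs` (unmasked pair count per distance).
#' @export
obsExp <- function(balanced) {
  n <- nrow(balanced)
  expected <- rep(NA_real_, n)
  nPairs <- integer(n)
  oe <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    idx <- cbind(i, i + d)
    vals <- balanced[idx]
    ok <- !is.na(vals)
    nPairs[d + 1L] <- sum(ok)
    if (any(ok)) {
      expected[d + 1L] <- mean(vals[ok])
      if (expected[d + 1L] > 0) {
        r <- vals / expected[d + 1L]
        oe[idx] <- r
        oe[idx[, c(2, 1), drop = FALSE]] <- r
      }
    }
  }
  list(oe = oe, expected = expected, nPairs = nPairs)
}

# Compartment label of each contact-matrix bin (by bin-midpoint lookup).
.binLabels <- function(nBins, chrom, resolution, track) {
  mids <- (seq_len(nBins) - 0.5) * resolution
  assignLabel(data.frame(chrom = chrom, pos = floor(mids) + 1), track)
}

#' Compartment- and distance-specific average interaction
#'
#' For each obs/exp matrix, every interaction whose two bins lie in the same
#' compartment is assigned that compartment; per (compartment, distance) the
#' mean obs/exp value is accumulated over all chromosomes. The pooled
#' per-distance mean over all same-compartment pairs is kept as the
#' fallback used for SVs whose two ends lie in different compartments.
#'
#' @param oeList named list (by chromosome) of lists as returned by
#'   [obsExp()], or of plain obs/exp matrices.
#' @param track compartment segmentation GRanges with `label`.
#' @param resolution bin size in bp.
#' @return object of class `svcCompartmentProfile`: list with `value`
#'   (labels x distances matrix of means), `pooled` (per-distance vector),
#'   `n` (pair counts), `resolution`.
#' @export
compartmentDistanceProfile <- function(oeList, track, resolution) {
  lev <- sort(unique(as.character(mcols(track)$label)))
  maxBins <- max(vapply(oeList, function(x)
    nrow(if (is.list(x)) x$oe else x), integer(1)))
  sums <- matrix(0, length(lev) + 1L, maxBins,
                 dimnames = list(c(lev, ".pooled"), NULL))
  cnts <- matrix(0, length(lev) + 1L, maxBins)
  for (ch in names(oeList)) {
    oe <- if (is.list(oeList[[ch]])) oeList[[ch]]$oe else oeList[[ch]]
    nb <- nrow(oe)
    lab <- .binLabels(nb, ch, resolution, track)
    code <- match(lab, lev)
    for (d in 0:(nb - 1L)) {
      i <- seq_len(nb - d)
      same <- !is.na(code[i]) & code[i] == code[i + d]
      if (!any(same)) next
      vals <- oe[cbind(i[same], i[same] + d)]
      ok <- !is.na(vals)
      if (!any(ok)) next
      cc <- code[i][same][ok]
      tt <- tapply(vals[ok], cc, sum)
      nn <- tapply(ok[ok], cc, sum)
      rows <- as.integer(names(tt))
      sums[rows, d + 1L] <- sums[rows, d + 1L] + as.numeric(tt)
      cnts[rows, d + 1L] <- cnts[rows, d + 1L] + as.numeric(nn)
      sums[length(lev) + 1L, d + 1L] <- sums[length(lev) + 1L, d + 1L] + sum(vals[ok])
      cnts[length(lev) + 1L, d + 1L] <- cnts[length(lev) + 1L, d + 1L] + sum(ok)
    }
  }
  value <- sums / ifelse(cnts > 0, cnts, NA)
  structure(list(value = value[seq_along(lev), , drop = FALSE],
                 pooled = value[length(lev) + 1L, ],
                 n = cnts, labels = lev, resolution = resolution),
            class = "svcCompartmentProfile")
}

#' Normalized Hi-C interaction of SV breakpoint pairs
#'
#' Each SV longer than `minLength` has its two ends assigned to separate
#' bins; the obs/exp value of that bin pair is divided by the compartment-
#' and distance-specific average interaction (the pooled same-compartment
#' average at that distance when the two ends lie in different
#' compartments). SVs are excluded, with a reason, when too short, when both
#' ends share a bin, when either bin is masked, or when the expected value
#' at that distance is unstable (fewer than `minPairs` unmasked pairs).
#'
#' @param svs SV GRanges (intra-chromosomal by construction).
#' @param oeList named list by chromosome of [obsExp()] results.
#' @param profile result of [compartmentDistanceProfile()].
#' @param track compartment segmentation GRanges.
#' @param minLength minimum SV length in bp (default 5000; SVs must be
#'   strictly longer).
#' @param minPairs minimum unmasked pair count per distance (default 10).
#' @return data.frame with one row per SV: bins, distance (bp), `obsexp`,
#'   `compartment` (label or `"mixed"`), normalized `value`, `mechanism`,
#'   and `excluded` (NA or the reason).
#' @export
svInteractions <- function(svs, oeList, profile, track,
                           minLength = 5000L, minPairs = 10L) {
  res <- profile$resolution
  ch <- as.character(seqnames(svs))
  n <- length(svs)
  out <- data.frame(mechanism = as.character(mcols(svs)$mechanism),
                    chrom = ch, bin_i = NA_integer_, bin_j = NA_integer_,
                    distance = NA_real_, obsexp = NA_real_,
                    compartment = NA_character_, value = NA_real_,
                    excluded = NA_character_, stringsAsFactors = FALSE)
  labsCache <- list()
  for (k in seq_len(n)) {
    if (is.null(oeList[[ch[k]]])) { out$excluded[k] <- "no matrix"; next }
    len <- end(svs)[k] - start(svs)[k]
    if (len <= minLength) { out$excluded[k] <- "too short"; next }
    oeDat <- oeList[[ch[k]]]
    oe <- if (is.list(oeDat)) oeDat$oe else oeDat
    nPairs <- if (is.list(oeDat)) oeDat$nPairs else NULL
    i <- (start(svs)[k] - 1) %/% res + 1
    j <- (end(svs)[k] - 1) %/% res + 1
    if (i == j) { out$excluded[k] <- "same bin"; next }
    if (j > nrow(oe)) { out$excluded[k] <- "outside matrix"; next }
    out$bin_i[k] <- i; out$bin_j[k] <- j
    d <- j - i
    out$distance[k] <- d * res
    v <- oe[i, j]
    if (is.na(v)) { out$excluded[k] <- "masked bin"; next }
    if (!is.null(nPairs) && nPairs[d + 1L] < minPairs) {
      out$excluded[k] <- "unstable distance"; next
    }
    out$obsexp[k] <- v
    if (is.null(labsCache[[ch[k]]]))
      labsCache[[ch[k]]] <- .binLabels(nrow(oe), ch[k], res, track)
    labs <- labsCache[[ch[k]]]
    lab <- if (!is.na(labs[i]) && labs[i] == labs[j] &&
               labs[i] %in% profile$labels) labs[i] else "mixed"
    out$compartment[k] <- lab
    denom <- if (lab == "mixed") profile$pooled[d + 1L]
             else profile$value[lab, d + 1L]
    if (is.na(denom) || denom <= 0) {
      denom <- profile$pooled[d + 1L]
      if (is.na(denom) || denom <= 0) {
        out$excluded[k] <- "no compartment average"; next
      }
    }
    out$value[k] <- v / denom
  }
  out
}
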