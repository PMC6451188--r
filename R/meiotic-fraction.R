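#' Closed-form estimate of the meiotic fraction of NAHR deletions
#'
#' The aggregated meiotic-DSB signal at NAHR breakpoints is modeled as a
#' mixture of two components: a fraction `x` of deletions that sit at
#' meiotic DSBs (contributing a unit signal, attenuated by the experimental
#' capture fraction `f_m`) and a fraction `1 - x` of HDR-related deletions
#' contributing only background `b` (attenuated by the spontaneous-capture
#' fraction `f_s`):
#' \deqn{f_m x + b (1 - x) f_s = S_{obs}}
#' giving the closed form
#' \deqn{x = (S_{obs} - b f_s) / (f_m - b f_s).}
#' With the observed values `S_obs = 0.08` and `b = 0.04`, `x` only weakly
#' depends on the capture fractions.
#'
#' @param S_obs observed aggregated signal at NAHR breakpoints
#'   (default 0.08).
#' @param b background signal from non-NAHR repair deletions
#'   (default 0.04).
#' @param f_m,f_s capture fractions in `(0, 1]` of the meiotic and
#'   spontaneous DSB experiments.
#' @return estimate `x` as a plain number. Values outside `[0, 1]` are
#'   returned as-is with a model-violation warning.
#' @examples
#' meioticFraction(f_m = 1, f_s = 1)       # 0.0417
#' meioticFraction(f_m = 0.5, f_s = 0.5)   # 0.125
#' @export
meioticFraction <- function(S_obs = 0.08, b = 0.04, f_m, f_s) {
  if (any(f_m <= 0 | f_m > 1) || any(f_s <= 0 | f_s > 1))
    stop("capture fractions must be in (0, 1]")
  denom <- f_m - b * f_s
  if (any(denom <= 0))
    stop("denominator f_m - b*f_s must be positive")
  x <- (S_obs - b * f_s) / denom
  if (any(x < 0 | x > 1))
    warning("estimate outside [0, 1]: the mixture model is violated")
  x
}

#' Range of the meiotic-fraction estimate over a capture-fraction box
#'
#' Evaluates [meioticFraction()] on a dense grid over the `f_m` x `f_s`
#' box and reports the extrema. `x` is monotone decreasing in `f_m` and
#' monotone in `f_s` for fixed `f_m`, so the extrema are attained at box
#' corners; the grid evaluation is kept as the defining computation.
#'
#' @inheritParams meioticFraction
#' @param f_m_range,f_s_range bounds within `(0, 1]` (default `[0.5, 1]`).
#' @param gridSize grid points per axis (default 101).
#' @return list with `x_min`, `x_max`, and the evaluation `grid`
#'   (data.frame `f_m`, `f_s`, `x`).
#' @export
meioticFractionRange <- function(S_obs = 0.08, b = 0.04,
                                 f_m_range = c(0.5, 1),
                                 f_s_range = c(0.5, 1),
                                 gridSize = 101L) {
  fm <- seq(f_m_range[1], f_m_range[2], length.out = gridSize)
  fs <- seq(f_s_range[1], f_s_range[2], length.out = gridSize)
  g <- expand.grid(f_m = fm, f_s = fs)
  g$x <- suppressWarnings(meioticFraction(S_obs, b, g$f_m, g$f_s))
  list(x_min = min(g$x), x_max = max(g$x), grid = g)
}

#' Estimate the meiotic fraction from aggregation profiles
#'
#' Pipeline form of [meioticFraction()]: `S_obs` is the offset-zero value
#' of the meiotic-DSB aggregation profile around NAHR breakpoints (mean of
#' the two bins flanking offset 0), `b` the mean offset-zero value across
#' the control profiles (typically NHEJ and NHrepl breakpoints).
#'
#' @param nahrProfile [AggregationProfile-class] of meiotic-DSB signal
#'   around NAHR breakpoints.
#' @param controlProfiles list of control [AggregationProfile-class]s.
#' @param f_m,f_s capture fractions.
#' @return list with `S_obs`, `b`, `f_m`, `f_s`, `x`.
#' @export
estimateFromProfiles <- function(nahrProfile, controlProfiles, f_m, f_s) {
  S_obs <- offsetZeroValue(nahrProfile)
  b <- mean(vapply(controlProfiles, offsetZeroValue, numeric(1)))
  x <- meioticFraction(S_obs = S_obs, b = b, f_m = f_m, f_s = f_s)
  list(S_obs = S_obs, b = b, f_m = f_m, f_s = f_s, x = x)
}
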