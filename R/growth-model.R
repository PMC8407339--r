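#' Logistic-with-lag population model
#'
#' Deterministic mean trajectory used by the simulator: the population stays
#' at `n0` until `lag`, then follows logistic growth with intrinsic rate
#' `r = ln(2) / gt` towards `capacity`,
#' `N(t) = capacity * n0 * e^{r(t - lag)} / (capacity + n0 * (e^{r(t - lag)} - 1))`.
#' A non-growing colony is encoded by `gt = Inf` and stays flat at `n0`.
#'
#' @param t Numeric vector of times, hours.
#' @param gt Generation time, hours per doubling (`Inf` for a non-grower).
#' @param lag Growth lag, hours (>= 0).
#' @param n0 Initial population proxy (> 0).
#' @param capacity Carrying capacity (> `n0`).
#' @return Numeric vector of population-size values at `t`.
#' @examples
#' growth_model(0:10, gt = 2, lag = 1, n0 = 0.05, capacity = 50)
#' @export
growth_model <- function(t, gt, lag = 0, n0 = 0.05, capacity = 50) {
  if (is.infinite(gt)) return(rep(n0, length(t)))
  stopifnot_msg(is.finite(gt) && gt > 0,
                "`gt` must be positive or Inf (parameter error)")
  stopifnot_msg(lag >= 0, "`lag` must be >= 0")
  stopifnot_msg(n0 > 0 && capacity > n0, "need capacity > n0 > 0")
  r <- log(2) / gt
  e <- exp(r * pmax(t - lag, 0))
  capacity * n0 * e / (capacity + n0 * (e - 1))
}

#' Simulate one colony growth curve
#'
#' Samples the logistic-with-lag model on a regular time grid and applies
#' multiplicative log-normal measurement noise per time point
#' (`value = N(t) * 2^eps`, `eps ~ N(0, noise_sd)` in log2 units).
#'
#' @inheritParams growth_model
#' @param sampling_interval Time between samples, hours.
#' @param horizon Total duration, hours; the curve has
#'   `floor(horizon / sampling_interval) + 1` points starting at `t = 0`.
#' @param noise_sd Sd of the per-point log2 noise; 0 gives the exact model.
#' @param seed Optional integer seed for the noise draw.
#' @return A tibble with columns `time_h` and `value`.
#' @examples
#' simulate_curve(gt = 2, lag = 4, noise_sd = 0.01, seed = 1)
#' @export
simulate_curve <- function(gt, lag = 0, n0 = 0.05, capacity = 50,
                           sampling_interval = 1 / 3, horizon = 96,
                           noise_sd = 0, seed = NULL) {
  stopifnot_msg(sampling_interval > 0 && horizon > sampling_interval,
                "`horizon` must exceed `sampling_interval` > 0")
  t <- seq(0, by = sampling_interval,
           length.out = floor(horizon / sampling_interval) + 1)
  mu <- growth_model(t, gt = gt, lag = lag, n0 = n0, capacity = capacity)
  if (noise_sd > 0) {
    eps <- if (is.null(seed)) rnorm(length(t), 0, noise_sd) else
      with_seed(seed, rnorm(length(t), 0, noise_sd))
    mu <- mu * 2^eps
  }
  tibble::tibble(time_h = t, value = mu)
}
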