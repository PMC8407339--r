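## colony identity columns recognised in long curve tables
colony_keys <- function(df) {
  intersect(c("plate_id", "row", "col", "run", "condition",
              "strain_id", "is_control", "replicate_index"), names(df))
}

#' Smooth growth curves
#'
#' Median filter followed by a short moving average, applied per colony.
#' Both passes shrink their window at the curve ends, so the time grid is
#' unchanged; a constant curve passes through untouched and single-point
#' spikes shorter than half the median window are removed.
#'
#' @param curves Long tibble with columns `time_h`, `value` and any of the
#'   colony key columns (`plate_id`, `row`, `col`, `run`, `condition`,
#'   `strain_id`, `replicate_index`).
#' @param median_window Odd width (>= 3) of the median filter.
#' @param ma_window Odd width of the moving-average pass.
#' @return The input tibble with `value` replaced by its smoothed version.
#' @examples
#' crv <- simulate_curve(gt = 2, lag = 4, noise_sd = 0.05, seed = 1)
#' sm <- smooth_curve(crv)
#' @export
smooth_curve <- function(curves, median_window = 5, ma_window = 3) {
  check_window <- function(w, name) {
    stopifnot_msg(w >= 3 && w %% 2 == 1,
                  sprintf("`%s` must be an odd integer >= 3", name))
  }
  check_window(median_window, "median_window")
  check_window(ma_window, "ma_window")
  per_colony(curves, function(d) {
    stopifnot_msg(nrow(d) > median_window,
                  "curve too short to smooth (extraction error)")
    v <- shrink_filter(d$value, median_window, median)
    d$value <- shrink_filter(v, ma_window, mean)
    d
  })
}

## apply fun over a centred window, shrinking symmetrically at the ends
shrink_filter <- function(v, window, fun) {
  n <- length(v)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1L, n - i)
    fun(v[(i - k):(i + k)])
  }, numeric(1))
}

per_colony <- function(curves, f) {
  keys <- colony_keys(curves)
  if (length(keys) == 0) return(f(dplyr::arrange(curves, .data$time_h)))
  curves |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::group_modify(function(d, g) f(d)) |>
    dplyr::ungroup()
}

#' Calibrate curve values through a monotone map
#'
#' Maps the raw population proxy through a calibration table or function
#' (e.g. pixel intensity to OD600). The default is the identity map. Table
#' calibration interpolates linearly between the supplied points and holds
#' the end values outside the table range.
#'
#' @inheritParams smooth_curve
#' @param calibration `NULL` (identity), a function, or a data frame with
#'   columns `raw` and `od`, strictly increasing in both.
#' @return The input tibble with calibrated `value`.
#' @export
calibrate_curve <- function(curves, calibration = NULL) {
  if (is.null(calibration)) return(curves)
  if (is.function(calibration)) {
    curves$value <- calibration(curves$value)
    return(curves)
  }
  stopifnot_msg(all(c("raw", "od") %in% names(calibration)),
                "calibration table needs `raw` and `od` columns")
  ord <- order(calibration$raw)
  raw <- calibration$raw[ord]; od <- calibration$od[ord]
  stopifnot_msg(all(diff(raw) > 0) && all(diff(od) > 0),
                "calibration must be strictly increasing (calibration error)")
  curves$value <- stats::approx(raw, od, xout = curves$value, rule = 2)$y
  curves
}

#' Extract generation time, lag and yield from growth curves
#'
#' The maximal specific growth rate is estimated as the largest least-squares
#' slope of `log2(value)` over a sliding window of `slope_window` points;
#' generation time is its reciprocal (hours per doubling). Lag is where the
#' tangent line through the max-slope window falls back to the initial
#' `log2` level, clipped to be non-negative. Yield is `max(value) - value[1]`.
#' A colony is scored a grower when its total fold change reaches
#' `nongrower_fold` and the generation time does not exceed `gt_cap` (48 h by
#' default: colonies doubling slower than that are treated as completely
#' inhibited). Non-growers carry `NA` generation time and lag.
#'
#' @inheritParams smooth_curve
#' @param slope_window Points per regression window (>= 3).
#' @param nongrower_fold Minimum `max(value)/value[1]` for a grower.
#' @param gt_cap Generation times above this (hours) are treated as
#'   non-growth.
#' @return One row per colony: the colony key columns plus `gt_h`, `lag_h`,
#'   `yield`, `grower`, `window_start`, `fit_r2`, `n_points`.
#' @examples
#' crv <- simulate_curve(gt = 3, lag = 5)
#' extract_features(crv)
#' @export
extract_features <- function(curves, slope_window = 5,
                             nongrower_fold = 2, gt_cap = 48) {
  stopifnot_msg(slope_window >= 3, "`slope_window` must be >= 3")
  keys <- colony_keys(curves)
  if (length(keys) == 0) {
    return(extract_one(dplyr::arrange(curves, .data$time_h),
                       slope_window, nongrower_fold, gt_cap))
  }
  curves |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::group_modify(function(d, g)
      extract_one(d, slope_window, nongrower_fold, gt_cap)) |>
    dplyr::ungroup()
}

extract_one <- function(d, slope_window, nongrower_fold, gt_cap) {
  n <- nrow(d)
  stopifnot_msg(n >= 8, "need >= 8 points per curve (extraction error)")
  stopifnot_msg(slope_window < n, "`slope_window` must be < curve length")
  stopifnot_msg(all(d$value > 0),
                "non-positive curve values (extraction error)")
  t <- d$time_h; y <- log2(d$value)
  sl <- window_slopes(t, y, slope_window)
  i <- which.max(sl$slope)
  slope_max <- sl$slope[i]
  yield <- max(max(d$value) - d$value[1], 0)
  fold <- max(d$value) / d$value[1]

  if (!is.finite(slope_max) || slope_max <= 0) {
    return(tibble::tibble(gt_h = NA_real_, lag_h = NA_real_, yield = yield,
                          grower = FALSE, window_start = NA_integer_,
                          fit_r2 = NA_real_, n_points = n))
  }
  gt <- 1 / slope_max
  lag <- (y[1] - sl$intercept[i]) / slope_max
  lag <- min(max(lag, 0), max(t))
  grower <- fold >= nongrower_fold && gt <= gt_cap
  tibble::tibble(gt_h = ifelse(grower, gt, NA_real_),
                 lag_h = ifelse(grower, lag, NA_real_),
                 yield = yield, grower = grower,
                 window_start = as.integer(i), fit_r2 = sl$r2[i],
                 n_points = n)
}

## least-squares slope/intercept/R^2 of y ~ t over every length-w window
window_slopes <- function(t, y, w) {
  n <- length(t)
  m <- n - w + 1L
  cs <- function(z) {
    c0 <- cumsum(z)
    c0[w:n] - c(0, c0)[w:n - w + 1L]
  }
  St <- cs(t); Sy <- cs(y); Stt <- cs(t * t); Sty <- cs(t * y); Syy <- cs(y * y)
  den <- w * Stt - St^2
  slope <- (w * Sty - St * Sy) / den
  intercept <- (Sy - slope * St) / w
  ssy <- Syy - Sy^2 / w
  r2 <- pmin(ifelse(ssy > 0, slope^2 * den / w / ssy, 1), 1)
  list(slope = slope, intercept = intercept, r2 = r2, start = seq_len(m))
}
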