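#' Build the IQR-restricted null reference
#'
#' Most strains in a dense CRISPRi screen behave like the control, so LPI
#' differences inside the interquartile range of the complete data set are
#' treated as chance variation. The null reference keeps every LPI value `v`
#' with `q1 <= v <= q3`, where the quartiles use the linear-interpolation
#' convention (R's default, type 7).
#'
#' @param lpi Numeric vector of per-replicate LPI values (the complete data
#'   set); non-finite entries are dropped.
#' @return A list of class `"lpi_null"` with `q1`, `q3`, `null_sample`,
#'   `null_mean`, `n_total`.
#' @examples
#' build_null(c(1, 2, 3, 4, 5, 6, 7, 8))   # q1 = 2.75, q3 = 6.25
#' @export
build_null <- function(lpi) {
  v <- lpi[is.finite(lpi)]
  stopifnot_msg(length(v) >= 4, "need >= 4 finite LPI values for the null")
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  keep <- v[v >= q[1] & v <= q[2]]
  structure(list(q1 = q[1], q3 = q[2], null_sample = keep,
                 null_mean = mean(keep), n_total = length(v)),
            class = "lpi_null")
}

#' @export
print.lpi_null <- function(x, ...) {
  cat(sprintf("<lpi_null> IQR [%.4g, %.4g], %d of %d values, mean %.4g\n",
              x$q1, x$q3, length(x$null_sample), x$n_total, x$null_mean))
  invisible(x)
}

#' Welch's two-sample two-sided t test against the null reference
#'
#' Compares a strain's LPI replicates with the IQR-restricted null sample
#' using the unequal-variance t statistic and Welch-Satterthwaite degrees of
#' freedom. The alternative `mode = "one-sample"` tests the strain mean
#' against the null mean using only the strain's own variance (the ambiguity
#' between the two readings of "difference from the mean of the IQR data
#' set" is exposed here; two-sample is the default).
#'
#' @param x Numeric vector of the strain's LPI replicates (3-6 typically).
#' @param null An `"lpi_null"` object from [build_null()].
#' @param mode `"two-sample"` (Welch) or `"one-sample"`.
#' @return A list `t_stat`, `df`, `p_raw`, `untestable`. Strains with fewer
#'   than 2 finite replicates are flagged untestable (`NA` statistics), not
#'   an error. Two zero-variance samples give `p = 1` when the means agree
#'   and `p = 0` otherwise.
#' @export
welch_test <- function(x, null, mode = c("two-sample", "one-sample")) {
  mode <- match.arg(mode)
  x <- x[is.finite(x)]
  if (length(x) < 2) {
    return(list(t_stat = NA_real_, df = NA_real_, p_raw = NA_real_,
                untestable = TRUE))
  }
  y <- null$null_sample
  mx <- mean(x); vx <- var(x); nx <- length(x)
  if (mode == "two-sample") {
    w <- welch_stats(mx, vx, nx, mean(y), var(y), length(y))
    return(list(t_stat = w$t, df = w$df, p_raw = w$p, untestable = FALSE))
  } else {
    if (vx == 0) {
      p <- if (mx == null$null_mean) 1 else 0
      return(list(t_stat = if (p == 1) 0 else sign(mx - null$null_mean) * Inf,
                  df = NA_real_, p_raw = p, untestable = FALSE))
    }
    t <- (mx - null$null_mean) / sqrt(vx / nx)
    df <- nx - 1
  }
  list(t_stat = t, df = df, p_raw = 2 * pt(-abs(t), df), untestable = FALSE)
}

## vectorized Welch statistic; degenerate zero-variance pairs give p = 1
## when the means agree and p = 0 otherwise
welch_stats <- function(mx, vx, nx, my, vy, ny) {
  se2 <- vx / nx + vy / ny
  t <- ifelse(se2 > 0, (mx - my) / sqrt(se2),
              ifelse(mx == my, 0, sign(mx - my) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * pt(-abs(t), df), ifelse(mx == my, 1, 0))
  list(t = t, df = df, p = p)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up adjustment: sort the m p values, compute `m * p / rank`,
#' enforce monotonicity from the largest rank down, cap at 1, and return in
#' the input order. `NA` entries (untestable strains) are excluded from `m`
#' and returned as `NA`.
#'
#' @param p Numeric vector of p values in `[0, 1]` (NAs allowed).
#' @return Adjusted p values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))   # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  stopifnot_msg(all(p[ok] >= 0 & p[ok] <= 1),
                "p values must lie in [0, 1] (validation error)")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(out)
  o <- order(pv)
  adj <- pmin(1, cummin((m / m:1) * pv[o][m:1])[m:1])
  ## assignment into a subset of a subset needs the explicit two-step form
  tmp <- out[ok]; tmp[o] <- adj; out[ok] <- tmp
  out
}

#' Control-strain effect-size envelope
#'
#' The interval between the smallest and largest of the per-control-strain
#' mean LPIs. Strains must clear this envelope (below its minimum for
#' tolerant, above its maximum for sensitive) in addition to the FDR
#' threshold, so that effects smaller than what neutral guide RNAs show are
#' never called.
#'
#' @param control_means Numeric vector of mean LPI per control strain
#'   (one entry per strain, not per replicate); at least 2.
#' @return A list of class `"control_envelope"` with `t_tolerant` (min) and
#'   `t_sensitive` (max).
#' @examples
#' control_envelope(c(-0.01, 0.02, 0.00))
#' @export
control_envelope <- function(control_means) {
  v <- control_means[is.finite(control_means)]
  stopifnot_msg(length(v) >= 2,
                "need >= 2 control strain means for the envelope")
  structure(list(t_tolerant = min(v), t_sensitive = max(v)),
            class = "control_envelope")
}

#' @export
print.control_envelope <- function(x, ...) {
  cat(sprintf("<control_envelope> tolerant < %.4g, sensitive > %.4g\n",
              x$t_tolerant, x$t_sensitive))
  invisible(x)
}

#' Classify one strain
#'
#' Pure decision rule combining the effect-size envelope, the FDR threshold
#' and the non-grower rescue: strains dead in basal medium are excluded
#' (`basal_dead`); strains that grew in basal medium but whose stress
#' replicates were all non-growers are `nongrower_sensitive` without any
#' statistics; otherwise `sensitive` needs `mean_lpi > t_sensitive` and
#' `p_adj <= alpha`, `tolerant` needs `mean_lpi < t_tolerant` and
#' `p_adj <= alpha`, and everything else is `unchanged`.
#'
#' @param mean_lpi Strain mean LPI (may be `NA` for non-growers).
#' @param p_adj BH-adjusted p value (may be `NA`).
#' @param envelope A [control_envelope()] object.
#' @param basal_dead Did the strain fail to grow in basal medium?
#' @param stress_dead Did every basal-growing replicate fail under stress?
#' @param alpha FDR threshold (default 0.1).
#' @return One of `"tolerant"`, `"sensitive"`, `"unchanged"`,
#'   `"nongrower_sensitive"`, `"basal_dead"`.
#' @export
classify_strain <- function(mean_lpi, p_adj, envelope,
                            basal_dead = FALSE, stress_dead = FALSE,
                            alpha = 0.1) {
  stopifnot_msg(alpha > 0 && alpha < 1, "`alpha` must be in (0, 1)")
  if (basal_dead && stress_dead) {
    rlang::abort("contradictory flags: basal_dead strain with stress data",
                 class = "colonyscreen_error")
  }
  if (basal_dead) return("basal_dead")
  if (stress_dead) return("nongrower_sensitive")
  if (is.na(mean_lpi) || is.na(p_adj)) return("unchanged")
  if (mean_lpi > envelope$t_sensitive && p_adj <= alpha) return("sensitive")
  if (mean_lpi < envelope$t_tolerant && p_adj <= alpha) return("tolerant")
  "unchanged"
}

#' Call tolerant and sensitive strains from per-replicate LPI values
#'
#' The screen's hit-calling stage. From the per-replicate LPI table (output
#' of [compute_lpi()]) it (i) builds the IQR-restricted null from all finite
#' per-replicate LPI values, (ii) runs Welch's two-sample two-sided t test of
#' every library strain's replicates against the null sample, (iii) adjusts p
#' values with the Benjamini-Hochberg step-up, (iv) derives the
#' control-strain effect-size envelope, and (v) classifies every strain,
#' applying the non-grower rescue rule to strains that grew in basal medium
#' but not under stress.
#'
#' @param lpi_tbl Per-replicate LPI tibble with columns `strain_id`,
#'   `lpi_gt`, `stress_nongrower`, `basal_nongrower` (and optionally `run`).
#' @param controls Character vector of control strain identifiers; their mean
#'   LPIs define the envelope and they are excluded from the calls table.
#' @param alpha FDR threshold on the adjusted p value (default 0.1).
#' @param welch_mode Passed to [welch_test()].
#' @param null_on `"replicates"` pools every per-replicate LPI into the null
#'   data set (default); `"strain_means"` uses per-strain means instead.
#' @return A tibble of class `"screen_calls"`, one row per library strain:
#'   `strain_id`, `n_replicates`, `mean_lpi`, `t_stat`, `p_raw`, `p_adj`,
#'   `call`. Attributes `null` (the `lpi_null`), `envelope`, `alpha` and
#'   `counts` carry the run-level summaries; see [glance.screen_calls()].
#' @export
call_screen <- function(lpi_tbl, controls, alpha = 0.1,
                        welch_mode = c("two-sample", "one-sample"),
                        null_on = c("replicates", "strain_means")) {
  welch_mode <- match.arg(welch_mode)
  null_on <- match.arg(null_on)
  stopifnot_msg(alpha > 0 && alpha < 1, "`alpha` must be in (0, 1)")
  stopifnot_msg(length(controls) >= 1, "control strain list required")

  per_strain <- lpi_tbl |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(
      n_replicates = sum(is.finite(.data$lpi_gt)),
      mean_lpi = ifelse(n_replicates > 0,
                        mean(.data$lpi_gt[is.finite(.data$lpi_gt)]),
                        NA_real_),
      s2_lpi = ifelse(n_replicates > 1,
                      var(.data$lpi_gt[is.finite(.data$lpi_gt)]), NA_real_),
      n_positions = dplyr::n(),
      n_basal_dead = sum(.data$basal_nongrower),
      n_stress_ng = sum(.data$stress_nongrower),
      basal_dead = n_basal_dead == n_positions,
      stress_dead = !basal_dead & n_stress_ng > 0 & n_replicates == 0,
      .groups = "drop")

  null_values <- if (null_on == "replicates") {
    lpi_tbl$lpi_gt
  } else {
    per_strain$mean_lpi
  }
  null <- build_null(null_values)

  ctrl_means <- per_strain |>
    dplyr::filter(.data$strain_id %in% controls, is.finite(.data$mean_lpi))
  envelope <- control_envelope(ctrl_means$mean_lpi)

  lib <- dplyr::filter(per_strain, !.data$strain_id %in% controls)
  testable <- lib$n_replicates >= 2
  if (welch_mode == "two-sample") {
    ns <- null$null_sample
    w <- welch_stats(lib$mean_lpi, lib$s2_lpi, lib$n_replicates,
                     mean(ns), var(ns), length(ns))
  } else {
    w <- list(
      t = (lib$mean_lpi - null$null_mean) /
        sqrt(lib$s2_lpi / lib$n_replicates),
      df = lib$n_replicates - 1)
    w$p <- 2 * pt(-abs(w$t), w$df)
    zero <- !is.na(lib$s2_lpi) & lib$s2_lpi == 0
    w$t[zero] <- ifelse(lib$mean_lpi[zero] == null$null_mean, 0,
                        sign(lib$mean_lpi[zero] - null$null_mean) * Inf)
    w$p[zero] <- ifelse(lib$mean_lpi[zero] == null$null_mean, 1, 0)
  }
  lib$t_stat <- ifelse(testable, w$t, NA_real_)
  lib$p_raw <- ifelse(testable, w$p, NA_real_)
  ## non-growers bypass statistics entirely
  lib$p_raw[lib$basal_dead | lib$stress_dead] <- NA_real_
  lib$t_stat[lib$basal_dead | lib$stress_dead] <- NA_real_
  lib$p_adj <- bh_adjust(lib$p_raw)

  n_untestable <- sum(is.na(lib$p_raw) & !lib$basal_dead & !lib$stress_dead)
  if (n_untestable > 0) {
    rlang::inform(sprintf(
      "%d strain(s) with < 2 LPI replicates were untestable and left unchanged",
      n_untestable))
  }

  lib$call <- purrr::pmap_chr(
    list(lib$mean_lpi, lib$p_adj, lib$basal_dead, lib$stress_dead),
    function(m, p, bd, sd) classify_strain(m, p, envelope, bd, sd, alpha))

  out <- lib |>
    dplyr::select("strain_id", "n_replicates", "mean_lpi", "t_stat",
                  "p_raw", "p_adj", "call")
  structure(out,
            class = c("screen_calls", class(out)),
            null = null, envelope = envelope, alpha = alpha,
            welch_mode = welch_mode, null_on = null_on,
            n_controls = nrow(ctrl_means))
}

#' @export
print.screen_calls <- function(x, ...) {
  cat(sprintf("<screen_calls> %d strains; %s\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$call)), table(x$call)),
                    collapse = ", ")))
  print(attr(x, "null"))
  print(attr(x, "envelope"))
  NextMethod()
}
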