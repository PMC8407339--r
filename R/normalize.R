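#' Fit the spatial control surface of one plate
#'
#' Estimates the expected control-strain generation time at every requested
#' grid position from the control colonies interleaved across the plate
#' (every fourth position in the default layout). The estimator is a
#' Gaussian-kernel local quadratic regression on `log2(gt)` of the control
#' growers, followed by two twicing passes (the same smoother applied to the
#' control-position residuals and added back), which remove the leading
#' orders of smoothing bias so that a smooth noiseless bias field is
#' reproduced almost exactly. The fitted surface is returned on the
#' generation-time scale.
#'
#' @param features Per-colony feature tibble for one plate (one run and
#'   condition), with columns `row`, `col`, `gt_h`, `grower`, `is_control`.
#' @param bandwidth Gaussian kernel sd in grid units.
#' @param eval_at Positions to evaluate, a data frame with `row` and `col`;
#'   defaults to all positions present in `features`.
#' @return A tibble `row`, `col`, `control_gt` (hours, strictly positive).
#' @export
fit_control_surface <- function(features, bandwidth = 4, eval_at = NULL) {
  ctrl <- dplyr::filter(features, .data$is_control, .data$grower,
                        is.finite(.data$gt_h))
  if (nrow(ctrl) < 10) {
    rlang::abort(sprintf(
      "only %d usable control colonies; >= 10 required (normalization error)",
      nrow(ctrl)), class = "colonyscreen_normalization_error")
  }
  if (is.null(eval_at)) eval_at <- dplyr::distinct(features, .data$row, .data$col)

  z <- log2(ctrl$gt_h)
  fit <- local_quad_fit(ctrl$row, ctrl$col, z, bandwidth)
  ## twicing, twice: smooth the control-position residuals and add back,
  ## then repeat on what is left -- each pass knocks out the leading
  ## remaining order of smoothing bias
  res1 <- z - fit(ctrl$row, ctrl$col)
  fit1 <- local_quad_fit(ctrl$row, ctrl$col, res1, bandwidth)
  res2 <- res1 - fit1(ctrl$row, ctrl$col)
  fit2 <- local_quad_fit(ctrl$row, ctrl$col, res2, bandwidth)
  tibble::tibble(
    row = eval_at$row, col = eval_at$col,
    control_gt = 2^(fit(eval_at$row, eval_at$col) +
                      fit1(eval_at$row, eval_at$col) +
                      fit2(eval_at$row, eval_at$col))
  )
}

## Gaussian-weighted degree-2 polynomial fit; returns an evaluator function
local_quad_fit <- function(r0, c0, z, bandwidth) {
  force(r0); force(c0); force(z)
  function(r, c) {
    vapply(seq_along(r), function(i) {
      dr <- r0 - r[i]; dc <- c0 - c[i]
      w <- exp(-(dr^2 + dc^2) / (2 * bandwidth^2))
      X <- cbind(1, dr, dc, dr^2, dc^2, dr * dc)
      XtW <- t(X * w)
      beta <- solve(XtW %*% X, XtW %*% z)
      beta[1]
    }, numeric(1))
  }
}

#' Compute spatially normalized log strain coefficients (LSC)
#'
#' For every colony, `lsc_gt = log2(gt) - log2(surface)`: the population
#' doubling time relative to the local expectation from the spatial control
#' strain, on a log2 scale. A control surface is fitted separately for every
#' plate x run x condition. Non-growing colonies keep an `NA` coefficient and
#' their `grower` flag.
#'
#' @param features Per-colony feature tibble (all plates), with columns
#'   `plate_id`, `row`, `col`, `run`, `condition`, `strain_id`, `is_control`,
#'   `replicate_index`, `gt_h`, `grower`.
#' @inheritParams fit_control_surface
#' @return `features` plus columns `surface_gt` and `lsc_gt`.
#' @export
compute_lsc <- function(features, bandwidth = 4) {
  features |>
    dplyr::group_by(.data$plate_id, .data$run, .data$condition) |>
    dplyr::group_modify(function(d, g) {
      surf <- fit_control_surface(d, bandwidth = bandwidth)
      d |>
        dplyr::left_join(surf, by = c("row", "col")) |>
        dplyr::mutate(surface_gt = .data$control_gt,
                      lsc_gt = ifelse(.data$grower,
                                      log2(.data$gt_h) - log2(.data$control_gt),
                                      NA_real_)) |>
        dplyr::select(-"control_gt")
    }) |>
    dplyr::ungroup()
}

#' Plate-median batch correction of LSC values
#'
#' Subtracts, within every plate (x run x condition), the median of all
#' finite LSC values of that plate -- controls included, non-growers excluded
#' -- from each colony's LSC. Because the spatial control strain occupies a
#' quarter of every plate and most library strains behave like it, the plate
#' median is an estimate of the plate's batch offset. The operation is
#' idempotent.
#'
#' @param phenotypes Tibble with at least `plate_id`, `run`, `condition`,
#'   `lsc_gt`.
#' @return `phenotypes` plus `lsc_gt_corrected`.
#' @export
batch_correct <- function(phenotypes) {
  stopifnot_msg(nrow(phenotypes) > 0, "empty phenotype table")
  phenotypes |>
    dplyr::group_by(.data$plate_id, .data$run, .data$condition) |>
    dplyr::mutate(lsc_gt_corrected = {
      v <- .data$lsc_gt[is.finite(.data$lsc_gt)]
      stopifnot_msg(length(v) >= 2,
                    "need >= 2 finite LSC values per plate (normalization error)")
      .data$lsc_gt - median(v)
    }) |>
    dplyr::ungroup()
}

#' Form per-replicate log phenotypic indices (LPI)
#'
#' Pairs each colony's corrected LSC in the stress condition with the
#' corrected LSC of the same plate position (same strain replicate, same run)
#' in the basal condition and takes the difference:
#' `lpi_gt = lsc_corrected(stress) - lsc_corrected(basal)`. This isolates the
#' stress-specific growth effect: a strain that is equally slow in both media
#' has LPI 0. A colony that grew in basal medium but not under stress yields
#' a `stress_nongrower` record with no numeric LPI; a colony that failed to
#' grow in basal medium is flagged `basal_nongrower` and is excluded from the
#' statistical screen downstream. Positions measured in only one condition
#' are kept (with `NA` LPI) and counted in a warning.
#'
#' @param phenotypes Output of [batch_correct()]: per-colony rows for both
#'   conditions with `lsc_gt_corrected` and `grower`.
#' @param conditions Length-2 character vector, basal first, stress second.
#' @return One row per (plate position x run): strain and position keys plus
#'   `lsc_basal`, `lsc_stress`, `lpi_gt`, `stress_nongrower`,
#'   `basal_nongrower`.
#' @export
compute_lpi <- function(phenotypes, conditions = c("basal", "stress")) {
  stopifnot_msg(all(conditions %in% phenotypes$condition),
                "both conditions must be present in `phenotypes`")
  basal <- conditions[1]; stress <- conditions[2]
  keys <- intersect(c("plate_id", "row", "col", "run",
                      "strain_id", "is_control", "replicate_index"),
                    names(phenotypes))
  wide <- phenotypes |>
    dplyr::filter(.data$condition %in% conditions) |>
    dplyr::mutate(condition = ifelse(.data$condition == basal,
                                     "basal", "stress")) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(keys),
                       names_from = "condition",
                       values_from = c("lsc_gt_corrected", "grower"))
  for (col in c("lsc_gt_corrected_basal", "lsc_gt_corrected_stress",
                "grower_basal", "grower_stress")) {
    if (!col %in% names(wide)) wide[[col]] <- NA
  }
  n_unpaired <- sum(is.na(wide$grower_basal) | is.na(wide$grower_stress))
  if (n_unpaired > 0) {
    rlang::warn(sprintf(
      "%d position(s) measured in only one condition; kept with NA LPI",
      n_unpaired))
  }
  wide |>
    dplyr::mutate(
      lsc_basal = .data$lsc_gt_corrected_basal,
      lsc_stress = .data$lsc_gt_corrected_stress,
      basal_nongrower = !dplyr::coalesce(.data$grower_basal, TRUE),
      stress_nongrower = dplyr::coalesce(.data$grower_basal, FALSE) &
        !dplyr::coalesce(.data$grower_stress, TRUE),
      lpi_gt = dplyr::if_else(
        dplyr::coalesce(.data$grower_basal, FALSE) &
          dplyr::coalesce(.data$grower_stress, FALSE),
        .data$lsc_stress - .data$lsc_basal, NA_real_)
    ) |>
    dplyr::select(dplyr::all_of(keys), "lsc_basal", "lsc_stress", "lpi_gt",
                  "stress_nongrower", "basal_nongrower")
}
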