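#' Smooth multiplicative spatial bias field for one plate
#'
#' Draws a random smooth field over the plate grid: a low-order polynomial in
#' the normalized coordinates plus three radial Gaussian bumps of fixed width
#' (sd 12 grid units), linearly rescaled so that the multiplier spans exactly
#' `[1 - amplitude, 1 + amplitude]`. With `amplitude = 0` the field is
#' identically 1.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param amplitude Multiplicative half-range in `[0, 1)`.
#' @param bump_sd Width (sd, grid units) of the radial bumps.
#' @return An `n_rows x n_cols` matrix of multipliers.
#' @keywords internal
#' @export
make_bias_field <- function(n_rows, n_cols, amplitude, bump_sd = 12) {
  if (amplitude == 0) return(matrix(1, n_rows, n_cols))
  x <- matrix(rep((seq_len(n_cols) - 1) / (n_cols - 1) * 2 - 1, each = n_rows),
              n_rows, n_cols)
  y <- matrix(rep((seq_len(n_rows) - 1) / (n_rows - 1) * 2 - 1, n_cols),
              n_rows, n_cols)
  a <- runif(5, -1, 1)
  f <- a[1] * x + a[2] * y + a[3] * x * y + a[4] * x^2 + a[5] * y^2
  for (k in 1:3) {
    cr <- runif(1, 0, n_rows - 1); cc <- runif(1, 0, n_cols - 1)
    h <- runif(1, -1, 1)
    d2 <- (matrix(rep(seq_len(n_rows) - 1, n_cols), n_rows) - cr)^2 +
      (matrix(rep(seq_len(n_cols) - 1, each = n_rows), n_rows) - cc)^2
    f <- f + h * exp(-d2 / (2 * bump_sd^2))
  }
  rng <- range(f)
  if (diff(rng) < .Machine$double.eps) return(matrix(1, n_rows, n_cols))
  (1 - amplitude) + 2 * amplitude * (f - rng[1]) / diff(rng)
}

#' Simulate a complete colony-array screen
#'
#' Generates layouts, a ground-truth effect table, per-physical-plate spatial
#' bias fields and batch offsets, and the resulting per-colony growth
#' phenotypes for every run x condition x plate. Each colony's generation
#' time is
#' `control_gt * cond_multiplier * 2^(basal_offset + stress_effect + batch + noise) * bias(position)`
#' with the stress effect applied only in the stress condition; strains
#' flagged as stress-inhibited are non-growers (infinite generation time) in
#' the stress condition only, basal-inhibited strains in both conditions.
#'
#' By default the simulator returns the per-colony feature table directly
#' (the quantity every downstream stage consumes); with `curves = TRUE` it
#' additionally samples the full logistic growth curve of every colony at the
#' configured interval, which is what the feature-extraction module is tested
#' against.
#'
#' @param config A [sim_config()] object.
#' @param curves If `TRUE`, also return the long per-colony time series.
#' @return A list of class `"colony_screen_sim"` with elements `features`
#'   (tibble: `plate_id, row, col, run, condition, strain_id, is_control,
#'   replicate_index, gt_h, lag_h, yield, grower`), `layout`, `truth`,
#'   `bias_fields` (named list of matrices, one per plate x run x condition),
#'   `batch_offsets` (tibble), `config`, and optionally `curves` (tibble:
#'   colony keys plus `time_h`, `value`).
#' @examples
#' sim <- simulate_screen(sim_config(n_strains = 24, n_rows = 8, n_cols = 12,
#'                                   seed = 1))
#' dplyr::count(sim$features, run, condition)
#' @export
simulate_screen <- function(config, curves = FALSE) {
  validate_sim_config(config)
  strains <- sprintf("S%05d", seq_len(config$n_strains))
  layout <- make_layout(strains, config$n_rows, config$n_cols,
                        control_id = config$control_id)
  truth <- sample_truth(c(strains, config$control_id), config)
  plates <- unique(layout$plate_id)
  runs <- seq_len(config$n_runs)
  stress <- config$conditions[2]

  with_seed(config$seed, {
    keys <- tidyr::expand_grid(plate_id = plates, run = runs,
                               condition = config$conditions)
    bias_fields <- purrr::pmap(keys, function(plate_id, run, condition) {
      make_bias_field(config$n_rows, config$n_cols,
                      config$spatial_bias_amplitude)
    })
    names(bias_fields) <- sprintf("%s.run%d.%s", keys$plate_id, keys$run,
                                  keys$condition)
    batch <- dplyr::mutate(keys,
                           batch_offset = rnorm(nrow(keys), 0,
                                                config$plate_batch_sd))

    colonies <- tidyr::expand_grid(run = runs,
                                   condition = config$conditions,
                                   layout) |>
      dplyr::left_join(truth, by = "strain_id") |>
      dplyr::left_join(batch, by = c("plate_id", "run", "condition")) |>
      dplyr::arrange(.data$run, .data$condition, .data$plate_id,
                     .data$row, .data$col)

    fkey <- sprintf("%s.run%d.%s", colonies$plate_id, colonies$run,
                    colonies$condition)
    bias <- numeric(nrow(colonies))
    for (k in unique(fkey)) {
      idx <- which(fkey == k)
      bias[idx] <- bias_fields[[k]][cbind(colonies$row[idx] + 1L,
                                          colonies$col[idx] + 1L)]
    }

    is_stress <- colonies$condition == stress
    noise <- rnorm(nrow(colonies), 0, config$replicate_noise_sd)
    log2gt <- log2(config$control_gt) +
      ifelse(is_stress, log2(config$stress_gt_multiplier), 0) +
      colonies$basal_log2gt_offset +
      ifelse(is_stress, colonies$stress_lpi_effect, 0) +
      log2(bias) + colonies$batch_offset + noise
    gt <- 2^log2gt
    dead <- colonies$inhibited_in_basal |
      (colonies$inhibited_in_stress & is_stress)
    gt[dead] <- Inf

    features <- colonies |>
      dplyr::mutate(
        gt_h = gt,
        lag_h = ifelse(is_stress, config$lag_stress, config$lag_basal),
        yield = ifelse(is.finite(gt), config$capacity - config$n0, 0),
        grower = is.finite(gt)
      ) |>
      dplyr::select("plate_id", "row", "col", "run", "condition",
                    "strain_id", "is_control", "replicate_index",
                    "gt_h", "lag_h", "yield", "grower")

    out <- list(features = features, layout = layout, truth = truth,
                bias_fields = bias_fields, batch_offsets = batch,
                config = config)
    if (curves) {
      out$curves <- features |>
        dplyr::mutate(.curve = purrr::map2(.data$gt_h, .data$lag_h, function(g, l) {
          simulate_curve(gt = g, lag = l, n0 = config$n0,
                         capacity = config$capacity,
                         sampling_interval = config$sampling_interval,
                         horizon = config$horizon,
                         noise_sd = config$curve_noise_sd)
        })) |>
        dplyr::select("plate_id", "row", "col", "run", "condition",
                      "strain_id", ".curve") |>
        tidyr::unnest(".curve")
    }
    structure(out, class = "colony_screen_sim")
  })
}

#' @export
print.colony_screen_sim <- function(x, ...) {
  cat("<colony_screen_sim>\n")
  cat(sprintf("  %d colonies (%d plates x %d runs x %d conditions)\n",
              nrow(x$features), length(unique(x$layout$plate_id)),
              x$config$n_runs, length(x$config$conditions)))
  cat(sprintf("  %d strains; classes: %s\n", x$config$n_strains,
              paste(sprintf("%s=%d", names(table(x$truth$class)),
                            table(x$truth$class)), collapse = ", ")))
  if (!is.null(x$curves)) cat(sprintf("  curves: %d points\n", nrow(x$curves)))
  invisible(x)
}
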