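make_plate_features <- function(gt_fun, n_rows = 16, n_cols = 24) {
  lay <- make_layout(sprintf("S%03d", seq_len(n_rows * n_cols / 4)),
                     n_rows = n_rows, n_cols = n_cols)
  dplyr::mutate(lay, run = 1L, condition = "basal",
                gt_h = gt_fun(row, col), grower = TRUE)
}

test_that("constant controls give a constant surface", {
  feat <- make_plate_features(function(r, c) 2)
  surf <- fit_control_surface(feat)
  expect_equal(surf$control_gt, rep(2, nrow(surf)), tolerance = 1e-10)
})

test_that("a linear gradient across columns is tracked by the surface", {
  n_cols <- 24
  grad <- function(r, c) 2 + (3 - 2) * c / (n_cols - 1)
  feat <- make_plate_features(grad)
  surf <- fit_control_surface(feat, bandwidth = 4)
  interior <- surf[surf$col >= 2 & surf$col <= n_cols - 3, ]
  expect_equal(interior$control_gt, grad(interior$row, interior$col),
               tolerance = 0.03)
})

test_that("one outlier control barely moves the surface far away", {
  feat <- make_plate_features(function(r, c) 2)
  ctrl_pos <- which(feat$is_control)
  feat2 <- feat
  feat2$gt_h[ctrl_pos[1]] <- 8         # control at (1,1)-ish corner
  s1 <- fit_control_surface(feat, bandwidth = 4)
  s2 <- fit_control_surface(feat2, bandwidth = 4)
  far <- sqrt((s1$row - feat$row[ctrl_pos[1]])^2 +
                (s1$col - feat$col[ctrl_pos[1]])^2) > 20
  expect_true(all(abs(s2$control_gt[far] / s1$control_gt[far] - 1) < 0.001))
})

test_that("surface fitting demands enough control growers", {
  feat <- make_plate_features(function(r, c) 2)
  feat$grower[which(feat$is_control)[-(1:5)]] <- FALSE
  expect_error(fit_control_surface(feat),
               class = "colonyscreen_normalization_error")
})

test_that("lsc is the log2 ratio of colony gt to the local surface", {
  # colony exactly on the surface -> 0; at twice the surface -> 1
  feat <- make_plate_features(function(r, c) 2)
  feat$gt_h[!feat$is_control][1] <- 4
  lsc <- compute_lsc(feat)
  lib <- lsc[!lsc$is_control, ]
  expect_equal(lib$lsc_gt[1], 1, tolerance = 1e-9)
  expect_equal(lib$lsc_gt[-1], rep(0, nrow(lib) - 1), tolerance = 1e-9)
})

test_that("spatial normalization cancels a strong bias field", {
  cfg <- clean_config(spatial_bias_amplitude = 0.3, seed = 31)
  sim <- simulate_screen(cfg)
  feat <- dplyr::filter(sim$features, condition == "basal", run == 1)
  lsc <- compute_lsc(feat)
  ctrl <- dplyr::filter(lsc, is_control)

  # before normalization the controls spread with the bias field
  raw <- log2(feat$gt_h[feat$is_control])
  expect_gte(sd(raw - mean(raw)), 0.1)
  # after normalization they collapse
  expect_lte(sd(ctrl$lsc_gt), 0.02)
})

test_that("noiseless injected offsets are recovered through the surface", {
  # full 32 x 48 plate: the bias field varies on the scale the estimator is
  # tuned for, and interior offsets come back to better than 1e-3 log2 units
  cfg <- clean_config(n_strains = 384, n_rows = 32, n_cols = 48,
                      spatial_bias_amplitude = 0.3, basal_offset_sd = 0.1,
                      fraction_tolerant = 0, fraction_sensitive = 0,
                      n_runs = 1, seed = 13)
  sim <- simulate_screen(cfg)
  feat <- dplyr::filter(sim$features, condition == "basal", run == 1)
  lsc <- compute_lsc(feat) |>
    dplyr::left_join(sim$truth, by = "strain_id") |>
    dplyr::filter(!is_control, row >= 4, row <= 27, col >= 4, col <= 43)
  expect_lt(max(abs(lsc$lsc_gt - lsc$basal_log2gt_offset)), 1e-3)
})

test_that("batch correction subtracts the plate median", {
  ph <- tibble::tibble(plate_id = "P01", run = 1L, condition = "basal",
                       lsc_gt = c(0.1, 0.2, 0.3))
  expect_equal(batch_correct(ph)$lsc_gt_corrected, c(-0.1, 0, 0.1))

  same <- dplyr::mutate(ph, lsc_gt = 0.7)
  expect_equal(batch_correct(same)$lsc_gt_corrected, rep(0, 3))

  # even count: mean-of-middle-two convention
  even <- tibble::tibble(plate_id = "P01", run = 1L, condition = "basal",
                         lsc_gt = c(0, 0.1, 0.2, 0.5))
  expect_equal(batch_correct(even)$lsc_gt_corrected,
               c(-0.15, -0.05, 0.05, 0.35))
})

test_that("batch correction is idempotent and per plate", {
  ph <- tidyr::expand_grid(plate_id = c("P01", "P02"), run = 1:2,
                           condition = c("basal", "stress"),
                           i = 1:25) |>
    dplyr::mutate(lsc_gt = sin(i + match(plate_id, c("P01", "P02"))))
  once <- batch_correct(ph)
  twice <- batch_correct(dplyr::mutate(once, lsc_gt = lsc_gt_corrected))
  expect_equal(twice$lsc_gt_corrected, once$lsc_gt_corrected,
               tolerance = 1e-12)
  meds <- once |>
    dplyr::group_by(plate_id, run, condition) |>
    dplyr::summarise(m = median(lsc_gt_corrected), .groups = "drop")
  expect_true(all(abs(meds$m) < 1e-12))
})

test_that("lpi is the stress-basal difference on paired positions", {
  ph <- tibble::tibble(
    plate_id = "P01", row = 0L, col = 0L, run = 1L,
    strain_id = "S1", is_control = FALSE, replicate_index = 1L,
    condition = c("basal", "stress"),
    lsc_gt = c(0.1, 0.3), lsc_gt_corrected = c(0.1, 0.3),
    grower = TRUE)
  lpi <- compute_lpi(ph)
  expect_equal(lpi$lpi_gt, 0.2)
  expect_false(lpi$stress_nongrower)

  # identical LSC in both conditions -> LPI 0, however slow the strain
  ph2 <- dplyr::mutate(ph, lsc_gt_corrected = 0.9)
  expect_equal(compute_lpi(ph2)$lpi_gt, 0)
})

test_that("stress non-growers become rescue records, not numbers", {
  ph <- tibble::tibble(
    plate_id = "P01", row = 0L, col = 0L, run = 1L,
    strain_id = "S1", is_control = FALSE, replicate_index = 1L,
    condition = c("basal", "stress"),
    lsc_gt = c(0.1, NA), lsc_gt_corrected = c(0.1, NA),
    grower = c(TRUE, FALSE))
  lpi <- compute_lpi(ph)
  expect_true(is.na(lpi$lpi_gt))
  expect_true(lpi$stress_nongrower)
  expect_false(lpi$basal_nongrower)
})

test_that("unpaired positions are kept and warned about", {
  ph <- tibble::tibble(
    plate_id = "P01", row = c(0L, 0L, 2L), col = c(0L, 0L, 2L), run = 1L,
    strain_id = c("S1", "S1", "S2"), is_control = FALSE,
    replicate_index = 1L,
    condition = c("basal", "stress", "basal"),
    lsc_gt = c(0.1, 0.3, 0.2), lsc_gt_corrected = c(0.1, 0.3, 0.2),
    grower = TRUE)
  expect_warning(lpi <- compute_lpi(ph), "one condition")
  expect_equal(nrow(lpi), 2)      # S2 kept with NA LPI
  expect_true(is.na(lpi$lpi_gt[lpi$strain_id == "S2"]))
})

test_that("noiseless screens return the injected stress effects exactly", {
  # bias amplitude 0: the per-condition surfaces then cancel exactly, so the
  # only remaining terms are the injected effects and the (shared) batch
  # offsets, both of which the normalization removes to machine precision
  cfg <- clean_config(fraction_tolerant = 0.1, fraction_sensitive = 0.1,
                      basal_offset_sd = 0.05, spatial_bias_amplitude = 0,
                      plate_batch_sd = 0.05, seed = 21)
  sim <- simulate_screen(cfg)
  lpi <- compute_lpi(batch_correct(compute_lsc(sim$features))) |>
    dplyr::left_join(sim$truth, by = "strain_id") |>
    dplyr::filter(!is_control)
  # spatial surface and batch medians cancel between conditions
  expect_equal(lpi$lpi_gt, lpi$stress_lpi_effect, tolerance = 1e-6)
})

test_that("lpi ignores plate-constant shifts applied to both conditions", {
  cfg <- clean_config(fraction_tolerant = 0.1, seed = 8)
  sim <- simulate_screen(cfg)
  lsc <- batch_correct(compute_lsc(sim$features))
  shifted <- dplyr::mutate(lsc, lsc_gt_corrected = lsc_gt_corrected + 0.42)
  expect_equal(compute_lpi(shifted)$lpi_gt, compute_lpi(lsc)$lpi_gt,
               tolerance = 1e-12)
})
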