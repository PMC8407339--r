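test_that("IQR null matches the hand-computed example", {
  null <- build_null(c(1, 2, 3, 4, 5, 6, 7, 8))
  expect_equal(null$q1, 2.75)
  expect_equal(null$q3, 6.25)
  expect_setequal(null$null_sample, c(3, 4, 5, 6))
  expect_equal(null$null_mean, 4.5)
  expect_true(all(null$null_sample >= null$q1 &
                    null$null_sample <= null$q3))
})

test_that("IQR null of a symmetric sample is centred at zero", {
  v <- c(-(1:50) / 10, (1:50) / 10)
  expect_equal(build_null(v)$null_mean, 0)
  expect_error(build_null(c(1, 2, 3)), ">= 4")
})

test_that("welch test agrees with the reference implementation", {
  set.seed(404)
  for (i in 1:200) {
    nx <- sample(2:6, 1)
    ny <- sample(4:60, 1)
    x <- rnorm(nx, sd = runif(1, 0.01, 2))
    y <- rnorm(ny, mean = runif(1, -1, 1), sd = runif(1, 0.01, 2))
    null <- list(null_sample = y, null_mean = mean(y))
    got <- welch_test(x, null)
    ref <- t.test(x, y, var.equal = FALSE)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p_raw, ref$p.value, tolerance = 1e-10)
  }
})

test_that("welch test handles degenerate and untestable inputs", {
  null <- build_null(rep(c(0.02, 0.03), 10))
  expect_true(welch_test(0.5, null)$untestable)

  same <- list(null_sample = rep(0.1, 8), null_mean = 0.1)
  expect_equal(welch_test(c(0.1, 0.1), same)$p_raw, 1)
  expect_equal(welch_test(c(0.4, 0.4), same)$p_raw, 0)

  # a clearly shifted strain is significant; with n = 3 the Welch df is ~2,
  # so the p value is small but not astronomically so -- assert against the
  # reference implementation and the significance threshold
  big_null <- list(null_sample = rnorm(1000, 0.025, 0.03) |>
                     (\(v) 0.025 + (v - mean(v)) * 0.03 / sd(v))())
  got <- welch_test(c(0.30, 0.32, 0.28), big_null)
  ref <- t.test(c(0.30, 0.32, 0.28), big_null$null_sample)
  expect_equal(got$p_raw, ref$p.value, tolerance = 1e-10)
  expect_lt(got$p_raw, 0.01)
})

test_that("welch test is antisymmetric in its two samples", {
  x <- c(0.3, 0.25, 0.35)
  y <- rnorm(50, 0, 0.05)
  a <- welch_test(x, list(null_sample = y))
  b <- t.test(y, x, var.equal = FALSE)   # swapped
  expect_equal(a$t_stat, -unname(b$statistic), tolerance = 1e-12)
  expect_equal(a$p_raw, b$p.value, tolerance = 1e-12)
})

test_that("BH adjustment reproduces hand and oracle results", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:1000) {
    n <- sample(1:500, 1)
    p <- runif(n)^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, method = "BH"), tolerance = 1e-12)
    if (i <= 50) expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("BH keeps NA (untestable) entries out of m", {
  p <- c(0.01, NA, 0.02, 0.04, NA)
  adj <- bh_adjust(p)
  expect_true(all(is.na(adj[c(2, 5)])))
  expect_equal(adj[!is.na(p)], bh_adjust(c(0.01, 0.02, 0.04)))
})

test_that("control envelope is the min/max of per-strain means", {
  env <- control_envelope(c(-0.01, 0.02, 0.00))
  expect_equal(env$t_tolerant, -0.01)
  expect_equal(env$t_sensitive, 0.02)
  expect_error(control_envelope(0.05), ">= 2")
})

test_that("classification follows the published thresholds", {
  env <- structure(list(t_tolerant = -0.037, t_sensitive = 0.166),
                   class = "control_envelope")
  expect_equal(classify_strain(0.20, 0.05, env), "sensitive")
  expect_equal(classify_strain(-0.10, 0.05, env), "tolerant")
  expect_equal(classify_strain(0.20, 0.2, env), "unchanged")
  expect_equal(classify_strain(0.10, 0.01, env), "unchanged")  # inside envelope
  expect_equal(classify_strain(NA, NA, env, stress_dead = TRUE),
               "nongrower_sensitive")
  expect_equal(classify_strain(NA, NA, env, basal_dead = TRUE), "basal_dead")
  expect_error(classify_strain(0, 0.5, env, basal_dead = TRUE,
                               stress_dead = TRUE), "contradictory")
})

test_that("call_screen results are invariant to row order", {
  cfg <- tiny_config(fraction_tolerant = 0.1, fraction_sensitive = 0.1,
                     seed = 19)
  sim <- simulate_screen(cfg)
  lpi <- compute_lpi(batch_correct(compute_lsc(sim$features)))
  controls <- c(sim$truth$strain_id[sim$truth$class == "library_control"],
                "CTRL")
  a <- call_screen(lpi, controls)
  set.seed(1)
  b <- call_screen(lpi[sample(nrow(lpi)), ], controls)
  expect_equal(dplyr::arrange(tidy(a), strain_id),
               dplyr::arrange(tidy(b), strain_id))
})

test_that("nongrower rescue and basal exclusion propagate into calls", {
  lpi <- tibble::tibble(
    strain_id = rep(c("ok", "dead_stress", "dead_basal", "ctrl1", "ctrl2"),
                    each = 4),
    run = rep(1:2, 10),
    lpi_gt = c(rnorm(4, 0.0, 0.01),
               rep(NA, 4), rep(NA, 4),
               rnorm(4, 0, 0.01), rnorm(4, 0, 0.01)),
    stress_nongrower = rep(c(FALSE, TRUE, FALSE, FALSE, FALSE), each = 4),
    basal_nongrower = rep(c(FALSE, FALSE, TRUE, FALSE, FALSE), each = 4))
  calls <- call_screen(lpi, controls = c("ctrl1", "ctrl2"))
  expect_equal(calls$call[calls$strain_id == "dead_stress"],
               "nongrower_sensitive")
  expect_true(is.na(calls$p_raw[calls$strain_id == "dead_stress"]))
  expect_equal(calls$call[calls$strain_id == "dead_basal"], "basal_dead")
})

test_that("gene aggregation counts guides and converts LPI to percent", {
  calls <- tibble::tibble(
    strain_id = c("a", "b", "c", "d"),
    n_replicates = 6, mean_lpi = c(-0.1, -0.2, 1.0, NA),
    t_stat = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
    call = c("tolerant", "tolerant", "sensitive", "nongrower_sensitive"))
  gm <- data.frame(strain_id = c("a", "b", "c", "d"),
                   gene_id = c("G1", "G1", "G2", "G2"))
  gs <- aggregate_genes(calls, gm)
  g1 <- gs[gs$gene_id == "G1", ]
  expect_equal(g1$n_tolerant, 2)
  expect_equal(g1$pct_change_min, (2^-0.2 - 1) * 100, tolerance = 1e-9)
  expect_equal(g1$pct_change_max, (2^-0.1 - 1) * 100, tolerance = 1e-9)
  g2 <- gs[gs$gene_id == "G2", ]
  expect_equal(g2$n_sensitive, 2)               # rescue counts as sensitive
  expect_equal(g2$n_complete_inhibition, 1)
  expect_equal(g2$pct_change_max, 100)          # LPI 1 doubles the GT

  expect_error(aggregate_genes(calls, gm[-1, ]), "unmapped")
})

test_that("replicate concordance is 1 for identical or mirrored runs", {
  lpi <- tibble::tibble(strain_id = rep(sprintf("S%d", 1:10), 2),
                        run = rep(1:2, each = 10),
                        lpi_gt = c(1:10 / 10, 1:10 / 10))
  cc <- replicate_concordance(lpi)
  expect_equal(cc$pearson_r, 1)
  expect_equal(cc$r_squared, 1)

  mirrored <- dplyr::mutate(lpi, lpi_gt = ifelse(run == 2, -lpi_gt, lpi_gt))
  cm <- replicate_concordance(mirrored)
  expect_equal(cm$pearson_r, -1)
  expect_equal(cm$r_squared, 1)

  flat <- dplyr::mutate(lpi, lpi_gt = ifelse(run == 2, 1, lpi_gt))
  expect_true(replicate_concordance(flat)$degenerate)
})

test_that("concordance approaches the variance-components prediction", {
  # strain mean over n replicates: run-level R^2 ~ var_e / (var_e + 2*var_n/n)
  set.seed(303)
  n_strains <- 4000; n_rep <- 3
  var_e <- 0.04; var_n <- 0.01
  eff <- rnorm(n_strains, 0, sqrt(var_e))
  lpi <- tidyr::expand_grid(strain_id = sprintf("S%04d", 1:n_strains),
                            run = 1:2, rep = 1:n_rep) |>
    dplyr::mutate(lpi_gt = eff[match(strain_id, sprintf("S%04d", 1:n_strains))] +
                    rnorm(dplyr::n(), 0, sqrt(var_n)))
  cc <- replicate_concordance(lpi)
  pred <- var_e / (var_e + var_n / n_rep)
  # r = cov / var ; with equal run variances R^2 -> (var_e/(var_e+var_n/n))^2
  expect_equal(cc$r_squared, pred^2, tolerance = 0.05)
})
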