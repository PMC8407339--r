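#' Sample a ground-truth effect table for a simulated screen
#'
#' Assigns each library strain its true phenotype: a basal generation-time
#' offset (log2 hours relative to the control strain), a stress-specific log
#' phenotypic index effect, and complete-inhibition flags. Exact numbers of
#' tolerant / sensitive / inhibited strains are `round(fraction * n)`; which
#' strains receive which class is drawn from the config seed. The control
#' strain, if present, always has zero effects and false flags.
#'
#' @param strains Character vector of strain identifiers.
#' @param config A [sim_config()] object supplying fractions, effect
#'   distributions and the seed.
#'
#' @return A tibble keyed by `strain_id` with columns `class`
#'   (`"neutral"`, `"tolerant"`, `"sensitive"`, `"stress_inhibited"`,
#'   `"basal_inhibited"`, `"control"`), `basal_log2gt_offset`,
#'   `stress_lpi_effect`, `inhibited_in_stress`, `inhibited_in_basal`.
#' @examples
#' cfg <- sim_config(n_strains = 100, seed = 7)
#' truth <- sample_truth(sprintf("S%03d", 1:100), cfg)
#' table(truth$class)
#' @export
sample_truth <- function(strains, config) {
  validate_sim_config(config)
  is_ctrl <- strains == config$control_id
  lib <- strains[!is_ctrl]
  n <- length(lib)

  n_lc <- config$n_library_controls
  n_tol <- round(config$fraction_tolerant * n)
  n_sen <- round(config$fraction_sensitive * n)
  n_sti <- round(config$fraction_stress_inhibited * n)
  n_bai <- round(config$fraction_basal_inhibited * n)
  stopifnot_msg(n_tol + n_sen + n_sti + n_bai + n_lc <= n,
                "effect fractions exceed the strain count (config error)")

  with_seed(config$seed + 101L, {
    ord <- sample.int(n)
    cls <- rep("neutral", n)
    take <- function(k) {
      idx <- head(ord, k)
      ord <<- tail(ord, length(ord) - k)
      idx
    }
    cls[take(n_tol)] <- "tolerant"
    cls[take(n_sen)] <- "sensitive"
    cls[take(n_sti)] <- "stress_inhibited"
    cls[take(n_bai)] <- "basal_inhibited"
    cls[take(n_lc)] <- "library_control"

    eff <- numeric(n)
    eff[cls == "tolerant"] <-
      rnorm(n_tol, config$tolerant_effect_mean, config$effect_sd)
    eff[cls == "sensitive"] <-
      rnorm(n_sen, config$sensitive_effect_mean, config$effect_sd)
    offs <- rnorm(n, 0, config$basal_offset_sd)
    offs[cls == "library_control"] <- 0

    out <- tibble::tibble(
      strain_id = lib,
      class = cls,
      basal_log2gt_offset = offs,
      stress_lpi_effect = eff,
      inhibited_in_stress = cls == "stress_inhibited",
      inhibited_in_basal = cls == "basal_inhibited"
    )
    if (any(is_ctrl)) {
      out <- dplyr::bind_rows(
        out,
        tibble::tibble(strain_id = strains[is_ctrl], class = "control",
                       basal_log2gt_offset = 0, stress_lpi_effect = 0,
                       inhibited_in_stress = FALSE, inhibited_in_basal = FALSE))
    }
    out[match(strains, out$strain_id), ]
  })
}

## run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
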