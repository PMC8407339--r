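#' Configuration for a simulated colony-array screen
#'
#' Collects every knob of the synthetic screen generator. The defaults mirror
#' the design of a full-scale solid-medium CRISPRi screen: 1536-position
#' plates (32 x 48) holding 384 library strains each as 3 adjacent replicates,
#' every fourth position occupied by the spatial control strain, two growth
#' conditions (basal medium and 150 mM acetic acid), two independent runs
#' (6 replicate measurements per strain and condition), colonies imaged every
#' 20 minutes for 96 hours.
#'
#' Magnitudes not fixed by the experimental design are stated assumptions of
#' the generator, chosen so that the per-replicate spread of control log
#' strain coefficients is about 0.05 log2 units: `replicate_noise_sd = 0.05`,
#' `plate_batch_sd = 0.02`, `spatial_bias_amplitude = 0.15`. True effects are
#' injected into a `fraction_tolerant` of strains (mean log phenotypic index
#' `tolerant_effect_mean`, default -0.2) and a `fraction_sensitive` of strains
#' (mean `sensitive_effect_mean`, default +0.3); a further small fraction is
#' completely growth-inhibited under stress only, and another under basal
#' medium (these never enter the statistical screen).
#'
#' @param n_strains Number of library (non-control) strains.
#' @param n_rows,n_cols Plate grid dimensions; must both be even.
#' @param control_id Identifier of the spatial control strain.
#' @param conditions Character vector of the two condition labels; the second
#'   is the stress condition carrying the injected LPI effects.
#' @param n_runs Independent experimental repeats (each run grows every plate
#'   in every condition).
#' @param n_library_controls Number of library strains carrying non-targeting
#'   guides (true controls with zero effect); their mean LPIs define the
#'   effect-size envelope downstream.
#' @param fraction_tolerant,fraction_sensitive Proportions of library strains
#'   given negative / positive stress effects.
#' @param tolerant_effect_mean,sensitive_effect_mean,effect_sd Means and
#'   common sd (log2 units) of the injected LPI effect distributions.
#' @param basal_offset_sd Sd (log2 units) of per-strain basal generation-time
#'   offsets relative to the control strain.
#' @param fraction_stress_inhibited,fraction_basal_inhibited Proportions of
#'   strains with complete growth inhibition under stress only / under basal
#'   medium.
#' @param spatial_bias_amplitude Half-range of the multiplicative spatial bias
#'   field; multipliers span `[1 - a, 1 + a]`.
#' @param plate_batch_sd Sd (log2 units) of the per-(plate, run, condition)
#'   batch offset.
#' @param replicate_noise_sd Sd (log2 units) of per-colony generation-time
#'   noise.
#' @param curve_noise_sd Sd (log2 units) of multiplicative measurement noise
#'   applied per time point when curves are sampled.
#' @param control_gt Generation time of the control strain, hours.
#' @param stress_gt_multiplier Condition-wide multiplier on generation time in
#'   the stress condition (acetic acid slows everything down).
#' @param n0,capacity Initial population proxy and carrying capacity of the
#'   logistic growth model.
#' @param lag_basal,lag_stress Growth lag, hours, under each condition.
#' @param sampling_interval Time between samples, hours (default 1/3 h, i.e.
#'   every 20 minutes).
#' @param horizon Duration of the experiment, hours.
#' @param seed Integer seed making the whole simulation reproducible.
#'
#' @return A list of class `"sim_config"`, validated. The number of plates is
#'   implied: `ceiling(n_strains / (n_rows * n_cols * 3 / 4 / 3))`.
#' @examples
#' cfg <- sim_config(n_strains = 384)
#' cfg$n_runs
#' @export
sim_config <- function(n_strains = 9216,
                       n_rows = 32, n_cols = 48,
                       control_id = "CTRL",
                       conditions = c("basal", "stress"),
                       n_runs = 2,
                       n_library_controls = 20,
                       fraction_tolerant = 0.05,
                       fraction_sensitive = 0.05,
                       tolerant_effect_mean = -0.2,
                       sensitive_effect_mean = 0.3,
                       effect_sd = 0.05,
                       basal_offset_sd = 0.03,
                       fraction_stress_inhibited = 0.002,
                       fraction_basal_inhibited = 0.01,
                       spatial_bias_amplitude = 0.15,
                       plate_batch_sd = 0.02,
                       replicate_noise_sd = 0.05,
                       curve_noise_sd = 0.01,
                       control_gt = 3,
                       stress_gt_multiplier = 1.5,
                       n0 = 0.05, capacity = 50,
                       lag_basal = 2, lag_stress = 8,
                       sampling_interval = 1 / 3,
                       horizon = 96,
                       seed = 1L) {
  cfg <- list(
    n_strains = as.integer(n_strains), n_rows = as.integer(n_rows),
    n_cols = as.integer(n_cols), control_id = control_id,
    conditions = conditions, n_runs = as.integer(n_runs),
    n_library_controls = as.integer(n_library_controls),
    fraction_tolerant = fraction_tolerant,
    fraction_sensitive = fraction_sensitive,
    tolerant_effect_mean = tolerant_effect_mean,
    sensitive_effect_mean = sensitive_effect_mean,
    effect_sd = effect_sd, basal_offset_sd = basal_offset_sd,
    fraction_stress_inhibited = fraction_stress_inhibited,
    fraction_basal_inhibited = fraction_basal_inhibited,
    spatial_bias_amplitude = spatial_bias_amplitude,
    plate_batch_sd = plate_batch_sd,
    replicate_noise_sd = replicate_noise_sd,
    curve_noise_sd = curve_noise_sd,
    control_gt = control_gt, stress_gt_multiplier = stress_gt_multiplier,
    n0 = n0, capacity = capacity,
    lag_basal = lag_basal, lag_stress = lag_stress,
    sampling_interval = sampling_interval, horizon = horizon,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_msg(cfg$n_strains >= 1, "`n_strains` must be >= 1")
  stopifnot_msg(cfg$n_rows %% 2 == 0 && cfg$n_cols %% 2 == 0,
                "grid dimensions must be even (layout error)")
  fr <- c(cfg$fraction_tolerant, cfg$fraction_sensitive,
          cfg$fraction_stress_inhibited, cfg$fraction_basal_inhibited)
  stopifnot_msg(all(fr >= 0 & fr <= 1), "fractions must lie in [0, 1]")
  stopifnot_msg(cfg$fraction_tolerant + cfg$fraction_sensitive +
                  cfg$fraction_stress_inhibited + cfg$fraction_basal_inhibited < 1,
                "effect fractions must sum to < 1 (config error)")
  sds <- c(cfg$effect_sd, cfg$basal_offset_sd, cfg$plate_batch_sd,
           cfg$replicate_noise_sd, cfg$curve_noise_sd)
  stopifnot_msg(all(sds >= 0), "sd parameters must be >= 0")
  stopifnot_msg(cfg$spatial_bias_amplitude >= 0 && cfg$spatial_bias_amplitude < 1,
                "`spatial_bias_amplitude` must lie in [0, 1)")
  stopifnot_msg(cfg$horizon > cfg$sampling_interval,
                "`horizon` must exceed `sampling_interval`")
  stopifnot_msg(cfg$n0 > 0 && cfg$capacity > cfg$n0,
                "need capacity > n0 > 0")
  stopifnot_msg(length(cfg$conditions) == 2, "exactly two conditions expected")
  stopifnot_msg(cfg$n_library_controls >= 2 &&
                  cfg$n_library_controls < cfg$n_strains,
                "need 2 <= n_library_controls < n_strains")
  invisible(cfg)
}

stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg, class = "colonyscreen_error")
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d strains on %dx%d plates, %d runs, conditions: %s\n",
              x$n_strains, x$n_rows, x$n_cols, x$n_runs,
              paste(x$conditions, collapse = " / ")))
  cat(sprintf("  effects: %.1f%% tolerant (mean %.2f), %.1f%% sensitive (mean %.2f)\n",
              100 * x$fraction_tolerant, x$tolerant_effect_mean,
              100 * x$fraction_sensitive, x$sensitive_effect_mean))
  cat(sprintf("  bias amplitude %.2f, batch sd %.3f, replicate noise sd %.3f\n",
              x$spatial_bias_amplitude, x$plate_batch_sd, x$replicate_noise_sd))
  invisible(x)
}
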