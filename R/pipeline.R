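#' Run the screen analysis pipeline end to end
#'
#' Simulates (or accepts) a screen, then runs the full analysis chain:
#' feature table -> spatial normalization (LSC) -> plate-median batch
#' correction -> per-replicate LPI -> hit calling with the IQR null, Welch
#' test, BH adjustment, control envelope and non-grower rescue -> replicate
#' concordance. Control strains for the envelope are the library strains with
#' non-targeting guides plus the spatial control strain.
#'
#' @param config A [sim_config()]; ignored if `sim` is supplied.
#' @param sim Optionally a pre-built `"colony_screen_sim"` object.
#' @param bandwidth Spatial surface bandwidth, grid units.
#' @param alpha FDR threshold.
#' @param welch_mode,null_on Passed to [call_screen()].
#' @param out_dir Optional directory; when given, phenotypes and calls TSVs
#'   and a JSON run report are written there.
#' @return A list of class `"screen_report"`: `calls`, `phenotypes` (the
#'   per-replicate LPI table), `lsc`, `truth`, `concordance`,
#'   `concordance_called`, `summary` (the JSON-ready report list), `config`.
#' @examples
#' \donttest{
#' rep <- run_screen_pipeline(sim_config(n_strains = 96, n_rows = 16,
#'                                       n_cols = 24, seed = 2))
#' rep$summary$counts
#' }
#' @export
run_screen_pipeline <- function(config = sim_config(), sim = NULL,
                                bandwidth = 4, alpha = 0.1,
                                welch_mode = "two-sample",
                                null_on = "replicates",
                                out_dir = NULL) {
  if (is.null(sim)) sim <- simulate_screen(config)
  config <- sim$config

  lsc <- compute_lsc(sim$features, bandwidth = bandwidth)
  lsc <- batch_correct(lsc)
  lpi <- compute_lpi(lsc, conditions = config$conditions)

  controls <- c(sim$truth$strain_id[sim$truth$class == "library_control"],
                config$control_id)
  calls <- call_screen(lpi, controls = controls, alpha = alpha,
                       welch_mode = welch_mode, null_on = null_on)

  conc <- tryCatch(replicate_concordance(lpi), error = function(e) NULL)
  called <- calls$strain_id[calls$call %in%
                              c("tolerant", "sensitive",
                                "nongrower_sensitive")]
  conc_called <- tryCatch(replicate_concordance(lpi, subset = called),
                          error = function(e) NULL)

  null <- attr(calls, "null"); env <- attr(calls, "envelope")
  summary <- list(
    tool = "colonyscreen", version = as.character(utils::packageVersion("colonyscreen")),
    seed = config$seed,
    parameters = list(bandwidth = bandwidth, alpha = alpha,
                      welch_mode = welch_mode, null_on = null_on),
    iqr_bounds = c(null$q1, null$q3),
    null_mean = null$null_mean,
    envelope = c(env$t_tolerant, env$t_sensitive),
    counts = as.list(table(calls$call)),
    n_strains = nrow(calls),
    concordance = conc, concordance_called = conc_called
  )

  out <- structure(list(calls = calls, phenotypes = lpi, lsc = lsc,
                        truth = sim$truth, concordance = conc,
                        concordance_called = conc_called,
                        summary = summary, config = config),
                   class = "screen_report")
  if (!is.null(out_dir)) write_screen_report(out, out_dir)
  out
}

#' Write pipeline outputs to disk
#'
#' Writes `phenotypes.tsv` (per-replicate LPI), `calls.tsv` and
#' `report.json` into `out_dir`.
#'
#' @param report A `"screen_report"` from [run_screen_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_screen_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$phenotypes, file.path(out_dir, "phenotypes.tsv"),
                   progress = FALSE)
  readr::write_tsv(dplyr::as_tibble(report$calls),
                   file.path(out_dir, "calls.tsv"), progress = FALSE)
  jsonlite::write_json(report$summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  cat(sprintf("  IQR null [%.4g, %.4g]; envelope [%.4g, %.4g]\n",
              x$summary$iqr_bounds[1], x$summary$iqr_bounds[2],
              x$summary$envelope[1], x$summary$envelope[2]))
  cnt <- unlist(x$summary$counts)
  cat(sprintf("  calls: %s\n",
              paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", ")))
  if (!is.null(x$concordance)) {
    cat(sprintf("  run concordance: r = %.3f, R^2 = %.3f (all strains)\n",
                x$concordance$pearson_r, x$concordance$r_squared))
  }
  invisible(x)
}
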