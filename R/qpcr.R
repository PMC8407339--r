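#' Relative expression from qPCR cycle thresholds
#'
#' Normalizes target-gene CT values against the geometric mean of the
#' reference-gene CTs (computed on the cycle scale) and converts to relative
#' expression assuming perfect doubling per cycle:
#' `rel_expr = 2^(geomean(ct_refs) - ct_target)`. A target amplifying one
#' cycle later than the references is half as abundant (`rel_expr = 0.5`).
#'
#' @param ct Long tibble with columns `sample_id`, `strain_id`, `condition`,
#'   `gene`, `ct` (cycles, finite and positive).
#' @param ref_genes Character vector of reference gene names (e.g. ACT1 and
#'   IPP1); every sample must have a CT for each.
#' @return One row per (sample, non-reference gene): input keys plus
#'   `delta_ct` and `rel_expr`.
#' @examples
#' ct <- tibble::tibble(sample_id = "s1", strain_id = "X", condition = "basal",
#'                      gene = c("ACT1", "IPP1", "TDH3"), ct = c(20, 22, 21))
#' delta_ct(ct, ref_genes = c("ACT1", "IPP1"))
#' @export
delta_ct <- function(ct, ref_genes) {
  needed <- c("sample_id", "strain_id", "condition", "gene", "ct")
  stopifnot_msg(all(needed %in% names(ct)),
                paste("`ct` needs columns:", paste(needed, collapse = ", ")))
  stopifnot_msg(all(is.finite(ct$ct) & ct$ct > 0),
                "all CT values must be finite and > 0")
  refs <- ct |>
    dplyr::filter(.data$gene %in% ref_genes) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_refs = dplyr::n(),
                     ref_geomean = exp(mean(log(.data$ct))),
                     .groups = "drop")
  bad <- refs$sample_id[refs$n_refs < length(ref_genes)]
  if (length(bad) > 0 || !all(unique(ct$sample_id) %in% refs$sample_id)) {
    rlang::abort("missing reference CT for some sample(s)",
                 class = "colonyscreen_error")
  }
  ct |>
    dplyr::filter(!.data$gene %in% ref_genes) |>
    dplyr::left_join(refs[c("sample_id", "ref_geomean")], by = "sample_id") |>
    dplyr::mutate(delta_ct = .data$ref_geomean - .data$ct,
                  rel_expr = 2^.data$delta_ct) |>
    dplyr::select(dplyr::all_of(c("sample_id", "strain_id", "condition",
                                  "gene")), "delta_ct", "rel_expr")
}

#' Compare relative expression of a strain against pooled controls
#'
#' The two-step test used for qPCR validation: an F test of the variance
#' ratio decides whether a pooled-variance or an unequal-variance (Welch)
#' two-tailed t test is used for the difference in mean `2^dCT` between the
#' pooled control replicates and the strain's replicates. Percent change is
#' computed against the pooled control mean.
#'
#' @param control_expr Numeric vector of control replicate `rel_expr` values
#'   (all control strains pooled), >= 2.
#' @param strain_expr Numeric vector of the strain's replicate values, >= 2.
#' @param alpha_var Significance threshold of the (two-tailed) F test below
#'   which the Welch test is used (default 0.05).
#' @return A list: `pct_change` (vs pooled control mean), `p_value`,
#'   `variance_test_p`, `equal_variance` (branch taken), `degenerate`
#'   (both groups constant with unequal means: p is reported as 0 and
#'   flagged).
#' @examples
#' compare_expression(c(1.0, 1.1, 0.9), c(0.07, 0.08))
#' @export
compare_expression <- function(control_expr, strain_expr, alpha_var = 0.05) {
  stopifnot_msg(length(control_expr) >= 2 && length(strain_expr) >= 2,
                "need >= 2 replicates per group")
  pct <- (mean(strain_expr) / mean(control_expr) - 1) * 100
  vc <- var(control_expr); vs <- var(strain_expr)
  if (vc == 0 && vs == 0) {
    same <- mean(control_expr) == mean(strain_expr)
    return(list(pct_change = pct, p_value = if (same) 1 else 0,
                variance_test_p = NA_real_, equal_variance = TRUE,
                degenerate = !same))
  }
  fp <- stats::var.test(strain_expr, control_expr)$p.value
  eq <- fp >= alpha_var
  tt <- stats::t.test(strain_expr, control_expr, var.equal = eq)
  list(pct_change = pct, p_value = tt$p.value, variance_test_p = fp,
       equal_variance = eq, degenerate = FALSE)
}

#' Expression-change versus growth-change correlation
#'
#' For a set of strains targeting the same gene with guides of different
#' strength, reports the Pearson correlation between the percent change in
#' target expression and the percent change in relative generation time --
#' the quantity used to judge whether a phenotype tracks the degree of
#' knockdown.
#'
#' @param expr_change,growth_change Numeric vectors, one entry per strain.
#' @return A list `pearson_r`, `n`.
#' @export
expression_growth_correlation <- function(expr_change, growth_change) {
  stopifnot_msg(length(expr_change) == length(growth_change),
                "vectors must have equal length")
  ok <- is.finite(expr_change) & is.finite(growth_change)
  stopifnot_msg(sum(ok) >= 3, "need >= 3 complete strain pairs")
  list(pearson_r = cor(expr_change[ok], growth_change[ok]), n = sum(ok))
}

#' qPCR comparison table across strains
#'
#' Convenience wrapper running [compare_expression()] for every
#' (strain, condition) against the pooled control replicates of the same
#' condition.
#'
#' @param rel Output of [delta_ct()].
#' @param controls Character vector of control strain ids (pooled baseline).
#' @param alpha_var Passed to [compare_expression()].
#' @return A tibble per strain x condition x gene with `n_replicates`,
#'   `mean_rel_expr`, `pct_change`, `p_value`, `variance_test_p`,
#'   `equal_variance`.
#' @export
qpcr_compare_all <- function(rel, controls, alpha_var = 0.05) {
  ctrl <- dplyr::filter(rel, .data$strain_id %in% controls)
  stopifnot_msg(nrow(ctrl) >= 2, "need pooled control replicates")
  rel |>
    dplyr::filter(!.data$strain_id %in% controls) |>
    dplyr::group_by(.data$strain_id, .data$condition, .data$gene) |>
    dplyr::group_modify(function(d, g) {
      base <- ctrl$rel_expr[ctrl$condition == g$condition &
                              ctrl$gene == g$gene]
      if (length(base) < 2) base <- ctrl$rel_expr[ctrl$condition == g$condition]
      cmp <- compare_expression(base, d$rel_expr, alpha_var = alpha_var)
      tibble::tibble(n_replicates = nrow(d),
                     mean_rel_expr = mean(d$rel_expr),
                     pct_change = cmp$pct_change, p_value = cmp$p_value,
                     variance_test_p = cmp$variance_test_p,
                     equal_variance = cmp$equal_variance)
    }) |>
    dplyr::ungroup()
}
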