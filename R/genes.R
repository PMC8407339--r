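#' Aggregate strain calls to genes
#'
#' Each CRISPRi strain carries one guide RNA targeting one gene; several
#' strains usually target the same gene with guides of different strength.
#' This summary counts, per gene, how many strains were called tolerant or
#' sensitive and reports the range of percent change in generation time over
#' the called strains, converting the mean LPI with
#' `percent = (2^mean_lpi - 1) * 100`. Strains rescued by the non-grower rule
#' count as sensitive and are reported as complete inhibition.
#'
#' @param calls A `"screen_calls"` tibble from [call_screen()].
#' @param guide_map Data frame mapping `strain_id` to `gene_id`; every called
#'   strain must map to exactly one gene.
#' @return A tibble per gene: `gene_id`, `n_strains_total`, `n_tolerant`,
#'   `n_sensitive` (includes non-grower rescues), `n_complete_inhibition`,
#'   `pct_change_min`, `pct_change_max` (over called strains with a numeric
#'   LPI; `NA` when none).
#' @examples
#' # two tolerant guides for one gene
#' gm <- data.frame(strain_id = c("a", "b"), gene_id = "G1")
#' @export
aggregate_genes <- function(calls, guide_map) {
  stopifnot_msg(all(c("strain_id", "gene_id") %in% names(guide_map)),
                "`guide_map` needs columns strain_id, gene_id")
  dup <- guide_map$strain_id[duplicated(guide_map$strain_id)]
  stopifnot_msg(length(dup) == 0,
                paste("strains mapped to several genes:",
                      paste(unique(dup), collapse = ", ")))
  missing <- setdiff(calls$strain_id, guide_map$strain_id)
  if (length(missing) > 0) {
    rlang::abort(paste("unmapped strain(s):",
                       paste(head(missing, 10), collapse = ", ")),
                 class = "colonyscreen_error")
  }
  hit <- c("tolerant", "sensitive", "nongrower_sensitive")
  dplyr::as_tibble(calls) |>
    dplyr::left_join(guide_map[c("strain_id", "gene_id")], by = "strain_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_strains_total = dplyr::n(),
      n_tolerant = sum(.data$call == "tolerant"),
      n_sensitive = sum(.data$call %in%
                          c("sensitive", "nongrower_sensitive")),
      n_complete_inhibition = sum(.data$call == "nongrower_sensitive"),
      pct_change_min = safe_range(lpi_to_percent(
        .data$mean_lpi[.data$call %in% hit]), min),
      pct_change_max = safe_range(lpi_to_percent(
        .data$mean_lpi[.data$call %in% hit]), max),
      .groups = "drop")
}

safe_range <- function(v, f) {
  v <- v[is.finite(v)]
  if (length(v) == 0) NA_real_ else f(v)
}

#' Convert a log phenotypic index to percent change in generation time
#'
#' `(2^lpi - 1) * 100`: an LPI of 1 doubles the generation time (+100%), an
#' LPI of -0.1 shortens it by 6.7%.
#'
#' @param lpi Numeric vector of LPI values (log2 scale).
#' @return Percent change in generation time.
#' @examples
#' lpi_to_percent(c(-0.2, -0.1, 0, 1))
#' @export
lpi_to_percent <- function(lpi) (2^lpi - 1) * 100

#' Concordance of strain means between two independent runs
#'
#' Pearson correlation and coefficient of determination of per-strain mean
#' LPI between the two runs of a duplicated screen, optionally restricted to
#' a subset of strains (e.g. the called hits, whose concordance is expected
#' to be far higher than that of the full library, which is dominated by
#' strains with no true effect).
#'
#' @param lpi_tbl Per-replicate LPI tibble with `strain_id`, `run`, `lpi_gt`.
#' @param runs Length-2 vector naming the runs to compare.
#' @param subset Optional character vector of strain ids to keep.
#' @return A list `pearson_r`, `r_squared`, `n_strains`, `degenerate`
#'   (`TRUE` when either run's means have zero variance, in which case the
#'   statistics are `NA`).
#' @export
replicate_concordance <- function(lpi_tbl, runs = NULL, subset = NULL) {
  if (is.null(runs)) runs <- sort(unique(lpi_tbl$run))[1:2]
  stopifnot_msg(length(runs) == 2 && all(runs %in% lpi_tbl$run),
                "two valid runs required")
  d <- lpi_tbl |>
    dplyr::filter(.data$run %in% runs, is.finite(.data$lpi_gt))
  if (!is.null(subset)) d <- dplyr::filter(d, .data$strain_id %in% subset)
  wide <- d |>
    dplyr::group_by(.data$strain_id, .data$run) |>
    dplyr::summarise(m = mean(.data$lpi_gt), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "run", values_from = "m",
                       names_prefix = "run_") |>
    tidyr::drop_na()
  stopifnot_msg(nrow(wide) >= 3, "need >= 3 strains present in both runs")
  x <- wide[[2]]; y <- wide[[3]]
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(pearson_r = NA_real_, r_squared = NA_real_,
                n_strains = nrow(wide), degenerate = TRUE))
  }
  r <- cor(x, y)
  list(pearson_r = r, r_squared = r^2, n_strains = nrow(wide),
       degenerate = FALSE)
}
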