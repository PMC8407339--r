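#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a screen-calls table
#'
#' Returns the per-strain call table as a plain tibble (one row per library
#' strain with its mean LPI, Welch statistic, raw and adjusted p value and
#' classification), with the percent change in generation time added.
#'
#' @param x A `"screen_calls"` object from [call_screen()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.screen_calls <- function(x, ...) {
  tibble::as_tibble(unclass_calls(x)) |>
    dplyr::mutate(pct_gt_change = lpi_to_percent(.data$mean_lpi))
}

#' One-row summary of a screen
#'
#' @param x A `"screen_calls"` object.
#' @param ... Unused.
#' @return A one-row tibble: strain counts per call class, the IQR null
#'   bounds, the control envelope and the FDR threshold used.
#' @export
glance.screen_calls <- function(x, ...) {
  null <- attr(x, "null"); env <- attr(x, "envelope")
  tibble::tibble(
    n_strains = nrow(x),
    n_tolerant = sum(x$call == "tolerant"),
    n_sensitive = sum(x$call == "sensitive"),
    n_nongrower_sensitive = sum(x$call == "nongrower_sensitive"),
    n_basal_dead = sum(x$call == "basal_dead"),
    n_unchanged = sum(x$call == "unchanged"),
    iqr_lower = null$q1, iqr_upper = null$q3, null_mean = null$null_mean,
    envelope_tolerant = env$t_tolerant, envelope_sensitive = env$t_sensitive,
    alpha = attr(x, "alpha")
  )
}

unclass_calls <- function(x) {
  attr(x, "null") <- NULL; attr(x, "envelope") <- NULL
  attr(x, "alpha") <- NULL; attr(x, "welch_mode") <- NULL
  attr(x, "null_on") <- NULL; attr(x, "n_controls") <- NULL
  class(x) <- setdiff(class(x), "screen_calls")
  x
}
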