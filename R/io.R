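curve_schema <- c("plate_id", "row", "col", "run", "condition",
                  "time_h", "value")
layout_schema <- c("plate_id", "row", "col", "strain_id", "is_control",
                   "replicate_index")

read_table_checked <- function(path, schema, numeric_cols) {
  stopifnot_msg(file.exists(path), paste("file not found:", path))
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE,
                          delim = if (grepl("\\.tsv(\\.gz)?$", path)) "\t"
                                  else ",")
  miss <- setdiff(schema, names(df))
  if (length(miss) > 0) {
    rlang::abort(paste("missing column(s):", paste(miss, collapse = ", ")),
                 class = "colonyscreen_parse_error")
  }
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad) > 0) {
      rlang::abort(sprintf("non-numeric value in column `%s`, row %d",
                           cc, bad[1]),
                   class = "colonyscreen_parse_error")
    }
    df[[cc]] <- v
  }
  df
}

#' Read a long-format curves file
#'
#' CSV/TSV (gzip-transparent) with columns `plate_id, row, col, run,
#' condition, time_h, value`. Rows are sorted by time within each colony;
#' duplicated time points within a colony are an error.
#'
#' @param path File path.
#' @return A tibble of curves.
#' @export
read_curves <- function(path) {
  df <- read_table_checked(path, curve_schema,
                           c("row", "col", "run", "time_h", "value"))
  df <- dplyr::arrange(df, .data$plate_id, .data$row, .data$col, .data$run,
                       .data$condition, .data$time_h)
  key <- paste(df$plate_id, df$row, df$col, df$run, df$condition, df$time_h)
  if (anyDuplicated(key)) {
    rlang::abort("duplicated (colony, time) row(s) (parse error)",
                 class = "colonyscreen_parse_error")
  }
  df
}

#' Write a curves table
#' @param curves Tibble as produced by [simulate_screen()]'s `curves`.
#' @param path Output path; `.tsv` writes tab-separated, `.gz` compresses.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  write_any(curves[intersect(c(curve_schema, "strain_id"), names(curves))],
            path)
}

#' Read / write a plate layout
#'
#' Layout files are CSV/TSV with columns `plate_id, row, col, strain_id,
#' is_control, replicate_index` (0-based row/col).
#'
#' @param path File path.
#' @return A layout tibble.
#' @export
read_layout <- function(path) {
  df <- read_table_checked(path, layout_schema, c("row", "col"))
  df$is_control <- as.logical(df$is_control)
  df$replicate_index <- suppressWarnings(as.integer(df$replicate_index))
  df$row <- as.integer(df$row); df$col <- as.integer(df$col)
  key <- paste(df$plate_id, df$row, df$col)
  if (anyDuplicated(key)) {
    rlang::abort("duplicated plate position(s) (parse error)",
                 class = "colonyscreen_parse_error")
  }
  dplyr::arrange(df, .data$plate_id, .data$row, .data$col)
}

#' @rdname read_layout
#' @param layout Layout tibble from [make_layout()].
#' @export
write_layout <- function(layout, path) write_any(layout, path)

write_any <- function(df, path) {
  if (grepl("\\.tsv(\\.gz)?$", path)) {
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Ingest a deposited per-strain phenotype table
#'
#' Reads a per-strain LSC/LPI spreadsheet or delimited table (such as the
#' supplementary tables screens of this kind deposit) into the per-replicate
#' LPI format that [call_screen()] consumes. Because column naming varies
#' between deposits, a mapping must be supplied: the strain-id column and the
#' columns holding the per-replicate LPI values (wide format, one column per
#' replicate). Strains whose LPI replicates are all missing are kept and end
#' up untestable downstream, never silently dropped.
#'
#' @param path `.csv`, `.tsv` or `.xlsx` file (xlsx needs the readxl
#'   package).
#' @param strain_col Name of the strain identifier column.
#' @param lpi_cols Character vector of per-replicate LPI column names.
#' @param gene_col Optional gene identifier column to carry through.
#' @return A tibble `strain_id`, (`gene_id`,) `replicate_index`, `lpi_gt`,
#'   `stress_nongrower`, `basal_nongrower` (the flags default to `FALSE`:
#'   deposited tables carry numeric phenotypes only).
#' @export
read_deposited_tables <- function(path, strain_col, lpi_cols,
                                  gene_col = NULL) {
  stopifnot_msg(file.exists(path), paste("file not found:", path))
  df <- if (grepl("\\.xlsx$", path)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      rlang::abort("reading .xlsx requires the readxl package")
    }
    readxl::read_excel(path)
  } else {
    readr::read_delim(path, show_col_types = FALSE, progress = FALSE,
                      delim = if (grepl("\\.tsv$", path)) "\t" else ",")
  }
  miss <- setdiff(c(strain_col, lpi_cols, gene_col), names(df))
  if (length(miss) > 0) {
    rlang::abort(paste("unmapped column(s):", paste(miss, collapse = ", ")),
                 class = "colonyscreen_config_error")
  }
  out <- df |>
    dplyr::select(strain_id = dplyr::all_of(strain_col),
                  gene_id = dplyr::all_of(gene_col %||% character(0)),
                  dplyr::all_of(lpi_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(lpi_cols), names_to = "replicate",
                        values_to = "lpi_gt") |>
    dplyr::mutate(replicate_index = match(.data$replicate, lpi_cols),
                  lpi_gt = suppressWarnings(as.numeric(.data$lpi_gt)),
                  stress_nongrower = FALSE, basal_nongrower = FALSE) |>
    dplyr::select(-"replicate")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
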