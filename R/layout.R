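#' Build plate layouts for a colony-array screen
#'
#' Arranges library strains on 1536-format plates (or any even-dimensioned
#' grid) in the standard interleaved-control design: the grid is tiled with
#' 2 x 2 blocks, each block holds the three adjacent replicates of one library
#' strain plus one position for the spatial control strain, so exactly one
#' quarter of all positions carry the control. Strains fill blocks in input
#' order, row-major, plate by plate; blocks left over on the last plate are
#' filled entirely with the control strain.
#'
#' @param strains Character vector of library strain identifiers, in the order
#'   they should be placed.
#' @param n_rows,n_cols Grid dimensions, both even (default 32 x 48 = 1536).
#' @param control_id Identifier of the spatial control strain.
#' @param n_plates Optional fixed number of plates; an error is raised if the
#'   strains do not fit.
#'
#' @return A tibble with one row per grid position and columns `plate_id`,
#'   `row`, `col` (0-based), `strain_id`, `is_control`, `replicate_index`
#'   (1-3 for library strains, `NA` for control positions).
#' @examples
#' lay <- make_layout(sprintf("S%03d", 1:384))
#' nrow(lay)                      # 1536
#' sum(lay$is_control)            # 384: every fourth position
#' @export
make_layout <- function(strains, n_rows = 32, n_cols = 48,
                        control_id = "CTRL", n_plates = NULL) {
  stopifnot_msg(length(strains) >= 1, "at least one strain required")
  stopifnot_msg(!anyDuplicated(strains), "strain identifiers must be unique")
  stopifnot_msg(!control_id %in% strains,
                "`control_id` must not appear among library strains")
  stopifnot_msg(n_rows %% 2 == 0 && n_cols %% 2 == 0,
                "grid dimensions must be even (layout error)")

  blocks_per_plate <- (n_rows * n_cols) %/% 4L
  need <- ceiling(length(strains) / blocks_per_plate)
  if (is.null(n_plates)) {
    n_plates <- need
  } else if (n_plates < need) {
    rlang::abort(
      sprintf("%d strains do not fit on %d plate(s) of %d blocks (capacity error)",
              length(strains), n_plates, blocks_per_plate),
      class = "colonyscreen_capacity_error")
  }

  ## within each 2x2 block: three strain replicates + control at the
  ## odd-row/odd-col ("fourth") position
  block_rows <- rep(seq_len(n_rows / 2) - 1L, each = n_cols / 2)
  block_cols <- rep(seq_len(n_cols / 2) - 1L, times = n_rows / 2)

  one_plate <- function(plate_idx) {
    first <- (plate_idx - 1L) * blocks_per_plate + 1L
    ids <- strains[seq(first, length.out = blocks_per_plate)]
    ids[is.na(ids)] <- control_id           # spare blocks on the last plate
    filler <- ids == control_id
    tibble::tibble(
      plate_id = sprintf("P%02d", plate_idx),
      row = rep(2L * block_rows, times = 4) +
        rep(c(0L, 0L, 1L, 1L), each = blocks_per_plate),
      col = rep(2L * block_cols, times = 4) +
        rep(c(0L, 1L, 0L, 1L), each = blocks_per_plate),
      strain_id = c(ids, ids, ids, rep(control_id, blocks_per_plate)),
      is_control = c(filler, filler, filler, rep(TRUE, blocks_per_plate)),
      replicate_index = c(ifelse(filler, NA_integer_, 1L),
                          ifelse(filler, NA_integer_, 2L),
                          ifelse(filler, NA_integer_, 3L),
                          rep(NA_integer_, blocks_per_plate))
    )
  }

  purrr::map(seq_len(n_plates), one_plate) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$plate_id, .data$row, .data$col)
}
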