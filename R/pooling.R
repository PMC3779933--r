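#' Build the pooled screening design
#'
#' Lays `n_clones` out on 96-well source plates (95 clones + 1 negative
#' control well per plate, plate-major order) and pools `plates_per_pool`
#' source plates onto one assay plate: source well `w` of every plate in the
#' pool lands in assay well `w`, so each assay well receives up to
#' `plates_per_pool` different clones (16 by default, i.e. 16 x 95 = 1520
#' clones per assay plate). Control wells map to the control well of the
#' assay plate. A ragged final pool simply holds fewer clones per well.
#'
#' @param n_clones Number of clones to screen.
#' @param plates_per_pool Source plates pooled per assay plate (default 16).
#' @param wells_per_plate Wells per plate (default 96).
#' @param clones_per_plate Clones per source plate (default 95); the last
#'   row-major well (H12) is the negative control.
#' @param rounds_per_day Pooling rounds processed per day (default 8); only
#'   used by [verify_design_arithmetic()].
#' @param n_substrates Number of assays per clone (default 14).
#' @param clone_ids Optional clone id vector (default `clone_00001`, ...,
#'   matching [build_library()]).
#' @return A `pooling_design`: a tibble with one row per clone plus one
#'   control row (`clone_id` `NA`) per assay plate, columns `clone_id`,
#'   `source_plate`, `source_well`, `assay_plate`, `assay_well`, and the
#'   design parameters as attributes.
#' @examples
#' d <- build_pooling_design(1520)
#' dplyr::count(d[!is.na(d$clone_id), ], assay_plate, assay_well)
#' @export
build_pooling_design <- function(n_clones,
                                 plates_per_pool = 16,
                                 wells_per_plate = 96,
                                 clones_per_plate = 95,
                                 rounds_per_day = 8,
                                 n_substrates = 14,
                                 clone_ids = NULL) {
  n_clones <- check_count(n_clones, "n_clones")
  plates_per_pool <- check_count(plates_per_pool, "plates_per_pool")
  wells_per_plate <- check_count(wells_per_plate, "wells_per_plate")
  clones_per_plate <- check_count(clones_per_plate, "clones_per_plate")
  if (clones_per_plate > wells_per_plate) {
    abort("`clones_per_plate` cannot exceed `wells_per_plate`.",
          class = "screenbin_invalid_parameter")
  }
  if (is.null(clone_ids)) clone_ids <- sprintf("clone_%05d", seq_len(n_clones))
  stopifnot(length(clone_ids) == n_clones)

  wl <- well_labels()[seq_len(wells_per_plate)]
  plate_wells <- wl[seq_len(clones_per_plate)]
  control_well <- if (clones_per_plate < wells_per_plate) {
    wl[clones_per_plate + 1L]
  } else NA_character_

  i <- seq_len(n_clones)
  source_plate_n <- (i - 1L) %/% clones_per_plate + 1L
  assay_plate_n <- (source_plate_n - 1L) %/% plates_per_pool + 1L
  design <- tibble(
    clone_id = clone_ids,
    source_plate = sprintf("SP%03d", source_plate_n),
    source_well = plate_wells[(i - 1L) %% clones_per_plate + 1L],
    assay_plate = sprintf("AP%03d", assay_plate_n),
    assay_well = .data$source_well)
  if (!is.na(control_well)) {
    controls <- tibble(
      clone_id = NA_character_,
      source_plate = NA_character_,
      source_well = NA_character_,
      assay_plate = sprintf("AP%03d", unique(assay_plate_n)),
      assay_well = control_well)
    design <- bind_rows(design, controls)
  }
  structure(design,
            class = c("pooling_design", class(design)),
            plates_per_pool = plates_per_pool,
            wells_per_plate = wells_per_plate,
            clones_per_plate = clones_per_plate,
            rounds_per_day = check_count(rounds_per_day, "rounds_per_day"),
            n_substrates = check_count(n_substrates, "n_substrates"),
            control_well = control_well)
}

#' Build the expansion (confirmation) design
#'
#' After deconvolution, candidate clones are expanded one clone per well onto
#' fresh assay plates and screened individually. The returned design has the
#' same shape as [build_pooling_design()] with a pool factor of 1.
#'
#' @param clone_ids Character vector of candidate clone ids.
#' @param clones_per_plate Clones per expansion plate (default 95; last well
#'   is a negative control).
#' @param wells_per_plate Wells per plate (default 96).
#' @return A `pooling_design` tibble whose assay wells hold exactly one clone.
#' @export
build_expansion_design <- function(clone_ids, clones_per_plate = 95,
                                   wells_per_plate = 96) {
  clone_ids <- unique(clone_ids)
  n <- length(clone_ids)
  if (n == 0) {
    abort("No candidate clones to expand.",
          class = "screenbin_invalid_parameter")
  }
  d <- build_pooling_design(n, plates_per_pool = 1,
                            wells_per_plate = wells_per_plate,
                            clones_per_plate = clones_per_plate,
                            clone_ids = clone_ids)
  d$assay_plate <- sub("^AP", "EP", d$assay_plate)
  d
}
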