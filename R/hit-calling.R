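#' Call positive wells with the mean + k*SD plate rule
#'
#' For every (plate, substrate, timepoint) group the threshold is
#' `mean + sd_multiplier * sd` computed over *all* wells of that plate,
#' negative controls included. A well is designated positive when its signal
#' exceeds the threshold (strictly, by default) at any timepoint (rule
#' `"any"`). Visual (solid-media) readings are binary and bypass the
#' threshold: any value above zero is positive.
#'
#' Wells whose signal clears the threshold by less than 10% of the threshold
#' are additionally flagged `near_threshold`; such borderline activities are
#' the ones that typically fail to reproduce on re-screening (see
#' [confirm_clones()]).
#'
#' @param readings A readings tibble with columns `plate_id`, `well`,
#'   `substrate`, `timepoint`, `modality`, `value`.
#' @param sd_multiplier Number of standard deviations above the plate mean
#'   (default 2).
#' @param combine_timepoints `"any"` (default: positive at any timepoint),
#'   `"all"`, or the name of a single timepoint.
#' @param strict Use strict inequality `value > threshold` (default) rather
#'   than `>=`.
#' @param sd_type `"population"` (divide by n; the plate's wells are the
#'   entire population under test; default) or `"sample"` (divide by n - 1).
#' @return A `hit_table` tibble with one row per (plate, well, substrate):
#'   columns `plate_id`, `well`, `substrate`, `modality`, `max_value`,
#'   `positive`, `near_threshold`. The per-(plate, substrate, timepoint)
#'   thresholds are attached as an attribute; retrieve them with
#'   [hit_thresholds()].
#' @examples
#' r <- tibble::tibble(plate_id = "AP001", well = well_ids <- paste0("A", 1:4),
#'   substrate = "s", timepoint = "24h", modality = "absorbance",
#'   value = c(1, 1, 1, 10))
#' call_hits(r)
#' @export
call_hits <- function(readings, sd_multiplier = 2,
                      combine_timepoints = "any", strict = TRUE,
                      sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (sd_multiplier <= 0) {
    abort("`sd_multiplier` must be positive.",
          class = "screenbin_invalid_parameter")
  }
  if (!all(is.finite(readings$value))) {
    abort("Readings contain non-finite values.",
          class = "screenbin_data_error")
  }
  sd_fun <- if (sd_type == "population") sd_pop else stats::sd

  grouped <- readings |>
    group_by(.data$plate_id, .data$substrate, .data$timepoint)
  small <- grouped |>
    summarise(n_wells = n(), modality = first(.data$modality),
              .groups = "drop") |>
    filter(.data$n_wells < 2, .data$modality != "visual")
  if (nrow(small) > 0) {
    abort(sprintf("%d plate/substrate/timepoint group(s) have < 2 wells.",
                  nrow(small)), class = "screenbin_insufficient_data")
  }

  thresholds <- grouped |>
    summarise(modality = first(.data$modality),
              n_wells = n(),
              mean = mean(.data$value),
              sd = sd_fun(.data$value),
              .groups = "drop") |>
    mutate(threshold = if_else(.data$modality == "visual", NA_real_,
                               .data$mean + sd_multiplier * .data$sd))

  scored <- readings |>
    left_join(thresholds |>
                select("plate_id", "substrate", "timepoint", "threshold"),
              by = c("plate_id", "substrate", "timepoint")) |>
    mutate(pos_tp = if_else(
      .data$modality == "visual", .data$value > 0,
      if (strict) .data$value > .data$threshold
      else .data$value >= .data$threshold),
      excess = if_else(.data$modality == "visual", Inf,
                       .data$value - .data$threshold))

  combine <- function(pos, tp) {
    if (combine_timepoints == "any") any(pos)
    else if (combine_timepoints == "all") all(pos)
    else any(pos[tp == combine_timepoints])
  }
  hits <- scored |>
    group_by(.data$plate_id, .data$well, .data$substrate) |>
    summarise(modality = first(.data$modality),
              max_value = max(.data$value),
              positive = combine(.data$pos_tp, .data$timepoint),
              near_threshold = .data$positive & is.finite(max(.data$excess)) &
                max(.data$excess) < 0.1 * abs(first(.data$threshold)),
              .groups = "drop") |>
    mutate(near_threshold = tidyr::replace_na(.data$near_threshold, FALSE))

  structure(hits, class = c("hit_table", class(hits)),
            thresholds = thresholds,
            params = list(sd_multiplier = sd_multiplier,
                          combine_timepoints = combine_timepoints,
                          strict = strict, sd_type = sd_type))
}

#' Thresholds used by a hit call
#'
#' @param hits A `hit_table` from [call_hits()].
#' @return A tibble with one row per (plate, substrate, timepoint): `n_wells`,
#'   `mean`, `sd`, `threshold` (NA for visual assays).
#' @export
hit_thresholds <- function(hits) attr(hits, "thresholds")

#' Deconvolve positive pooled wells into candidate clones
#'
#' Every clone pooled into a positive assay well is a candidate for the
#' activity that fired there; candidates are expanded and re-screened
#' individually ([build_expansion_design()], [confirm_clones()]). A clone
#' appears once per substrate that fired on its well.
#'
#' @param hits A `hit_table` from [call_hits()] on pooled-plate readings.
#' @param design The [build_pooling_design()] used for pooling.
#' @return A tibble of candidates: `clone_id`, `substrate`, `assay_plate`,
#'   `assay_well`.
#' @export
deconvolve <- function(hits, design) {
  positives <- hits |>
    as_tibble() |>
    filter(.data$positive) |>
    select(assay_plate = "plate_id", assay_well = "well", "substrate")
  if (nrow(positives) == 0) {
    return(tibble(clone_id = character(), substrate = character(),
                  assay_plate = character(), assay_well = character()))
  }
  design_wells <- design |>
    as_tibble() |>
    distinct(.data$assay_plate, .data$assay_well)
  unknown <- positives |>
    distinct(.data$assay_plate, .data$assay_well) |>
    anti_join(design_wells, by = c("assay_plate", "assay_well"))
  if (nrow(unknown) > 0) {
    abort(sprintf("%d positive well(s) are absent from the pooling design.",
                  nrow(unknown)), class = "screenbin_consistency_error")
  }
  positives |>
    inner_join(design |>
                 as_tibble() |>
                 filter(!is.na(.data$clone_id)) |>
                 select("clone_id", "assay_plate", "assay_well"),
               by = c("assay_plate", "assay_well"),
               relationship = "many-to-many") |>
    distinct(.data$clone_id, .data$substrate, .data$assay_plate,
             .data$assay_well)
}

#' Confirm candidate clones on individual expansion plates
#'
#' Applies the same mean + k*SD rule to expansion plates that hold one clone
#' per well; a clone is confirmed for a substrate iff its well is positive.
#' When a second, independently seeded re-screen is supplied, borderline
#' (near-threshold) positives are confirmed only if they reproduce there;
#' confident positives are kept regardless.
#'
#' @param readings Readings of the expansion plates.
#' @param design The [build_expansion_design()] mapping clones to wells (one
#'   clone per well).
#' @param rescreen_readings Optional readings of a second expansion screen
#'   used to adjudicate near-threshold positives.
#' @inheritParams call_hits
#' @return An `activity_profile`: a tibble of confirmed (`clone_id`,
#'   `substrate`) pairs with a `near_threshold` flag; the full set of
#'   screened clones is attached as attribute `"clones"`.
#' @export
confirm_clones <- function(readings, design, rescreen_readings = NULL,
                           sd_multiplier = 2, combine_timepoints = "any",
                           strict = TRUE,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  per_well <- design |>
    as_tibble() |>
    filter(!is.na(.data$clone_id)) |>
    count(.data$assay_plate, .data$assay_well)
  if (any(per_well$n > 1)) {
    abort("Expansion design must hold one clone per well.",
          class = "screenbin_invalid_parameter")
  }
  hits <- call_hits(readings, sd_multiplier = sd_multiplier,
                    combine_timepoints = combine_timepoints,
                    strict = strict, sd_type = sd_type)
  confirmed <- hits |>
    as_tibble() |>
    filter(.data$positive) |>
    inner_join(design |>
                 as_tibble() |>
                 filter(!is.na(.data$clone_id)) |>
                 select("clone_id", assay_plate = "assay_plate",
                        assay_well = "assay_well"),
               by = c(plate_id = "assay_plate", well = "assay_well")) |>
    select("clone_id", "substrate", "near_threshold")

  if (!is.null(rescreen_readings) && any(confirmed$near_threshold)) {
    rehits <- call_hits(rescreen_readings, sd_multiplier = sd_multiplier,
                        combine_timepoints = combine_timepoints,
                        strict = strict, sd_type = sd_type) |>
      as_tibble() |>
      filter(.data$positive) |>
      inner_join(design |>
                   as_tibble() |>
                   filter(!is.na(.data$clone_id)) |>
                   select("clone_id", "assay_plate", "assay_well"),
                 by = c(plate_id = "assay_plate", well = "assay_well")) |>
      distinct(.data$clone_id, .data$substrate) |>
      mutate(reproduced = TRUE)
    confirmed <- confirmed |>
      left_join(rehits, by = c("clone_id", "substrate")) |>
      filter(!.data$near_threshold |
               tidyr::replace_na(.data$reproduced, FALSE)) |>
      select(-"reproduced")
  }
  activity_profile(confirmed,
                   clones = unique(design$clone_id[!is.na(design$clone_id)]))
}

#' Construct an activity profile
#'
#' A set of confirmed (clone, substrate) pairs together with the universe of
#' clones that were screened (needed to distinguish "screened and negative"
#' from "not screened").
#'
#' @param pairs Tibble with columns `clone_id`, `substrate` (extra columns
#'   kept).
#' @param clones Character vector of all screened clone ids.
#' @return An `activity_profile` tibble.
#' @export
activity_profile <- function(pairs, clones) {
  pairs <- as_tibble(pairs)
  if (!all(c("clone_id", "substrate") %in% names(pairs))) {
    abort("`pairs` needs columns `clone_id` and `substrate`.",
          class = "screenbin_invalid_parameter")
  }
  extra <- setdiff(unique(pairs$clone_id), clones)
  if (length(extra) > 0) {
    abort("Profile contains clones outside the screened universe.",
          class = "screenbin_consistency_error")
  }
  structure(pairs, class = c("activity_profile", class(pairs)),
            clones = clones)
}

#' Screened clone universe of an activity profile
#' @param profile An `activity_profile`.
#' @return Character vector of clone ids.
#' @export
profile_clones <- function(profile) attr(profile, "clones")

#' Limit of detection from a dilution series
#'
#' The LOD is the lowest enzyme concentration whose signal exceeds the
#' background measured from negative controls.
#'
#' @param series A data frame with columns `concentration` and `value`,
#'   sorted ascending by concentration.
#' @param background Background signal level.
#' @return The LOD concentration, or `NA` if no point exceeds background.
#' @examples
#' s <- tibble::tibble(concentration = c(0.001, 0.01, 0.1),
#'                     value = c(4.9, 5.1, 9.0))
#' determine_lod(s, background = 5.0)
#' @export
determine_lod <- function(series, background) {
  if (is.null(series) || nrow(series) == 0) {
    abort("Dilution series is empty.",
          class = "screenbin_invalid_parameter")
  }
  if (is.unsorted(series$concentration)) {
    abort("Dilution series must be sorted ascending by concentration.",
          class = "screenbin_invalid_parameter")
  }
  above <- series$value > background
  if (!any(above)) return(NA_real_)
  series$concentration[which(above)[1]]
}
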