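#' Filter an annotation table by e-value
#'
#' Removes records with e-value above the threshold (default 0.1) and,
#' when `best_hit_only`, keeps only the lowest-e-value annotation per ORF.
#' `best_hit_only` applies per ORF, not per clone: a clone keeps several
#' families when they sit on different ORFs.
#'
#' @param annotations Tibble with columns `clone_id`, `orf_id`, `family`,
#'   `evalue`.
#' @param evalue_threshold Maximum e-value retained (default 0.1).
#' @param best_hit_only Keep only the best hit per ORF (default `TRUE`).
#' @return The filtered annotation tibble.
#' @examples
#' a <- tibble::tibble(clone_id = "c", orf_id = c("o1", "o1", "o2"),
#'                     family = c("GH3", "GH1", "GH10"),
#'                     evalue = c(1e-30, 1e-5, 0.2))
#' filter_annotations(a)
#' @export
filter_annotations <- function(annotations, evalue_threshold = 0.1,
                               best_hit_only = TRUE) {
  if (evalue_threshold <= 0) {
    abort("`evalue_threshold` must be positive.",
          class = "screenbin_invalid_parameter")
  }
  if (any(annotations$evalue < 0)) {
    abort("Negative e-values in annotation table.",
          class = "screenbin_data_error")
  }
  out <- annotations |> filter(.data$evalue <= evalue_threshold)
  if (best_hit_only && nrow(out) > 0) {
    out <- out |>
      group_by(.data$clone_id, .data$orf_id) |>
      arrange(.data$evalue, .data$family, .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup()
  }
  out
}

#' Predict activity profiles from annotated enzyme families
#'
#' The predicted substrate set of a clone is the union of the substrates its
#' (filtered) families map to. Families absent from the map -- e.g. lone
#' carbohydrate-binding modules (CBMs), which bind but do not cleave --
#' contribute nothing and are recorded in the `"unmapped"` attribute.
#'
#' @param annotations A filtered annotation tibble (see
#'   [filter_annotations()]).
#' @param map A family-to-substrate map (tibble with `family`, `substrate`),
#'   e.g. [default_family_map()].
#' @param clones Optional character vector fixing the clone universe of the
#'   returned profile (defaults to the clones present in `annotations`).
#' @return An [activity_profile()] of predicted (`clone_id`, `substrate`)
#'   pairs; unmapped family records are in `attr(, "unmapped")`.
#' @export
predict_activities <- function(annotations, map = default_family_map(),
                               clones = NULL) {
  unmapped <- annotations |>
    filter(!(.data$family %in% map$family)) |>
    distinct(.data$clone_id, .data$family)
  if (nrow(unmapped) > 0) {
    inform(sprintf("%d annotation record(s) in %d clone(s) map to no substrate.",
                   nrow(unmapped), length(unique(unmapped$clone_id))))
  }
  pairs <- annotations |>
    inner_join(map, by = "family", relationship = "many-to-many") |>
    distinct(.data$clone_id, .data$substrate)
  universe <- clones %||% unique(annotations$clone_id)
  out <- activity_profile(pairs, clones = universe)
  attr(out, "unmapped") <- unmapped
  out
}

CONCORDANCE_STATES <- c("neither", "predicted_only", "confirmed_only", "both")

#' Classify predicted vs confirmed activities into four states
#'
#' Every (clone, substrate) pair falls into exactly one state of the 2 x 2
#' truth table: `both` (predicted in silico and biochemically confirmed),
#' `predicted_only`, `confirmed_only`, or `neither`.
#'
#' @param predicted,confirmed [activity_profile()]s over the same clone
#'   universe (a mismatch is an error, not silently unioned).
#' @param substrates Substrate universe (default: the panel's substrates).
#' @return A `concordance` tibble with columns `clone_id`, `substrate`,
#'   `state` (factor with the four levels above).
#' @export
classify_concordance <- function(predicted, confirmed,
                                 substrates = substrate_panel()$substrate) {
  pu <- profile_clones(predicted)
  cu <- profile_clones(confirmed)
  if (is.null(pu) || is.null(cu)) {
    abort("Both profiles must be activity_profile objects (see activity_profile()).",
          class = "screenbin_invalid_parameter")
  }
  if (!setequal(pu, cu)) {
    abort("Predicted and confirmed profiles cover different clone universes.",
          class = "screenbin_consistency_error")
  }
  grid <- tidyr::crossing(clone_id = sort(unique(pu)),
                          substrate = substrates)
  p <- as_tibble(predicted) |>
    distinct(.data$clone_id, .data$substrate) |>
    mutate(predicted = TRUE)
  k <- as_tibble(confirmed) |>
    distinct(.data$clone_id, .data$substrate) |>
    mutate(confirmed = TRUE)
  out <- grid |>
    left_join(p, by = c("clone_id", "substrate")) |>
    left_join(k, by = c("clone_id", "substrate")) |>
    mutate(predicted = tidyr::replace_na(.data$predicted, FALSE),
           confirmed = tidyr::replace_na(.data$confirmed, FALSE),
           state = factor(dplyr::case_when(
             .data$predicted & .data$confirmed ~ "both",
             .data$predicted ~ "predicted_only",
             .data$confirmed ~ "confirmed_only",
             TRUE ~ "neither"), levels = CONCORDANCE_STATES)) |>
    select("clone_id", "substrate", "state")
  structure(out, class = c("concordance", class(out)))
}

#' Per-substrate concordance proportions
#'
#' For each substrate: how often an in-silico prediction was biochemically
#' confirmed (`confirmed_given_predicted = both / (both + predicted_only)`,
#' `NA` when nothing was predicted), how many confirmed activities were not
#' predicted, and whether the substrate is fully concordant (no
#' one-sided states at all).
#'
#' @param concordance A [classify_concordance()] result.
#' @return A tibble with one row per substrate: counts of the four states,
#'   `confirmed_given_predicted`, `n_unpredicted_confirmed`,
#'   `fully_concordant`.
#' @export
summarize_concordance <- function(concordance) {
  if (nrow(concordance) == 0) {
    abort("Concordance matrix is empty.",
          class = "screenbin_invalid_parameter")
  }
  concordance |>
    as_tibble() |>
    count(.data$substrate, .data$state) |>
    tidyr::pivot_wider(names_from = "state", values_from = "n",
                       values_fill = 0L,
                       names_expand = TRUE) |>
    mutate(
      n_predicted = .data$both + .data$predicted_only,
      confirmed_given_predicted = if_else(
        .data$n_predicted > 0,
        .data$both / .data$n_predicted, NA_real_),
      n_unpredicted_confirmed = .data$confirmed_only,
      fully_concordant = .data$predicted_only == 0 &
        .data$confirmed_only == 0)
}

#' Cross clone bin assignments with concordance states
#'
#' Lays out the concordance matrix by genome bin so that co-occurrence of
#' decomposition traits within a composition-defined taxon becomes visible:
#' rows are clones grouped by bin, columns substrates, cells the four-state
#' classification. Clones without a bin assignment are grouped under bin 0.
#'
#' @param concordance A [classify_concordance()] result.
#' @param assignments Clone bin assignments ([assign_clones()] or
#'   `tidy(bin_clones(...))`).
#' @return A `bin_trait_table` tibble (`bin`, `clone_id`, `substrate`,
#'   `state`) sorted by bin; per-bin state counts are attached as
#'   `attr(, "bin_state_counts")`.
#' @export
bin_trait_table <- function(concordance, assignments) {
  out <- concordance |>
    as_tibble() |>
    left_join(assignments |> select("clone_id", "bin"), by = "clone_id") |>
    mutate(bin = tidyr::replace_na(.data$bin, 0L)) |>
    select("bin", "clone_id", "substrate", "state") |>
    arrange(.data$bin, .data$clone_id, .data$substrate)
  counts <- out |>
    count(.data$bin, .data$state, .drop = FALSE) |>
    filter(!is.na(.data$bin))
  structure(out, class = c("bin_trait_table", class(out)),
            bin_state_counts = counts)
}
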