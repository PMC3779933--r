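#' Tally a screen from confirmed activity profiles
#'
#' Aggregates confirmed clone-substrate activities into screen-level
#' statistics: total assays (`clones x substrates`), positive assays, unique
#' positive clones, clones active on several substrates, per-substrate
#' positive frequencies, and the average positive clone rate.
#'
#' @param profile An [activity_profile()] (or a tibble of confirmed
#'   `clone_id`/`substrate` pairs).
#' @param n_clones_screened Total clones screened (the denominator for all
#'   rates). Must be at least the number of distinct clones in the profile.
#' @param panel Substrate panel defining the assay universe (default
#'   [substrate_panel()]).
#' @return A `screen_summary` list with fields `n_clones_screened`,
#'   `n_substrates`, `n_assays`, `n_positive_assays`,
#'   `n_unique_positive_clones`, `n_multi_substrate_clones`,
#'   `avg_positive_rate_pct` and a `per_substrate` tibble (`substrate`,
#'   `n_positive`, `frequency_pct`).
#' @examples
#' prof <- activity_profile(
#'   tibble::tibble(clone_id = c("a", "a", "b"),
#'                  substrate = c("AZCL-xylan", "starch-azure", "AZCL-xylan")),
#'   clones = c("a", "b", "c"))
#' tally_screen(prof, n_clones_screened = 3)
#' @export
tally_screen <- function(profile, n_clones_screened,
                         panel = substrate_panel()) {
  pairs <- as_tibble(profile) |> distinct(.data$clone_id, .data$substrate)
  bad <- setdiff(unique(pairs$substrate), panel$substrate)
  if (length(bad) > 0) {
    abort(sprintf("Profile references substrates outside the panel: %s.",
                  paste(bad, collapse = ", ")),
          class = "screenbin_consistency_error")
  }
  n_clones_screened <- check_count(n_clones_screened, "n_clones_screened",
                                   min = 0)
  n_distinct_clones <- length(unique(pairs$clone_id))
  if (n_clones_screened < n_distinct_clones) {
    abort("`n_clones_screened` is smaller than the number of clones with hits.",
          class = "screenbin_consistency_error")
  }
  per_clone <- count(pairs, .data$clone_id)
  per_substrate <- tibble(substrate = panel$substrate) |>
    left_join(count(pairs, .data$substrate, name = "n_positive"),
              by = "substrate") |>
    mutate(n_positive = tidyr::replace_na(.data$n_positive, 0L),
           frequency_pct = 100 * .data$n_positive / n_clones_screened)

  structure(list(
    n_clones_screened = n_clones_screened,
    n_substrates = nrow(panel),
    n_assays = n_clones_screened * nrow(panel),
    n_positive_assays = nrow(pairs),
    n_unique_positive_clones = n_distinct_clones,
    n_multi_substrate_clones = sum(per_clone$n >= 2),
    avg_positive_rate_pct = 100 * n_distinct_clones / n_clones_screened,
    per_substrate = per_substrate), class = "screen_summary")
}

#' Summarize a screen from printed per-library positive-assay counts
#'
#' For screens reported only as count tables (positives per library and
#' substrate), computes total positive assays and per-substrate positive
#' frequencies. Unique positive clones cannot be derived from assay counts
#' (one clone may fire several assays), so that number is taken as an
#' argument when available.
#'
#' When the operator-supplied clone total disagrees with the column sum of
#' the table, both denominators are retained (`n_clones_screened` and
#' `n_clones_in_table`) and rates use the operator-supplied one.
#'
#' @param counts Long counts tibble from [read_screen_counts()] (`library`,
#'   `clones_screened`, `substrate`, `n_positive`).
#' @param n_clones_screened Optional operator-supplied clone total; defaults
#'   to the sum of the per-library `clones_screened`.
#' @param n_unique_positive_clones Optional number of unique positive clones.
#' @param n_substrates Assays per clone (default 14).
#' @return A `screen_summary` list (see [tally_screen()]); `per_substrate`
#'   holds the substrate totals over all libraries.
#' @export
summarize_screen_counts <- function(counts, n_clones_screened = NULL,
                                    n_unique_positive_clones = NULL,
                                    n_substrates = 14) {
  table_total <- counts |>
    distinct(.data$library, .data$clones_screened) |>
    pull(.data$clones_screened) |>
    sum()
  denom <- n_clones_screened %||% table_total
  per_substrate <- counts |>
    group_by(.data$substrate) |>
    summarise(n_positive = sum(.data$n_positive), .groups = "drop") |>
    mutate(frequency_pct = 100 * .data$n_positive / denom)
  structure(list(
    n_clones_screened = denom,
    n_clones_in_table = table_total,
    n_substrates = n_substrates,
    n_assays = denom * n_substrates,
    n_positive_assays = sum(counts$n_positive),
    n_unique_positive_clones = n_unique_positive_clones,
    n_multi_substrate_clones = NULL,
    avg_positive_rate_pct = if (!is.null(n_unique_positive_clones)) {
      100 * n_unique_positive_clones / denom
    },
    per_substrate = per_substrate), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("<screen_summary>\n")
  cat(sprintf("  clones screened: %s", format(x$n_clones_screened,
                                              big.mark = ",")))
  if (!is.null(x$n_clones_in_table) &&
      x$n_clones_in_table != x$n_clones_screened) {
    cat(sprintf(" (count table sums to %s)",
                format(x$n_clones_in_table, big.mark = ",")))
  }
  cat("\n")
  cat(sprintf("  assays: %s (%d per clone)\n",
              format(x$n_assays, big.mark = ","), x$n_substrates))
  cat(sprintf("  positive assays: %d\n", x$n_positive_assays))
  if (!is.null(x$n_unique_positive_clones)) {
    cat(sprintf("  unique positive clones: %d", x$n_unique_positive_clones))
    if (!is.null(x$avg_positive_rate_pct)) {
      cat(sprintf(" (%.2f%%)", x$avg_positive_rate_pct))
    }
    cat("\n")
  }
  if (!is.null(x$n_multi_substrate_clones)) {
    cat(sprintf("  multi-substrate clones: %d\n", x$n_multi_substrate_clones))
  }
  invisible(x)
}

#' @export
tidy.screen_summary <- function(x, ...) x$per_substrate

#' @export
glance.screen_summary <- function(x, ...) {
  tibble(n_clones_screened = x$n_clones_screened,
         n_substrates = x$n_substrates,
         n_assays = x$n_assays,
         n_positive_assays = x$n_positive_assays,
         n_unique_positive_clones = x$n_unique_positive_clones %||%
           NA_integer_,
         n_multi_substrate_clones = x$n_multi_substrate_clones %||%
           NA_integer_,
         avg_positive_rate_pct = x$avg_positive_rate_pct %||% NA_real_)
}
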