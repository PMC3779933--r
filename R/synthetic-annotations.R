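#' Synthesize a per-ORF annotation table for a clone library
#'
#' Emulates the output of an HMM-based annotation pipeline (one record per
#' ORF with a family label and an e-value) run over the clones of a
#' synthetic library. Each planted gene is reported with probability
#' `1 - fn_rate` with an e-value drawn log-uniformly in `[1e-30, 1e-2]`
#' (comfortably under a 0.1 filter); spurious records are added at an
#' expected `fp_rate` per clone with e-values log-uniform in `[1e-3, 1]`,
#' straddling the 0.1 threshold so that filtering is exercised on both
#' sides.
#'
#' @param library A [build_library()] result.
#' @param fn_rate False-negative rate in `[0, 1]`: probability that a planted
#'   gene is missed.
#' @param fp_rate Expected number of spurious family records per clone
#'   (Poisson).
#' @param seed Optional integer seed; the table is byte-identical for a fixed
#'   seed.
#' @return An annotation tibble with columns `clone_id`, `orf_id`, `family`,
#'   `evalue`; ORF ids are unique within a clone.
#' @export
synthesize_annotations <- function(library, fn_rate = 0, fp_rate = 0,
                                   seed = NULL) {
  stopifnot(inherits(library, "clone_library"))
  fn_rate <- check_fraction(fn_rate, "fn_rate")
  if (fp_rate < 0) {
    abort("`fp_rate` must be non-negative.",
          class = "screenbin_invalid_parameter")
  }
  families <- unique(library$family_map$family)
  with_seed(seed, {
    truth <- library$planted |> arrange(.data$clone_id, .data$position)
    keep <- if (nrow(truth) > 0) runif(nrow(truth)) >= fn_rate else logical()
    kept <- truth[keep, , drop = FALSE]
    kept$evalue <- 10^runif(nrow(kept), -30, -2)

    n_spur <- rpois(nrow(library$clones), fp_rate)
    spur_idx <- rep(seq_along(n_spur), n_spur)
    spurious <- tibble(
      clone_id = library$clones$clone_id[spur_idx],
      family = if (length(spur_idx) > 0) {
        sample(families, length(spur_idx), replace = TRUE)
      } else character(),
      evalue = 10^runif(length(spur_idx), -3, 0))

    out <- bind_rows(
      kept |> select("clone_id", "family", "evalue"),
      spurious) |>
      arrange(.data$clone_id)
    out |>
      group_by(.data$clone_id) |>
      mutate(orf_id = sprintf("orf_%03d", row_number())) |>
      ungroup() |>
      select("clone_id", "orf_id", "family", "evalue")
  })
}
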