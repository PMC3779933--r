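#' Plate-reader noise model
#'
#' An additive signal model for the simulated screen: a pooled well reads
#' `background + host_background + sum(active clone contributions) + noise`,
#' clipped at zero. `host_background` models constitutive enzymatic activity
#' of the expression host; setting it to zero corresponds to a host whose
#' interfering genes (e.g. wild-type amylases and phosphatases) have been
#' knocked out, which is the default. Solid-media (visual) assays are binary:
#' a well scores 1 when it contains an active clone or a host with background
#' activity on that substrate.
#'
#' @param panel Substrate panel, see [substrate_panel()].
#' @param background_mean,background_sd Mean and sd of the substrate
#'   background signal (signal units); scalars or vectors of one value per
#'   panel row.
#' @param host_background Host contribution per substrate (scalar or
#'   per-substrate vector); default 0 (knockout host).
#' @param active_signal_mean,active_signal_sd Distribution of a single active
#'   clone's signal contribution.
#' @return A list of class `noise_model` with a `per_substrate` tibble and
#'   the active-signal parameters.
#' @export
noise_model <- function(panel = substrate_panel(),
                        background_mean = 5, background_sd = 0.5,
                        host_background = 0,
                        active_signal_mean = 50, active_signal_sd = 5) {
  if (any(background_sd < 0) || active_signal_sd < 0) {
    abort("Standard deviations must be non-negative.",
          class = "screenbin_invalid_parameter")
  }
  n <- nrow(panel)
  rec <- function(x, name) {
    if (!length(x) %in% c(1L, n)) {
      abort(sprintf("`%s` must have length 1 or one value per substrate.",
                    name), class = "screenbin_invalid_parameter")
    }
    rep_len(x, n)
  }
  structure(list(
    per_substrate = tibble(
      substrate = panel$substrate,
      modality = panel$modality,
      background_mean = rec(background_mean, "background_mean"),
      background_sd = rec(background_sd, "background_sd"),
      host_background = rec(host_background, "host_background")),
    active_signal_mean = active_signal_mean,
    active_signal_sd = active_signal_sd), class = "noise_model")
}

#' Simulate plate-reader readings for a screening design
#'
#' Produces one signal value per (assay plate, well, substrate, timepoint).
#' Liquid-assay wells follow the additive model of [noise_model()]; active
#' clones contribute an independent draw per timepoint, so a clone can be
#' detected at either the early or the late read. Visual (solid-media)
#' substrates yield binary values. Deterministic for a fixed seed.
#'
#' @param library A [build_library()] result providing the true activities.
#' @param design A [build_pooling_design()] or [build_expansion_design()]
#'   mapping clones to assay wells.
#' @param noise A [noise_model()].
#' @param timepoints Character vector of reading timepoints (default
#'   `c("24h", "5d")`, the early and end-of-incubation reads).
#' @param seed Optional integer seed.
#' @return A tibble of readings with columns `plate_id`, `well`, `substrate`,
#'   `timepoint`, `modality`, `value`.
#' @export
simulate_readings <- function(library, design, noise = noise_model(),
                              timepoints = c("24h", "5d"), seed = NULL) {
  stopifnot(inherits(library, "clone_library"),
            inherits(noise, "noise_model"))
  des_clones <- design$clone_id[!is.na(design$clone_id)]
  missing <- setdiff(des_clones, library$clones$clone_id)
  if (length(missing) > 0) {
    abort(sprintf("Design references %d clone(s) absent from the library.",
                  length(missing)), class = "screenbin_consistency_error")
  }

  wells <- design |>
    as_tibble() |>
    distinct(.data$assay_plate, .data$assay_well)
  grid <- tidyr::crossing(wells, noise$per_substrate,
                          timepoint = timepoints) |>
    arrange(.data$assay_plate, .data$assay_well, .data$substrate,
            .data$timepoint)

  # number of active clones pooled in each well, per substrate
  active <- design |>
    as_tibble() |>
    filter(!is.na(.data$clone_id)) |>
    inner_join(library$activities, by = "clone_id",
               relationship = "many-to-many") |>
    count(.data$assay_plate, .data$assay_well, .data$substrate,
          name = "n_active")
  grid <- grid |>
    left_join(active, by = c("assay_plate", "assay_well", "substrate")) |>
    mutate(n_active = tidyr::replace_na(.data$n_active, 0L))

  with_seed(seed, {
    liquid <- grid$modality != "visual"
    value <- numeric(nrow(grid))
    nl <- sum(liquid)
    if (nl > 0) {
      bg <- rnorm(nl, grid$background_mean[liquid] +
                    grid$host_background[liquid],
                  grid$background_sd[liquid])
      # active contributions: one draw per active clone in the well
      k <- grid$n_active[liquid]
      contrib <- numeric(nl)
      has <- which(k > 0)
      if (length(has) > 0) {
        draws <- rnorm(sum(k[has]), noise$active_signal_mean,
                       noise$active_signal_sd)
        contrib[has] <- vapply(
          split(draws, rep(seq_along(has), k[has])), sum, numeric(1))
      }
      value[liquid] <- pmax(0, bg + contrib)
    }
    vis <- !liquid
    value[vis] <- as.numeric(grid$n_active[vis] > 0 |
                               grid$host_background[vis] > 0)
    grid |>
      mutate(value = value) |>
      select(plate_id = "assay_plate", well = "assay_well", "substrate",
             "timepoint", "modality", "value")
  })
}

#' Write / read a readings table
#'
#' Tab-delimited with a header row and columns `plate_id`, `well`,
#' `substrate`, `timepoint`, `modality`, `value`.
#'
#' @param readings A readings tibble (see [simulate_readings()]).
#' @param path File path.
#' @return `path` invisibly (write) or a readings tibble (read).
#' @export
write_readings <- function(readings, path) {
  readr::write_tsv(readings, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_readings
#' @export
read_readings <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    plate_id = "c", well = "c", substrate = "c", timepoint = "c",
    modality = "c", value = "d"), progress = FALSE)
}
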