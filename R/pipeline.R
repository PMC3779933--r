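#' Verify the throughput arithmetic of a pooled screening design
#'
#' The bookkeeping identities of the pooled design: clones per assay plate =
#' `plates_per_pool * clones_per_plate`; clones per day = that times
#' `rounds_per_day`; reactions per day = clones per day times the number of
#' substrates; total assays = total clones times the number of substrates.
#' With the default design (16 source plates of 95 clones pooled per assay
#' plate, 8 rounds, 14 assays) this gives 1,520 clones per assay plate,
#' 12,160 clones and 170,240 reactions per day.
#'
#' @param design Optionally a [build_pooling_design()]; its parameters are
#'   used instead of the defaults below.
#' @param plates_per_pool,clones_per_plate,rounds_per_day,n_substrates
#'   Design parameters (defaults 16, 95, 8, 14).
#' @param total_clones Optional total clones screened, for `total_assays`.
#' @return A one-row tibble: `clones_per_assay_plate`, `clones_per_day`,
#'   `reactions_per_day`, `total_clones`, `total_assays`.
#' @examples
#' verify_design_arithmetic(total_clones = 143228)
#' @export
verify_design_arithmetic <- function(design = NULL, plates_per_pool = 16,
                                     clones_per_plate = 95,
                                     rounds_per_day = 8, n_substrates = 14,
                                     total_clones = NULL) {
  if (!is.null(design)) {
    stopifnot(inherits(design, "pooling_design"))
    plates_per_pool <- attr(design, "plates_per_pool")
    clones_per_plate <- attr(design, "clones_per_plate")
    rounds_per_day <- attr(design, "rounds_per_day")
    n_substrates <- attr(design, "n_substrates")
  }
  cpap <- plates_per_pool * clones_per_plate
  cpd <- cpap * rounds_per_day
  tibble(clones_per_assay_plate = cpap,
         clones_per_day = cpd,
         reactions_per_day = cpd * n_substrates,
         total_clones = total_clones %||% NA_integer_,
         total_assays = if (is.null(total_clones)) NA_real_ else
           total_clones * n_substrates)
}

#' Assemble a pipeline configuration
#'
#' A single flat configuration for [run_pipeline()], with every design
#' constant of the screen (pool factor 16, 95 clones/plate, 8 rounds, 14
#' substrates, 2 SD threshold, 2 kb fragments, 5.5 neurons per point,
#' training radius 24, e-value cutoff 0.1) held in config rather than code.
#' Unspecified entries take the defaults below; `seed` is mandatory.
#'
#' @param seed Integer master seed; every stochastic stage derives its
#'   stream from it.
#' @param library,design,noise,hit_calling,annotations,binning,esom Named
#'   lists overriding individual defaults of the corresponding stage.
#' @param out_dir Optional output directory; when set, every intermediate
#'   table plus a plain-text summary and a file manifest are written there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            library = list(), design = list(),
                            noise = list(), hit_calling = list(),
                            annotations = list(), binning = list(),
                            esom = list(), out_dir = NULL) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory in a pipeline config.",
          class = "screenbin_invalid_parameter")
  }
  seed <- check_count(seed, "seed", min = 0)
  defaults <- list(
    library = list(n_clones = 1520, insert_size_range = c(36000, 48000),
                   taxon_mix = c(taxon_a = 0.5, taxon_b = 0.5),
                   active_gene_rate = 0.003, genome_length = 500000,
                   taxon_order = 3, concentration = 0.5,
                   linkage_config = NULL),
    design = list(plates_per_pool = 16, wells_per_plate = 96,
                  clones_per_plate = 95, rounds_per_day = 8),
    noise = list(background_mean = 5, background_sd = 0.5,
                 host_background = 0, active_signal_mean = 50,
                 active_signal_sd = 5),
    hit_calling = list(sd_multiplier = 2, combine_timepoints = "any",
                       strict = TRUE, sd_type = "population"),
    annotations = list(fn_rate = 0, fp_rate = 0, evalue_threshold = 0.1,
                       best_hit_only = TRUE),
    binning = list(enabled = TRUE, fragment_length = 2000,
                   min_sequence_length = 2000, strand_symmetric = TRUE,
                   normalization = "zscore", q = 60, merge_q = 80,
                   min_neurons = 5),
    esom = list(neurons_per_point = 5.5, start_radius = 24, end_radius = 1,
                epochs = 20, lr_start = 0.5, lr_end = 0.05,
                grid_aspect = 1.6))
  user <- list(library = library, design = design, noise = noise,
               hit_calling = hit_calling, annotations = annotations,
               binning = binning, esom = esom)
  cfg <- purrr::map2(defaults, user, utils::modifyList)
  unknown <- purrr::imap(user, function(u, s) {
    setdiff(names(u), names(defaults[[s]]))
  })
  unknown <- unlist(unknown)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config entries: %s.",
                  paste(unknown, collapse = ", ")),
          class = "screenbin_invalid_parameter")
  }
  structure(c(list(seed = seed, out_dir = out_dir), cfg),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the sections of [pipeline_config()]; `seed` is
#' mandatory.
#'
#' @param path Path to a YAML config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sections <- c("library", "design", "noise", "hit_calling", "annotations",
                "binning", "esom")
  args <- c(list(seed = y$seed, out_dir = y$out_dir),
            setNames(lapply(sections, function(s) {
              sec <- y[[s]] %||% list()
              if (!is.null(sec$taxon_mix)) sec$taxon_mix <- unlist(sec$taxon_mix)
              if (!is.null(sec$insert_size_range)) {
                sec$insert_size_range <- unlist(sec$insert_size_range)
              }
              sec
            }), sections))
  do.call(pipeline_config, args)
}

#' Run the full screen-and-bin pipeline on synthetic data
#'
#' Orchestrates the whole chain: generate taxon genomes and a fosmid clone
#' library; pool and screen against the substrate panel; call hits with the
#' mean + 2SD rule; deconvolve positive wells and confirm candidates
#' individually (with a second re-screen adjudicating near-threshold
#' positives); tally the screen; synthesize and filter annotations; predict
#' activities and classify predicted-vs-confirmed concordance; bin the
#' confirmed clones by tetranucleotide frequency on an emergent map; and
#' cross bins with traits. Every stage derives its RNG stream from the
#' config seed, so the report is a pure function of the config.
#'
#' @param config A [pipeline_config()] (or [read_pipeline_config()] result).
#' @return A `screen_report` list: `design_arithmetic`, `screen_summary`,
#'   `profile`, `truth` (true activities), `sensitivity`,
#'   `n_unexplained_confirmations`, `concordance`, `concordance_summary`,
#'   `binning` (a `clone_binning` or `NULL`), `bin_ari` (adjusted Rand index
#'   of bins vs true taxa), `bin_traits` and a `manifest` of files written.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 1,
#'                        library = list(n_clones = 190,
#'                                       insert_size_range = c(6000, 9000),
#'                                       genome_length = 40000,
#'                                       active_gene_rate = 0.1),
#'                        esom = list(epochs = 5))
#' rep <- run_pipeline(cfg)
#' rep$screen_summary
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  manifest <- character()
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(tbl, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(as_tibble(tbl), path, progress = FALSE)
    manifest <<- c(manifest, path)
    readr::write_lines(basename(manifest), file.path(out_dir, "MANIFEST"))
    invisible(path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "screenbin_stage_error", parent = e)
    })
  }

  lc <- config$library
  models <- stage("taxon_models", {
    taxa <- names(lc$taxon_mix)
    lapply(seq_along(taxa), function(i) {
      taxon_model(taxa[i], order = lc$taxon_order,
                  concentration = lc$concentration, seed = seed + i)
    })
  })
  family_map <- default_family_map()
  library <- stage("library", {
    params <- library_params(
      n_clones = lc$n_clones, insert_size_range = lc$insert_size_range,
      taxon_mix = lc$taxon_mix, active_gene_rate = lc$active_gene_rate,
      linkage_config = lc$linkage_config, genome_length = lc$genome_length)
    build_library(params, models, family_map, seed = seed + 100,
                  sequences = isTRUE(config$binning$enabled))
  })

  dc <- config$design
  design <- stage("pooling_design", {
    build_pooling_design(nrow(library$clones),
                         plates_per_pool = dc$plates_per_pool,
                         wells_per_plate = dc$wells_per_plate,
                         clones_per_plate = dc$clones_per_plate,
                         rounds_per_day = dc$rounds_per_day,
                         n_substrates = nrow(substrate_panel()),
                         clone_ids = library$clones$clone_id)
  })
  noise <- do.call(noise_model, config$noise)
  hc <- config$hit_calling

  pooled <- stage("pooled_readings", {
    simulate_readings(library, design, noise, seed = seed + 200)
  })
  emit(pooled, "pooled_readings")
  hits <- stage("hit_calling", {
    call_hits(pooled, sd_multiplier = hc$sd_multiplier,
              combine_timepoints = hc$combine_timepoints,
              strict = hc$strict, sd_type = hc$sd_type)
  })
  emit(hits, "pooled_hits")
  emit(hit_thresholds(hits), "pooled_thresholds")
  candidates <- stage("deconvolution", deconvolve(hits, design))
  emit(candidates, "candidates")

  profile <- if (nrow(candidates) > 0) {
    stage("confirmation", {
      exp_design <- build_expansion_design(candidates$clone_id,
                                           clones_per_plate =
                                             dc$clones_per_plate,
                                           wells_per_plate =
                                             dc$wells_per_plate)
      exp_readings <- simulate_readings(library, exp_design, noise,
                                        seed = seed + 300)
      rescreen <- simulate_readings(library, exp_design, noise,
                                    seed = seed + 400)
      confirm_clones(exp_readings, exp_design,
                     rescreen_readings = rescreen,
                     sd_multiplier = hc$sd_multiplier,
                     combine_timepoints = hc$combine_timepoints,
                     strict = hc$strict, sd_type = hc$sd_type)
    })
  } else {
    activity_profile(tibble(clone_id = character(), substrate = character()),
                     clones = character())
  }
  # confirmations only count for substrates the candidate was expanded for
  confirmed_pairs <- as_tibble(profile) |>
    semi_join(candidates, by = c("clone_id", "substrate")) |>
    distinct(.data$clone_id, .data$substrate)
  full_profile <- activity_profile(confirmed_pairs,
                                   clones = library$clones$clone_id)
  emit(full_profile, "confirmed_profile")

  summary <- stage("tally", {
    tally_screen(full_profile, n_clones_screened = nrow(library$clones))
  })
  emit(tidy(summary), "per_substrate_summary")

  truth <- library$activities
  sens <- if (nrow(truth) > 0) {
    nrow(semi_join(truth, confirmed_pairs,
                   by = c("clone_id", "substrate"))) / nrow(truth)
  } else NA_real_
  unexplained <- nrow(anti_join(confirmed_pairs, truth,
                                by = c("clone_id", "substrate")))

  ac <- config$annotations
  concordance <- stage("concordance", {
    anno <- synthesize_annotations(library, fn_rate = ac$fn_rate,
                                   fp_rate = ac$fp_rate, seed = seed + 500)
    kept <- filter_annotations(anno, evalue_threshold = ac$evalue_threshold,
                               best_hit_only = ac$best_hit_only)
    predicted <- predict_activities(kept, family_map,
                                    clones = library$clones$clone_id)
    classify_concordance(predicted, full_profile)
  })
  emit(concordance, "concordance")
  conc_summary <- summarize_concordance(concordance)
  emit(conc_summary, "concordance_summary")

  binning <- NULL
  bin_ari <- NA_real_
  bin_traits <- NULL
  if (isTRUE(config$binning$enabled) &&
      length(unique(confirmed_pairs$clone_id)) >= 2) {
    bc <- config$binning
    binning <- stage("binning", {
      conf_clones <- library$clones |>
        filter(.data$clone_id %in% confirmed_pairs$clone_id)
      do.call(bin_clones, c(
        list(conf_clones, fragment_length = bc$fragment_length,
             min_sequence_length = bc$min_sequence_length,
             strand_symmetric = bc$strand_symmetric,
             normalization = bc$normalization, q = bc$q,
             merge_q = bc$merge_q, min_neurons = bc$min_neurons,
             seed = seed + 600),
        config$esom))
    })
    assignments <- binning$assignments |>
      left_join(library$clones |> select("clone_id", "true_taxon"),
                by = "clone_id")
    bin_ari <- mclust::adjustedRandIndex(assignments$bin,
                                         assignments$true_taxon)
    emit(assignments, "bin_assignments")
    bin_traits <- bin_trait_table(concordance, binning$assignments)
    emit(bin_traits, "bin_traits")
  }

  arithmetic <- verify_design_arithmetic(
    design, total_clones = nrow(library$clones))

  report <- structure(list(
    config = config,
    design_arithmetic = arithmetic,
    screen_summary = summary,
    profile = full_profile,
    truth = truth,
    sensitivity = sens,
    n_unexplained_confirmations = unexplained,
    concordance = concordance,
    concordance_summary = conc_summary,
    binning = binning,
    bin_ari = bin_ari,
    bin_traits = bin_traits,
    manifest = manifest), class = "screen_report")
  if (!is.null(out_dir)) {
    txt <- utils::capture.output({
      print(arithmetic)
      print(summary)
      if (!is.null(binning)) print(binning)
      cat(sprintf("confirmation sensitivity: %s\n", format(sens)))
      cat(sprintf("unexplained confirmations: %d\n", unexplained))
      cat(sprintf("bin ARI vs true taxa: %s\n", format(bin_ari)))
    })
    readr::write_lines(txt, file.path(out_dir, "summary.txt"))
  }
  report
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  print(x$screen_summary)
  cat(sprintf("  confirmation sensitivity: %s\n", format(x$sensitivity)))
  cat(sprintf("  unexplained confirmations: %d\n",
              x$n_unexplained_confirmations))
  if (!is.null(x$binning)) {
    cat(sprintf("  bin ARI vs true taxa: %.3f\n", x$bin_ari))
  }
  invisible(x)
}

#' @describeIn run_pipeline One-row report summary.
#' @param x A `screen_report`.
#' @param ... Unused.
#' @export
glance.screen_report <- function(x, ...) {
  bind_cols(glance(x$screen_summary),
            tibble(sensitivity = x$sensitivity,
                   n_unexplained_confirmations =
                     x$n_unexplained_confirmations,
                   bin_ari = x$bin_ari))
}
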