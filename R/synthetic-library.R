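#' Parameters for a synthetic fosmid clone library
#'
#' @param n_clones Number of clones to generate.
#' @param insert_size_range Insert size interval in bp (default 36-48 kb,
#'   the size-selection window of a fosmid library).
#' @param taxon_mix Named numeric vector of taxon fractions (must sum to 1).
#' @param active_gene_rate Expected number of planted enzyme genes per clone
#'   (Poisson, capped at 3). The default 0.003 reproduces the rarity of
#'   positives observed in large environmental screens (~0.26% positive
#'   clones).
#' @param linkage_config Optional named list (taxon -> list of character
#'   vectors); each vector is a group of enzyme families that co-occur on one
#'   insert. When a clone of that taxon receives genes, they are drawn from a
#'   single group, emulating gene clusters such as adjacent GH cassettes.
#' @param genome_length Length of each simulated taxon genome in bp
#'   (default 500 kb; a desk-scale stand-in for a full genome).
#' @param clones_per_plate Clones picked per 96-well source plate (default
#'   95; the remaining well is a negative control).
#' @return A list of class `library_params`.
#' @export
library_params <- function(n_clones,
                           insert_size_range = c(36000, 48000),
                           taxon_mix,
                           active_gene_rate = 0.003,
                           linkage_config = NULL,
                           genome_length = 500000,
                           clones_per_plate = 95) {
  n_clones <- check_count(n_clones, "n_clones")
  if (length(taxon_mix) == 0 || is.null(names(taxon_mix)) ||
      any(names(taxon_mix) == "")) {
    abort("`taxon_mix` must be a non-empty named vector of fractions.",
          class = "screenbin_invalid_parameter")
  }
  if (abs(sum(taxon_mix) - 1) > 1e-8) {
    abort("`taxon_mix` fractions must sum to 1.",
          class = "screenbin_invalid_parameter")
  }
  if (any(insert_size_range > genome_length)) {
    abort("`insert_size_range` must lie within the genome length.",
          class = "screenbin_invalid_parameter")
  }
  if (active_gene_rate < 0) {
    abort("`active_gene_rate` must be non-negative.",
          class = "screenbin_invalid_parameter")
  }
  structure(list(n_clones = n_clones,
                 insert_size_range = as.integer(insert_size_range),
                 taxon_mix = taxon_mix,
                 active_gene_rate = active_gene_rate,
                 linkage_config = linkage_config,
                 genome_length = as.integer(genome_length),
                 clones_per_plate = check_count(clones_per_plate,
                                                "clones_per_plate")),
            class = "library_params")
}

#' Build a synthetic fosmid clone library with full ground truth
#'
#' Generates one genome per taxon, samples fosmid-sized inserts, plants 0-3
#' enzyme genes per clone at the configured rate, derives each clone's true
#' activity profile through the family-to-substrate map, and lays the clones
#' out on 96-well source plates (95 clones + 1 negative-control well, H12,
#' per plate).
#'
#' @param params A [library_params()] object.
#' @param taxon_models List of [taxon_model()] objects covering every taxon
#'   in `params$taxon_mix`.
#' @param family_map Family-to-substrate map (tibble with columns `family`,
#'   `substrate`), e.g. [default_family_map()]. Must cover every family named
#'   in `params$linkage_config`.
#' @param seed Optional integer seed; the whole library is a pure function of
#'   it.
#' @param sequences If `FALSE`, skip genome/insert sequence generation (the
#'   screening chain does not need sequences; binning does). Insert lengths
#'   are still drawn.
#' @return An object of class `clone_library`: a list with tibbles `clones`
#'   (`clone_id`, `source_plate`, `source_well`, `true_taxon`,
#'   `insert_length`, `insert_seq`), `planted` (`clone_id`, `family`,
#'   `position`), `activities` (`clone_id`, `substrate`; the true profile),
#'   the `genomes` (named character), `params` and `family_map`.
#' @examples
#' fm <- default_family_map()
#' mods <- list(a = taxon_model("a", seed = 1), b = taxon_model("b", seed = 2))
#' lp <- library_params(20, insert_size_range = c(5000, 8000),
#'                      taxon_mix = c(a = 0.5, b = 0.5),
#'                      genome_length = 20000)
#' lib <- build_library(lp, mods, fm, seed = 3)
#' lib$clones
#' @export
build_library <- function(params, taxon_models, family_map, seed = NULL,
                          sequences = TRUE) {
  stopifnot(inherits(params, "library_params"))
  taxa <- names(params$taxon_mix)
  model_ids <- vapply(taxon_models, function(m) m$taxon_id, character(1))
  names(taxon_models) <- model_ids
  if (!all(taxa %in% model_ids)) {
    abort("Every taxon in `taxon_mix` needs a matching taxon model.",
          class = "screenbin_invalid_parameter")
  }
  if (!is.null(params$linkage_config)) {
    linked <- unique(unlist(params$linkage_config))
    if (!all(linked %in% family_map$family)) {
      abort("`linkage_config` names families absent from `family_map`.",
            class = "screenbin_invalid_parameter")
    }
  }
  n <- params$n_clones
  with_seed(seed, {
    genomes <- if (sequences) {
      setNames(lapply(taxa, function(t) {
        generate_genome(taxon_models[[t]], params$genome_length)
      }), taxa)
    } else NULL

    true_taxon <- sample(taxa, n, replace = TRUE, prob = params$taxon_mix)
    sizes <- sample.int(diff(params$insert_size_range) + 1L, n,
                        replace = TRUE) + params$insert_size_range[1] - 1L
    inserts <- if (sequences) {
      offs <- vapply(seq_len(n), function(i) {
        sample.int(params$genome_length - sizes[i] + 1L, 1L)
      }, integer(1))
      vapply(seq_len(n), function(i) {
        substr(genomes[[true_taxon[i]]], offs[i], offs[i] + sizes[i] - 1L)
      }, character(1))
    } else rep(NA_character_, n)

    clone_id <- sprintf("clone_%05d", seq_len(n))
    cpp <- params$clones_per_plate
    # row-major wells; the last well of each plate is the negative control
    plate_wells <- well_labels()[seq_len(cpp)]
    clones <- tibble(
      clone_id = clone_id,
      source_plate = sprintf("SP%03d", (seq_len(n) - 1L) %/% cpp + 1L),
      source_well = plate_wells[(seq_len(n) - 1L) %% cpp + 1L],
      true_taxon = true_taxon,
      insert_length = as.integer(sizes),
      insert_seq = inserts)

    n_genes <- pmin(rpois(n, params$active_gene_rate), 3L)
    all_families <- unique(family_map$family)
    planted <- purrr::map_dfr(which(n_genes > 0), function(i) {
      k <- n_genes[i]
      pool <- all_families
      lc <- params$linkage_config[[true_taxon[i]]]
      if (!is.null(lc)) {
        group <- lc[[sample.int(length(lc), 1L)]]
        pool <- group
      }
      fams <- sample(pool, min(k, length(pool)))
      tibble(clone_id = clone_id[i], family = fams,
             position = vapply(fams, function(f) {
               sample.int(max(sizes[i] - 1000L, 1L), 1L)
             }, integer(1)))
    })
    if (nrow(planted) == 0) {
      planted <- tibble(clone_id = character(), family = character(),
                        position = integer())
    }
    activities <- planted |>
      inner_join(family_map, by = "family",
                 relationship = "many-to-many") |>
      distinct(.data$clone_id, .data$substrate)

    structure(list(clones = clones, planted = planted,
                   activities = activities, genomes = genomes,
                   params = params, family_map = family_map),
              class = "clone_library")
  })
}

#' @export
print.clone_library <- function(x, ...) {
  cat(sprintf(paste0("<clone_library> %d clones on %d source plates, ",
                     "%d taxa, %d planted genes, %d true clone-substrate ",
                     "activities\n"),
              nrow(x$clones), length(unique(x$clones$source_plate)),
              length(x$params$taxon_mix), nrow(x$planted),
              nrow(x$activities)))
  invisible(x)
}

#' @describeIn build_library Tidy a clone library into its clone table, with
#'   planted gene counts and true activities nested as list-columns.
#' @param x A `clone_library`.
#' @param ... Unused.
#' @export
tidy.clone_library <- function(x, ...) {
  acts <- x$activities |>
    group_by(.data$clone_id) |>
    summarise(true_activities = list(.data$substrate), .groups = "drop")
  x$clones |>
    left_join(count(x$planted, .data$clone_id, name = "n_planted"),
              by = "clone_id") |>
    left_join(acts, by = "clone_id") |>
    mutate(n_planted = tidyr::replace_na(.data$n_planted, 0L),
           true_activities = purrr::map(.data$true_activities,
                                        function(a) a %||% character()))
}

#' Write clone insert sequences as FASTA
#'
#' One record per clone, id = `clone_id`.
#'
#' @param library A `clone_library` (or a tibble with `clone_id` and
#'   `insert_seq` columns).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_clone_fasta <- function(library, path) {
  clones <- if (inherits(library, "clone_library")) library$clones else library
  if (any(is.na(clones$insert_seq))) {
    abort("Library was built without sequences; nothing to write.",
          class = "screenbin_invalid_parameter")
  }
  seqs <- Biostrings::DNAStringSet(clones$insert_seq)
  names(seqs) <- clones$clone_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read clone sequences from FASTA
#'
#' @param path FASTA path (record ids are taken as clone ids).
#' @return A tibble with columns `clone_id` and `insert_seq`.
#' @export
read_clone_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(clone_id = sub("\\s.*$", "", names(seqs)),
         insert_seq = unname(as.character(seqs)))
}
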