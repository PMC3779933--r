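# Shared builders for test fixtures (all generated in code, seeded).

# A single-plate readings table with explicit well values.
plate_readings <- function(values, plate_id = "AP001", substrate = "s",
                           timepoint = "24h", modality = "absorbance") {
  tibble::tibble(plate_id = plate_id,
                 well = well_labels()[seq_along(values)],
                 substrate = substrate, timepoint = timepoint,
                 modality = modality, value = values)
}

# A small two-taxon library with genomes sized for fast tests.
small_library <- function(n_clones = 20, seed = 1, active_gene_rate = 0,
                          insert_size_range = c(5000, 8000),
                          genome_length = 20000, sequences = TRUE) {
  mods <- list(taxon_model("tax_a", seed = seed),
               taxon_model("tax_b", seed = seed + 1))
  lp <- library_params(n_clones, insert_size_range = insert_size_range,
                       taxon_mix = c(tax_a = 0.5, tax_b = 0.5),
                       active_gene_rate = active_gene_rate,
                       genome_length = genome_length)
  build_library(lp, mods, default_family_map(), seed = seed + 2,
                sequences = sequences)
}

# Force a specific set of true activities onto a library (ground-truth
# injection for exact-value reading tests).
set_true_activities <- function(library, clone_id, substrate) {
  library$activities <- tibble::tibble(clone_id = clone_id,
                                       substrate = substrate)
  library
}

# Deterministic noise model (no stochastic terms).
exact_noise <- function(background_mean = 5, active_signal_mean = 50,
                        host_background = 0) {
  noise_model(background_mean = background_mean, background_sd = 0,
              host_background = host_background,
              active_signal_mean = active_signal_mean, active_signal_sd = 0)
}

# Minimal hand-built map object for BMU / U-matrix unit tests.
manual_esom <- function(codebook, grid_rows, grid_cols) {
  structure(list(codebook = codebook, grid_rows = grid_rows,
                 grid_cols = grid_cols,
                 training_log = tibble::tibble(),
                 params = list(), n_train = nrow(codebook)),
            class = "esom")
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
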