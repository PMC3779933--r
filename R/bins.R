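#' Extract genome bins from a trained map
#'
#' A deterministic, automated replacement for picking bins off the U-matrix
#' by eye. The default `"watershed"` method thresholds the U-matrix: neurons
#' with height at or below the q-th percentile form the foreground (basins),
#' toroidal 8-neighborhood connected components of the foreground become
#' bins, and components smaller than `min_neurons` are merged into label 0
#' (unassigned/boundary). The `"kmedoids"` alternative partitions all
#' neurons by k-medoids on the codebook. A manual partition (e.g. from
#' visual inspection) can be supplied as a neuron-label vector via
#' `manual`.
#'
#' Thresholding a U-matrix tends to over-segment: one genuine basin can be
#' cut in two by a spurious internal ridge that barely exceeds the foreground
#' cutoff, whereas real bin boundaries are wide, high ridges. A hysteresis
#' merge step repairs this: two components are fused when some single
#' boundary neuron touches both and its height stays below the `merge_q`-th
#' percentile (default 80). Set `merge_q <= q` to disable merging.
#'
#' @param som A trained [train_esom()] map.
#' @param umatrix The map's U-matrix (computed with [compute_umatrix()] if
#'   not supplied).
#' @param method `"watershed"` (default) or `"kmedoids"`.
#' @param q Percentile of U-matrix height delimiting the foreground, in
#'   (0, 100] (default 60).
#' @param merge_q Percentile below which a thin saddle between two
#'   components is treated as basin interior rather than a boundary
#'   (default 80).
#' @param min_neurons Smallest component kept as a bin (default 5).
#' @param k Number of bins for `"kmedoids"`.
#' @param manual Optional integer vector of neuron labels (length
#'   `n_neurons`, 0 = unassigned) overriding both methods.
#' @return A `bin_partition`: a tibble with one row per neuron (`neuron`,
#'   `row`, `col`, `bin`; bin 0 = boundary/unassigned), bins labelled
#'   1, 2, ... in decreasing neuron count, with the method parameters as
#'   attributes.
#' @export
extract_bins <- function(som, umatrix = NULL,
                         method = c("watershed", "kmedoids"),
                         q = 60, merge_q = 80, min_neurons = 5, k = NULL,
                         manual = NULL) {
  stopifnot(inherits(som, "esom"))
  method <- match.arg(method)
  rows <- som$grid_rows
  cols <- som$grid_cols
  m <- rows * cols

  if (!is.null(manual)) {
    stopifnot(length(manual) == m)
    labels <- as.integer(manual)
  } else if (method == "watershed") {
    if (q <= 0 || q > 100) {
      abort("`q` must lie in (0, 100].",
            class = "screenbin_invalid_parameter")
    }
    if (is.null(umatrix)) umatrix <- compute_umatrix(som)
    # umatrix is rows x cols; flatten to row-major neuron order
    h <- as.numeric(t(unclass(umatrix)))
    fg <- which(h <= quantile(h, q / 100))
    labels <- integer(m)
    if (length(fg) > 0) {
      comp <- toroidal_components(fg, rows, cols)
      labels[fg] <- comp
      if (merge_q > q && max(comp) > 1) {
        labels <- merge_thin_saddles(labels, h,
                                     quantile(h, merge_q / 100),
                                     rows, cols)
      }
      sizes <- table(labels[labels > 0])
      keep <- as.integer(names(sizes)[sizes >= min_neurons])
      labels[!(labels %in% c(0L, keep))] <- 0L
    }
  } else {
    k <- check_count(k %||% abort("`k` is required for method 'kmedoids'.",
                                  class = "screenbin_invalid_parameter"),
                     "k")
    labels <- cluster::pam(som$codebook, k, pamonce = 5)$clustering
  }

  # relabel bins 1..K by decreasing size
  nz <- labels[labels > 0]
  if (length(nz) > 0) {
    ord <- names(sort(table(nz), decreasing = TRUE))
    labels[labels > 0] <- match(as.character(nz), ord)
  }
  out <- bind_cols(tibble(neuron = seq_len(m)),
                   neuron_coords(som, seq_len(m)),
                   tibble(bin = as.integer(labels))) |>
    select("neuron", "row", "col", "bin")
  structure(out, class = c("bin_partition", class(out)),
            method = if (!is.null(manual)) "manual" else method,
            q = q, min_neurons = min_neurons, k = k,
            n_bins = length(unique(labels[labels > 0])))
}

# 8-neighborhood of 1-based row-major neuron indices on a toroidal grid:
# returns a length(idx) x 8 matrix of neighbor indices.
toroidal_neighbors <- function(idx, rows, cols) {
  r <- (idx - 1L) %/% cols
  c <- (idx - 1L) %% cols
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  vapply(seq_len(nrow(shifts)), function(i) {
    as.integer(((r + shifts$dr[i]) %% rows) * cols +
                 ((c + shifts$dc[i]) %% cols) + 1)
  }, integer(length(idx)))
}

# Connected components of a neuron subset on a toroidal grid
# (8-neighborhood). `members` are 1-based row-major neuron indices; returns
# integer component labels aligned with `members`.
toroidal_components <- function(members, rows, cols) {
  inset <- integer(rows * cols)
  inset[members] <- seq_along(members)
  nb <- toroidal_neighbors(members, rows, cols)
  if (length(members) == 1L) nb <- matrix(nb, nrow = 1L)
  from <- rep(seq_along(members), 8L)
  to <- inset[as.integer(nb)]
  keep <- to > 0L
  g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(members) -
                                     igraph::vcount(g)))
  as.integer(igraph::components(g)$membership[seq_along(members)])
}

# Hysteresis repair of over-segmented basins: any boundary neuron whose
# height is at or below `threshold` and which touches two or more components
# marks those components as parts of one basin; merges are transitive.
merge_thin_saddles <- function(labels, h, threshold, rows, cols) {
  saddles <- which(labels == 0L & h <= threshold)
  if (length(saddles) == 0) return(labels)
  nb <- toroidal_neighbors(saddles, rows, cols)
  if (length(saddles) == 1L) nb <- matrix(nb, nrow = 1L)
  nb_bin <- matrix(labels[as.integer(nb)], nrow = length(saddles))
  n_comp <- max(labels)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_along(saddles)) {
    touched <- unique(nb_bin[i, nb_bin[i, ] > 0L])
    if (length(touched) >= 2) {
      edges <- rbind(edges, cbind(touched[1], touched[-1]))
    }
  }
  if (nrow(edges) == 0) return(labels)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_comp - igraph::vcount(g)))
  membership <- as.integer(igraph::components(g)$membership)
  pos <- labels > 0L
  labels[pos] <- membership[labels[pos]]
  labels
}

#' Assign clones to bins by fragment majority vote
#'
#' Each clone inherits the bin containing the plurality of its fragments'
#' best-matching neurons. Fragments landing on boundary neurons (bin 0) are
#' ignored unless *all* of a clone's fragments are on the boundary, in which
#' case the clone is reported as bin 0. Ties are broken toward the bin whose
#' fragments sit closer to their codebook vectors (smaller mean distance)
#' and flagged.
#'
#' @param fragment_bmus A tibble linking fragments to neurons: columns
#'   `fragment_id`, `clone_id`, `neuron`, `dist` (from
#'   [best_matching_unit()] bound to the fragment table).
#' @param partition A [extract_bins()] partition.
#' @return A tibble with one row per clone: `clone_id`, `bin`,
#'   `n_fragments`, `majority_fraction` (plurality count over counted
#'   fragments, in (0, 1]), `tie` flag.
#' @export
assign_clones <- function(fragment_bmus, partition) {
  needed <- c("fragment_id", "clone_id", "neuron", "dist")
  if (!all(needed %in% names(fragment_bmus))) {
    abort(sprintf("`fragment_bmus` needs columns %s.",
                  paste(needed, collapse = ", ")),
          class = "screenbin_invalid_parameter")
  }
  labelled <- fragment_bmus |>
    left_join(partition |> as_tibble() |> select("neuron", "bin"),
              by = "neuron")
  if (any(is.na(labelled$bin))) {
    abort("Some fragments map to neurons outside the partition.",
          class = "screenbin_consistency_error")
  }
  labelled |>
    group_by(.data$clone_id) |>
    group_modify(function(d, key) {
      counted <- if (all(d$bin == 0L)) d else d[d$bin != 0L, , drop = FALSE]
      votes <- counted |>
        group_by(.data$bin) |>
        summarise(n = n(), mean_dist = mean(.data$dist), .groups = "drop")
      top <- votes |> filter(.data$n == max(.data$n))
      tie <- nrow(top) > 1
      winner <- top |> arrange(.data$mean_dist, .data$bin) |> head(1)
      tibble(bin = winner$bin,
             n_fragments = nrow(d),
             majority_fraction = winner$n / nrow(counted),
             tie = tie)
    }) |>
    ungroup()
}

#' Bin clone sequences end to end
#'
#' Convenience wrapper running the full composition-binning chain: fragment
#' the sequences ([fragment_sequences()]), compute and normalize
#' tetranucleotide frequencies ([tnf_matrix()], [normalize_features()]),
#' train the emergent map ([train_esom()]), compute the U-matrix, extract
#' bins ([extract_bins()]) and assign clones by fragment majority vote
#' ([assign_clones()]).
#'
#' @param clones Clone sequences (tibble with `clone_id`, `insert_seq`, a
#'   `clone_library`, or a named character vector).
#' @param fragment_length,min_sequence_length See [fragment_sequences()].
#' @param strand_symmetric See [tnf_vector()].
#' @param normalization `"zscore"` (default) or `"none"`.
#' @param q,merge_q,min_neurons See [extract_bins()].
#' @param seed Integer seed for map training.
#' @param ... Passed to [train_esom()] (e.g. `epochs`, `start_radius`).
#' @return An object of class `clone_binning`: list with `assignments` (the
#'   clone-level bin table), `som`, `umatrix`, `partition`,
#'   `fragment_bmus`, and `excluded` (clones too short to bin).
#' @export
bin_clones <- function(clones, fragment_length = 2000,
                       min_sequence_length = 2000, strand_symmetric = TRUE,
                       normalization = c("zscore", "none"), q = 60,
                       merge_q = 80, min_neurons = 5, seed = NULL, ...) {
  normalization <- match.arg(normalization)
  frags <- fragment_sequences(clones, fragment_length = fragment_length,
                              min_sequence_length = min_sequence_length)
  if (nrow(frags) < 2) {
    abort("Fewer than 2 fragments available for binning.",
          class = "screenbin_insufficient_data")
  }
  tnf <- tnf_matrix(frags, strand_symmetric = strand_symmetric)
  feat <- normalize_features(tnf, method = normalization)
  som <- train_esom(feat, seed = seed, ...)
  um <- compute_umatrix(som)
  part <- extract_bins(som, um, q = q, merge_q = merge_q,
                       min_neurons = min_neurons)
  bmus <- bind_cols(frags |> select("fragment_id", "clone_id"),
                    best_matching_unit(som, feat))
  assignments <- assign_clones(bmus, part)
  structure(list(assignments = assignments, som = som, umatrix = um,
                 partition = part, fragment_bmus = bmus,
                 excluded = attr(frags, "excluded")),
            class = "clone_binning")
}

#' @export
print.clone_binning <- function(x, ...) {
  cat(sprintf(paste0("<clone_binning> %d clones in %d bins ",
                     "(%d fragments on a %d x %d map; %d clones excluded)\n"),
              nrow(x$assignments), attr(x$partition, "n_bins"),
              nrow(x$fragment_bmus), x$som$grid_rows, x$som$grid_cols,
              nrow(x$excluded)))
  invisible(x)
}

#' @describeIn bin_clones Clone-level assignment table.
#' @param x A `clone_binning`.
#' @export
tidy.clone_binning <- function(x, ...) x$assignments

#' @describeIn bin_clones One-row binning summary.
#' @export
glance.clone_binning <- function(x, ...) {
  tibble(n_clones = nrow(x$assignments),
         n_bins = attr(x$partition, "n_bins"),
         n_fragments = nrow(x$fragment_bmus),
         n_excluded = nrow(x$excluded),
         grid_rows = x$som$grid_rows, grid_cols = x$som$grid_cols,
         mean_majority_fraction = mean(x$assignments$majority_fraction))
}
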