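#' Define a taxon-specific Markov sequence model
#'
#' A k-th order Markov chain over {A,C,G,T} whose transition weights act as a
#' compositional signature: two models with independently drawn weights
#' produce genomes with distinct tetranucleotide frequency (TNF) profiles,
#' the structure that composition-based genome binning relies on. Weights are
#' drawn per context from a gamma distribution (a Dirichlet draw after row
#' normalization); smaller `concentration` gives spikier, more distinctive
#' signatures.
#'
#' @param taxon_id Label for the taxon.
#' @param order Markov order (context length in bases). Default 3, so that
#'   4-mer distributions differ between taxa by construction.
#' @param concentration Dirichlet concentration of the random transition
#'   weights. Default 0.5.
#' @param gc_target Optional GC fraction in `[0, 1]`; when supplied, the C
#'   and G transition weights are scaled toward it (approximate bias, not an
#'   exact stationary GC).
#' @param weights Optional explicit weight matrix (`4^order` rows, 4 columns,
#'   contexts in lexicographic order). Overrides the random draw. Rows are
#'   normalized to sum to 1; entries must be non-negative.
#' @param seed Optional integer seed making the random draw reproducible.
#' @return An object of class `taxon_model`: a list with `taxon_id`, `order`
#'   and the row-stochastic `weights` matrix (rownames are contexts).
#' @examples
#' m <- taxon_model("tax1", order = 2, seed = 1)
#' rowSums(m$weights)[1:4]
#' @export
taxon_model <- function(taxon_id, order = 3, concentration = 0.5,
                        gc_target = NULL, weights = NULL, seed = NULL) {
  order <- check_count(order, "order", min = 0)
  n_ctx <- 4L^order
  if (is.null(weights)) {
    weights <- with_seed(seed, {
      matrix(rgamma(n_ctx * 4L, shape = concentration) + 1e-8,
             nrow = n_ctx, ncol = 4L)
    })
  } else {
    weights <- as.matrix(weights)
    if (!identical(dim(weights), c(n_ctx, 4L)) &&
        !identical(dim(weights), as.integer(c(n_ctx, 4)))) {
      abort(sprintf("`weights` must be a %d x 4 matrix for order %d.",
                    n_ctx, order), class = "screenbin_invalid_parameter")
    }
    if (any(weights < 0) || any(rowSums(weights) <= 0)) {
      abort("`weights` must be non-negative with positive row sums.",
            class = "screenbin_invalid_parameter")
    }
  }
  if (!is.null(gc_target)) {
    gc_target <- check_fraction(gc_target, "gc_target")
    f <- gc_target / (1 - gc_target + 1e-12)
    weights[, c(2L, 3L)] <- weights[, c(2L, 3L)] * f
  }
  weights <- weights / rowSums(weights)
  colnames(weights) <- DNA_BASES
  rownames(weights) <- if (order > 0) {
    g <- rev(expand.grid(rep(list(DNA_BASES), order),
                         stringsAsFactors = FALSE))
    do.call(paste0, g)
  } else ""
  structure(list(taxon_id = taxon_id, order = order, weights = weights),
            class = "taxon_model")
}

#' @export
print.taxon_model <- function(x, ...) {
  cat(sprintf("<taxon_model> %s: order-%d Markov chain (%d contexts)\n",
              x$taxon_id, x$order, nrow(x$weights)))
  invisible(x)
}

#' Generate a genome sequence from a taxon model
#'
#' Simulates a DNA string of the requested length from the model's Markov
#' chain. Deterministic for a fixed seed.
#'
#' @param model A [taxon_model()].
#' @param length Genome length in base pairs; must be at least
#'   `model$order + 1`.
#' @param seed Optional integer seed.
#' @return A single character string over {A,C,G,T} of `length` characters.
#' @examples
#' nchar(generate_genome(taxon_model("t", order = 0, seed = 1), 5000, seed = 2))
#' @export
generate_genome <- function(model, length, seed = NULL) {
  stopifnot(inherits(model, "taxon_model"))
  length <- check_count(length, "length", min = 1)
  if (length < model$order + 1) {
    abort("`length` must be at least `order + 1`.",
          class = "screenbin_invalid_parameter")
  }
  cumw <- t(apply(model$weights, 1, cumsum))
  if (nrow(model$weights) == 1L) cumw <- matrix(cumw, nrow = 1L)
  with_seed(seed, markov_chain_seq(cumw, model$order, length))
}

#' Sample a fosmid-sized insert from a genome
#'
#' Draws an insert of length uniform over `size_range` (36-48 kb for a fosmid
#' library) at an offset uniform over the valid starts, emulating random
#' shearing followed by size selection.
#'
#' @param genome DNA string to sample from.
#' @param size_range Length-2 integer vector `(min, max)` insert size in bp.
#' @param seed Optional integer seed.
#' @return A list with `sequence` (the insert) and `offset` (1-based start).
#' @examples
#' g <- generate_genome(taxon_model("t", order = 0, seed = 1), 10000, seed = 2)
#' ins <- sample_insert(g, c(2000, 3000), seed = 3)
#' nchar(ins$sequence)
#' @export
sample_insert <- function(genome, size_range, seed = NULL) {
  if (length(size_range) != 2 || any(size_range < 1) ||
      size_range[1] > size_range[2]) {
    abort("`size_range` must be an increasing positive interval.",
          class = "screenbin_invalid_parameter")
  }
  glen <- nchar(genome)
  if (glen < size_range[2]) {
    abort("Genome is shorter than the maximum insert size.",
          class = "screenbin_invalid_parameter")
  }
  with_seed(seed, {
    size <- sample.int(size_range[2] - size_range[1] + 1L, 1L) +
      size_range[1] - 1L
    offset <- sample.int(glen - size + 1L, 1L)
    list(sequence = substr(genome, offset, offset + size - 1L),
         offset = offset)
  })
}
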