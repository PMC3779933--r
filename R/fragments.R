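#' Fragment clone sequences into fixed-length windows
#'
#' Sequences shorter than `min_sequence_length` are excluded from binning
#' entirely (recorded in the `"excluded"` attribute); the rest are cut into
#' non-overlapping `fragment_length` windows starting at offsets 0, 2000,
#' 4000, ... with any trailing remainder shorter than a full window
#' discarded.
#'
#' @param clones A tibble with columns `clone_id` and `insert_seq` (e.g.
#'   from [read_clone_fasta()]), a `clone_library`, or a named character
#'   vector of sequences.
#' @param fragment_length Window size in bp (default 2000).
#' @param min_sequence_length Minimum sequence length for inclusion (default
#'   2000; must be at least `fragment_length`).
#' @return A tibble with columns `fragment_id`, `clone_id`, `offset`
#'   (0-based), `frag_seq`; excluded clones are recorded in
#'   `attr(, "excluded")`.
#' @examples
#' frags <- fragment_sequences(
#'   tibble::tibble(clone_id = "c1",
#'                  insert_seq = strrep("ACGT", 1250)))
#' nrow(frags)  # floor(5000 / 2000) = 2
#' @export
fragment_sequences <- function(clones, fragment_length = 2000,
                               min_sequence_length = 2000) {
  if (inherits(clones, "clone_library")) clones <- clones$clones
  if (is.character(clones)) {
    clones <- tibble(clone_id = names(clones) %||%
                       sprintf("seq_%04d", seq_along(clones)),
                     insert_seq = unname(clones))
  }
  fragment_length <- check_count(fragment_length, "fragment_length", min = 4)
  if (min_sequence_length < fragment_length) {
    abort("`min_sequence_length` must be at least `fragment_length`.",
          class = "screenbin_invalid_parameter")
  }
  check_dna(clones$insert_seq, "insert_seq")

  len <- nchar(clones$insert_seq)
  keep <- len >= min_sequence_length
  excluded <- tibble(clone_id = clones$clone_id[!keep],
                     length = len[!keep],
                     reason = sprintf("shorter than %d bp",
                                      as.integer(min_sequence_length)))
  inc <- clones[keep, , drop = FALSE]
  n_frag <- nchar(inc$insert_seq) %/% fragment_length
  idx <- rep(seq_len(nrow(inc)), n_frag)
  within <- unlist(lapply(n_frag, seq_len), use.names = FALSE)
  offset <- (within - 1L) * fragment_length
  out <- tibble(
    fragment_id = sprintf("%s_f%04d", inc$clone_id[idx], within),
    clone_id = inc$clone_id[idx],
    offset = offset,
    frag_seq = substr(rep(inc$insert_seq, n_frag), offset + 1L,
                      offset + fragment_length))
  structure(out, excluded = excluded)
}

#' Tetranucleotide frequency vector of a fragment
#'
#' Counts every overlapping 4-mer along the fragment and, when
#' `strand_symmetric`, along its reverse complement as well (the insert
#' orientation in a fosmid is arbitrary). Windows containing `N` are
#' skipped. Counts are divided by the total number of counted windows, so
#' the vector sums to 1 whenever at least one valid window exists; a
#' fragment with no valid window returns the zero vector flagged with
#' `attr(, "no_valid_windows")`.
#'
#' @param fragment A DNA string of length >= 4 over {A,C,G,T,N}.
#' @param strand_symmetric Count both strands (default `TRUE`).
#' @return A named numeric vector of length 256 (4-mers in lexicographic
#'   order AAAA ... TTTT).
#' @examples
#' v <- tnf_vector(strrep("A", 100))
#' v[c("AAAA", "TTTT")]
#' @export
tnf_vector <- function(fragment, strand_symmetric = TRUE) {
  if (nchar(fragment) < 4) {
    abort("Fragment must be at least 4 bp.",
          class = "screenbin_invalid_parameter")
  }
  check_dna(fragment, "fragment")
  v <- seq_to_codes(fragment)
  counts <- tnf_counts(v)
  if (strand_symmetric) counts <- counts + tnf_counts(rev(3L - v))
  total <- sum(counts)
  out <- if (total > 0) counts / total else numeric(256)
  names(out) <- tnf_kmer_names()
  if (total == 0) attr(out, "no_valid_windows") <- TRUE
  out
}

# Sliding-window 4-mer counts from integer codes (NA windows skipped).
tnf_counts <- function(v) {
  L <- length(v)
  code <- v[1:(L - 3)] * 64L + v[2:(L - 2)] * 16L +
    v[3:(L - 1)] * 4L + v[4:L]
  tabulate(code[!is.na(code)] + 1L, nbins = 256L)
}

#' Tetranucleotide frequency matrix of a fragment set
#'
#' @param fragments A fragment tibble from [fragment_sequences()] (columns
#'   `fragment_id`, `frag_seq`).
#' @inheritParams tnf_vector
#' @return A numeric matrix, fragments x 256 4-mers (lexicographic column
#'   order); rownames are fragment ids. Fragment ids with no valid window
#'   are listed in `attr(, "no_valid_windows")`.
#' @export
tnf_matrix <- function(fragments, strand_symmetric = TRUE) {
  m <- t(vapply(fragments$frag_seq, function(s) {
    as.numeric(tnf_vector(s, strand_symmetric = strand_symmetric))
  }, numeric(256), USE.NAMES = FALSE))
  rownames(m) <- fragments$fragment_id
  colnames(m) <- tnf_kmer_names()
  empty <- rowSums(m) == 0
  if (any(empty)) attr(m, "no_valid_windows") <- fragments$fragment_id[empty]
  m
}

#' Normalize a feature matrix for map training
#'
#' `"zscore"` centers and scales each column by its population (divide-by-n)
#' standard deviation, mapping zero-variance columns to all zeros; `"none"`
#' returns the input unchanged.
#'
#' @param x A numeric matrix (rows = observations).
#' @param method `"zscore"` (default) or `"none"`.
#' @return The normalized matrix.
#' @export
normalize_features <- function(x, method = c("zscore", "none")) {
  method <- match.arg(method)
  if (method == "none") return(x)
  if (nrow(x) < 2) {
    abort("z-scoring needs at least 2 rows.",
          class = "screenbin_insufficient_data")
  }
  mu <- colMeans(x)
  sd <- sqrt(colMeans(sweep(x, 2, mu)^2))
  out <- sweep(x, 2, mu)
  nz <- sd > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sd[nz], "/")
  out[, !nz] <- 0
  out
}
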