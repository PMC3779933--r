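# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed when one is supplied; otherwise run
# in the ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min),
          class = "screenbin_invalid_parameter")
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name),
          class = "screenbin_invalid_parameter")
  }
  as.numeric(x)
}

check_dna <- function(x, name = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("`%s` contains characters outside {A, C, G, T, N}.", name),
          class = "screenbin_data_error")
  }
  invisible(x)
}

#' Well labels of a microtiter plate
#'
#' Row-major labels: A1..A12, B1..B12, ..., H12 for the default 8 x 12
#' (96-well) plate.
#'
#' @param n_rows,n_cols Plate dimensions (default 8 x 12).
#' @return Character vector of `n_rows * n_cols` well labels.
#' @export
well_labels <- function(n_rows = 8, n_cols = 12) {
  paste0(rep(LETTERS[seq_len(n_rows)], each = n_cols),
         rep(seq_len(n_cols), times = n_rows))
}

# Population (divide-by-n) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

DNA_BASES <- c("A", "C", "G", "T")

# All 256 tetranucleotides in lexicographic order (AAAA, AAAC, ..., TTTT).
tnf_kmer_names <- function() {
  g <- expand.grid(b4 = DNA_BASES, b3 = DNA_BASES, b2 = DNA_BASES,
                   b1 = DNA_BASES, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3, g$b4)
}

# Map a DNA string to integer codes A=0, C=1, G=2, T=3; N and anything else
# become NA (callers validate the alphabet separately).
seq_to_codes <- local({
  lut <- rep(NA_integer_, 127)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("T")] <- 3L
  function(s) lut[utf8ToInt(s)]
})

reverse_complement <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(s, NULL), function(x) {
    paste(rev(x), collapse = "")
  }, character(1)))
}
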