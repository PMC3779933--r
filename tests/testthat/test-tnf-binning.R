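test_that("fragmentation drops remainders and excludes short sequences", {
  withr::with_seed(1, {
    s35k <- random_dna(35000)
    s2k <- random_dna(2000)
    s1999 <- random_dna(1999)
  })
  f <- fragment_sequences(c(a = s35k, b = s2k, c = s1999))
  expect_equal(sum(f$clone_id == "a"), 17)
  expect_equal(sum(f$clone_id == "b"), 1)
  expect_false("c" %in% f$clone_id)
  excl <- attr(f, "excluded")
  expect_equal(excl$clone_id, "c")
  expect_true(all(nchar(f$frag_seq) == 2000))
  expect_equal(f$offset[f$clone_id == "a"], seq(0, 32000, by = 2000))
  expect_error(fragment_sequences(c(x = "ACGU")),
               class = "screenbin_data_error")
})

test_that("fragment counts are conserved as floor(length / 2000)", {
  withr::with_seed(2, {
    lens <- sample(1500:9000, 20)
    seqs <- vapply(lens, random_dna, "")
  })
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  f <- fragment_sequences(seqs)
  got <- table(factor(f$clone_id, levels = names(seqs)))
  expect_equal(as.integer(got), ifelse(lens >= 2000, lens %/% 2000, 0L))
})

test_that("TNF vectors match an independent window-count oracle", {
  skip_if_not_installed("Biostrings")
  withr::with_seed(3, {
    frags <- vapply(1:25, function(i) {
      random_dna(sample(100:2000, 1), alphabet = c("A", "C", "G", "T", "N"))
    }, "")
  })
  for (s in frags) {
    v <- tnf_vector(s)
    d <- Biostrings::DNAString(s)
    cnt <- Biostrings::oligonucleotideFrequency(d, 4) +
      Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(d), 4)
    o <- if (sum(cnt) > 0) cnt / sum(cnt) else as.numeric(cnt)
    expect_equal(unname(v), unname(o[names(v)]), tolerance = 1e-12)
  }
})

test_that("TNF respects strand symmetry, normalization and edge cases", {
  expect_equal(unname(tnf_vector(strrep("A", 2000))[c("AAAA", "TTTT")]),
               c(0.5, 0.5))
  withr::with_seed(4, s <- random_dna(2000))
  v <- tnf_vector(s)
  expect_equal(sum(v), 1)
  expect_equal(v, tnf_vector(reverse_complement(s)))
  # forward-only counts: L - k + 1 windows
  fwd <- tnf_vector(s, strand_symmetric = FALSE)
  expect_true(all(abs(fwd * 1997 - round(fwd * 1997)) < 1e-9))
  # all-N fragment: zero vector, flagged
  allN <- tnf_vector(strrep("N", 50))
  expect_equal(sum(allN), 0)
  expect_true(attr(allN, "no_valid_windows"))
  expect_error(tnf_vector("ACG"), class = "screenbin_invalid_parameter")
})

test_that("the TNF matrix is row-stochastic with lexicographic columns", {
  lib <- small_library(n_clones = 3, seed = 5)
  f <- fragment_sequences(lib)
  m <- tnf_matrix(f)
  expect_equal(colnames(m)[c(1, 2, 256)], c("AAAA", "AAAC", "TTTT"))
  expect_equal(unname(rowSums(m)), rep(1, nrow(m)))
  expect_equal(rownames(m), f$fragment_id)
  # reverse-complementing every fragment leaves the matrix unchanged
  f2 <- dplyr::mutate(f, frag_seq = reverse_complement(frag_seq))
  expect_equal(unname(tnf_matrix(f2)), unname(m))
})

test_that("z-scoring centres columns and zeroes constant ones", {
  withr::with_seed(6, x <- cbind(matrix(rnorm(40), ncol = 2), 3))
  z <- normalize_features(x)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(z[, 3] == 0))
  expect_identical(normalize_features(x, method = "none"), x)
  expect_error(normalize_features(x[1, , drop = FALSE]),
               class = "screenbin_insufficient_data")
})

test_that("map sizing follows the neurons-per-point rule", {
  withr::with_seed(7, x <- matrix(rnorm(100 * 4), ncol = 4))
  som <- train_esom(x, epochs = 2, seed = 1)
  expect_gte(som$grid_rows * som$grid_cols, ceiling(5.5 * 100))
  expect_equal(som$training_log$radius[1], 24)
  expect_equal(som$training_log$radius[nrow(som$training_log)], 1)
  expect_error(train_esom(x, grid_rows = 10, grid_cols = 10, seed = 1),
               class = "screenbin_invalid_parameter")
  expect_error(train_esom(x, start_radius = 1, end_radius = 5),
               class = "screenbin_invalid_parameter")
  # deterministic for a fixed seed
  som2 <- train_esom(x, epochs = 2, seed = 1)
  expect_identical(som$codebook, som2$codebook)
})

test_that("training pulls codebooks onto tight clusters", {
  withr::with_seed(8, {
    x <- rbind(matrix(rnorm(60 * 3, mean = 0, sd = 0.01), ncol = 3),
               matrix(rnorm(60 * 3, mean = 5, sd = 0.01), ncol = 3))
  })
  som <- train_esom(x, epochs = 10, start_radius = 6, seed = 2)
  b <- best_matching_unit(som, x)
  expect_lt(max(b$dist), 0.1)
  # identical inputs collapse every BMU codebook onto the common vector
  v <- matrix(rep(c(1, 2, 3), each = 20), ncol = 3)
  som_v <- train_esom(v, epochs = 3, start_radius = 3, seed = 3)
  bv <- best_matching_unit(som_v, v)
  expect_true(all(bv$dist < 1e-6))
})

test_that("best-matching unit equals exhaustive search and breaks ties row-major", {
  withr::with_seed(9, {
    som <- train_esom(matrix(rnorm(40), ncol = 4), epochs = 2,
                      start_radius = 3, seed = 4)
    for (i in 1:50) {
      q <- rnorm(4)
      b <- best_matching_unit(som, q)
      brute <- which.min(sqrt(rowSums(sweep(som$codebook, 2, q)^2)))
      expect_equal(b$neuron, as.integer(brute))
    }
  })
  # exact-match and duplicated-codebook tie cases
  W <- rbind(c(0, 0), c(1, 1), c(1, 1), c(5, 5), c(2, 0), c(0, 2))
  som <- manual_esom(W, grid_rows = 2, grid_cols = 3)
  expect_equal(best_matching_unit(som, c(5, 5))$neuron, 4L)
  tie <- best_matching_unit(som, c(1, 1))
  expect_equal(tie$neuron, 2L)  # lowest row-major index wins
  expect_equal(tie[, c("row", "col")],
               tibble::tibble(row = 1L, col = 2L))
  expect_error(best_matching_unit(som, c(1, 2, 3)),
               class = "screenbin_invalid_parameter")
})

test_that("the U-matrix is zero for uniform maps and ridges block boundaries", {
  flat <- manual_esom(matrix(1, 36, 2), 6, 6)
  expect_true(all(compute_umatrix(flat) == 0))

  # rows 1-3 hold codebook (0,0), rows 4-6 hold (10,10); on a torus the
  # interior rows are 2 and 5, all other rows touch the opposite block
  W <- matrix(0, 36, 2)
  W[rep(1:6, each = 6) >= 4, ] <- 10
  block <- manual_esom(W, 6, 6)
  u <- compute_umatrix(block)
  expect_true(all(u >= 0))
  expect_true(all(u[c(2, 5), ] == 0))
  expect_true(all(u[c(1, 3, 4, 6), ] > 0))
})

test_that("watershed bin extraction finds basins and honours q", {
  W <- matrix(0, 36, 2)
  W[rep(1:6, each = 6) >= 4, ] <- 10
  block <- manual_esom(W, 6, 6)
  u <- compute_umatrix(block)
  # q low enough to keep only the zero-height interiors: two ring basins
  part <- extract_bins(block, u, q = 30, min_neurons = 3)
  expect_equal(attr(part, "n_bins"), 2)
  expect_equal(as.integer(table(part$bin[part$bin > 0])), c(6L, 6L))
  # q = 100 spans the whole (connected) map with a single bin
  all_in <- extract_bins(block, u, q = 100, min_neurons = 1)
  expect_equal(attr(all_in, "n_bins"), 1)
  expect_true(all(all_in$bin == 1))
  # an all-identical map is one single bin
  flat <- manual_esom(matrix(1, 36, 2), 6, 6)
  expect_equal(attr(extract_bins(flat, q = 60), "n_bins"), 1)
  expect_error(extract_bins(block, u, q = 0),
               class = "screenbin_invalid_parameter")
  # k-medoids alternative partitions every neuron into k bins
  km <- extract_bins(block, method = "kmedoids", k = 2)
  expect_equal(attr(km, "n_bins"), 2)
  expect_true(all(km$bin > 0))
})

test_that("thin low saddles merge basins; high ridges keep them apart", {
  # 8x8 ring map (d = 1): a low thin ridge at column 4 splits two zero
  # basins; a high thin ridge at column 8 is a real boundary
  W <- matrix(0, 64, 1)
  col_of <- (seq_len(64) - 1) %% 8 + 1
  W[col_of == 4, ] <- 0.5
  W[col_of == 8, ] <- 5
  som <- manual_esom(W, 8, 8)
  u <- compute_umatrix(som)
  # foreground = the four flat columns; the saddle at column 4 is thin and
  # low, so hysteresis merges across it
  merged <- extract_bins(som, u, q = 50, merge_q = 80, min_neurons = 3)
  expect_equal(attr(merged, "n_bins"), 1)
  # with merging disabled the two basins stay distinct
  split <- extract_bins(som, u, q = 50, merge_q = 50, min_neurons = 3)
  expect_equal(attr(split, "n_bins"), 2)
})

test_that("clones inherit the plurality bin of their fragments", {
  part <- tibble::tibble(neuron = 1:4, bin = c(1L, 2L, 0L, 3L))
  bmu <- function(clone, neurons, dist = 1) {
    tibble::tibble(fragment_id = sprintf("%s_f%02d", clone,
                                         seq_along(neurons)),
                   clone_id = clone, neuron = neurons, dist = dist)
  }
  # [A,A,A,B,B] -> A with majority fraction 0.6
  a <- assign_clones(bmu("c1", c(1, 1, 1, 2, 2)), part)
  expect_equal(a$bin, 1L)
  expect_equal(a$majority_fraction, 0.6)
  expect_false(a$tie)
  # a single fragment assigns its bin with fraction 1
  s <- assign_clones(bmu("c2", 4), part)
  expect_equal(s$bin, 3L)
  expect_equal(s$majority_fraction, 1)
  # [A,A,B,B] tie resolved toward the closer codebook, flagged
  t <- assign_clones(
    bmu("c3", c(1, 1, 2, 2), dist = c(2, 2, 0.5, 0.5)), part)
  expect_equal(t$bin, 2L)
  expect_true(t$tie)
  # boundary fragments are ignored unless the clone has nothing else
  m <- assign_clones(bmu("c4", c(3, 3, 1)), part)
  expect_equal(m$bin, 1L)
  expect_equal(m$majority_fraction, 1)
  z <- assign_clones(bmu("c5", c(3, 3)), part)
  expect_equal(z$bin, 0L)
})
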