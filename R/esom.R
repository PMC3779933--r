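#' Train an emergent self-organizing map (ESOM) on a feature matrix
#'
#' An emergent map uses many more neurons than data points (default 5.5
#' neurons per point) so that cluster structure emerges as low-distance
#' basins on the U-matrix rather than one-neuron-per-cluster quantization.
#' The grid is toroidal (edges wrap), which avoids border artifacts. Training
#' is the classic online algorithm: for each sample the best-matching unit
#' (Euclidean argmin) is found and all neurons within the current radius are
#' pulled toward the sample under a Gaussian neighborhood kernel; radius and
#' learning rate decay linearly over epochs. The codebook is initialized
#' uniformly within the per-feature data range. Fully deterministic for a
#' fixed seed.
#'
#' @param x Numeric matrix of training vectors (e.g. a z-scored TNF matrix),
#'   at least 2 rows.
#' @param neurons_per_point Map size per data point (default 5.5); the grid
#'   satisfies `rows * cols >= ceiling(neurons_per_point * nrow(x))`.
#' @param start_radius,end_radius Neighborhood radius (grid units) at the
#'   first and last epoch (defaults 24 and 1).
#' @param epochs Training epochs (default 20).
#' @param lr_start,lr_end Learning rate at the first and last epoch
#'   (defaults 0.5, 0.05).
#' @param grid_aspect Target columns/rows ratio (default 1.6).
#' @param grid_rows,grid_cols Optional explicit grid; must satisfy the
#'   neurons-per-point requirement.
#' @param seed Optional integer seed.
#' @return An object of class `esom`: list with `codebook` (neurons x
#'   features, row-major neuron order), `grid_rows`, `grid_cols`,
#'   `training_log` (epoch, radius, learning_rate) and the call parameters.
#' @examples
#' x <- matrix(rnorm(200), ncol = 4)
#' som <- train_esom(x, epochs = 2, start_radius = 3, seed = 1)
#' glance(som)
#' @export
train_esom <- function(x, neurons_per_point = 5.5, start_radius = 24,
                       end_radius = 1, epochs = 20, lr_start = 0.5,
                       lr_end = 0.05, grid_aspect = 1.6, grid_rows = NULL,
                       grid_cols = NULL, seed = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) {
    abort("Training needs at least 2 rows.",
          class = "screenbin_insufficient_data")
  }
  if (start_radius < end_radius || end_radius < 0) {
    abort("Radii must satisfy start_radius >= end_radius >= 0.",
          class = "screenbin_invalid_parameter")
  }
  epochs <- check_count(epochs, "epochs")
  required <- as.integer(ceiling(neurons_per_point * nrow(x)))
  if (is.null(grid_rows) || is.null(grid_cols)) {
    grid_rows <- max(2L, as.integer(floor(sqrt(required / grid_aspect))))
    grid_cols <- as.integer(ceiling(required / grid_rows))
  } else {
    grid_rows <- check_count(grid_rows, "grid_rows", min = 1)
    grid_cols <- check_count(grid_cols, "grid_cols", min = 1)
    if (grid_rows * grid_cols < required) {
      abort(sprintf("Grid %d x %d is smaller than the required %d neurons.",
                    grid_rows, grid_cols, required),
            class = "screenbin_invalid_parameter")
    }
  }
  fit <- with_seed(seed, {
    esom_train_cpp(x, grid_rows, grid_cols, epochs, start_radius,
                   end_radius, lr_start, lr_end)
  })
  codebook <- fit$codebook
  colnames(codebook) <- colnames(x)
  structure(list(
    codebook = codebook,
    grid_rows = grid_rows,
    grid_cols = grid_cols,
    training_log = tibble(epoch = seq_len(epochs),
                          radius = fit$radius,
                          learning_rate = fit$learning_rate),
    params = list(neurons_per_point = neurons_per_point,
                  start_radius = start_radius, end_radius = end_radius,
                  epochs = epochs, lr_start = lr_start, lr_end = lr_end,
                  grid_aspect = grid_aspect, topology = "toroidal",
                  seed = seed),
    n_train = nrow(x)), class = "esom")
}

#' @export
print.esom <- function(x, ...) {
  cat(sprintf(paste0("<esom> toroidal %d x %d grid (%d neurons, %.1f per ",
                     "training point), %d features, %d epochs\n"),
              x$grid_rows, x$grid_cols, x$grid_rows * x$grid_cols,
              x$grid_rows * x$grid_cols / x$n_train, ncol(x$codebook),
              x$params$epochs))
  invisible(x)
}

#' @describeIn train_esom One row per epoch of the training schedule.
#' @param ... Unused.
#' @export
tidy.esom <- function(x, ...) x$training_log

#' @describeIn train_esom One-row map summary.
#' @export
glance.esom <- function(x, ...) {
  tibble(grid_rows = x$grid_rows, grid_cols = x$grid_cols,
         n_neurons = x$grid_rows * x$grid_cols, n_features = ncol(x$codebook),
         n_train = x$n_train, epochs = x$params$epochs,
         start_radius = x$params$start_radius,
         end_radius = x$params$end_radius)
}

# 1-based row-major neuron index <-> grid coordinates
neuron_coords <- function(som, neuron) {
  tibble(row = (neuron - 1L) %/% som$grid_cols + 1L,
         col = (neuron - 1L) %% som$grid_cols + 1L)
}

#' Best-matching unit(s) on a trained map
#'
#' Finds, for each input vector, the neuron with minimal Euclidean distance
#' to its codebook vector. Ties break to the lowest row-major (row, col)
#' index.
#'
#' @param som A trained [train_esom()] map.
#' @param x A vector of length `ncol(codebook)` or a matrix with that many
#'   columns (one row per query).
#' @return A tibble with one row per query: `row`, `col`, `neuron` (1-based
#'   row-major index) and `dist` (Euclidean distance to the codebook).
#' @export
best_matching_unit <- function(som, x) {
  stopifnot(inherits(som, "esom"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != ncol(som$codebook)) {
    abort(sprintf("Query dimension %d does not match the codebook (%d).",
                  ncol(x), ncol(som$codebook)),
          class = "screenbin_invalid_parameter")
  }
  W <- som$codebook
  d2 <- outer(rep(1, nrow(x)), rowSums(W^2)) - 2 * tcrossprod(x, W) +
    rowSums(x^2)
  neuron <- max.col(-d2, ties.method = "first")
  dist <- sqrt(pmax(0, d2[cbind(seq_len(nrow(x)), neuron)]))
  bind_cols(neuron_coords(som, neuron), tibble(neuron = neuron, dist = dist))
}

#' U-matrix of a trained map
#'
#' The U-matrix height of a neuron is the mean Euclidean distance between
#' its codebook vector and those of its 8 toroidal grid neighbors. Ridges of
#' high height separate basins of similar neurons; genome bins appear as
#' low-height basins.
#'
#' @param som A trained [train_esom()] map.
#' @return A `grid_rows` x `grid_cols` numeric matrix of class `umatrix`.
#' @export
compute_umatrix <- function(som) {
  stopifnot(inherits(som, "esom"))
  W <- som$codebook
  rows <- som$grid_rows
  cols <- som$grid_cols
  m <- rows * cols
  r <- (seq_len(m) - 1L) %/% cols
  c <- (seq_len(m) - 1L) %% cols
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  acc <- numeric(m)
  for (i in seq_len(nrow(shifts))) {
    r2 <- (r + shifts$dr[i]) %% rows
    c2 <- (c + shifts$dc[i]) %% cols
    idx <- r2 * cols + c2 + 1L
    acc <- acc + sqrt(rowSums((W - W[idx, , drop = FALSE])^2))
  }
  structure(matrix(acc / nrow(shifts), nrow = rows, ncol = cols,
                   byrow = TRUE), class = "umatrix")
}
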