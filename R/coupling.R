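#' Build distance-dependent coupling weight matrices
#'
#' Computes the excitatory and inhibitory spatial weight matrices of the
#' recurrent network. The weight from neuron `i` to neuron `j` is
#' `g * exp(-d_ij^2 / (2 sigma^2))` for the Gaussian kernel or
#' `g * exp(-d_ij / sigma)` for the exponential variant, with `d_ij` the 3D
#' Euclidean distance in micrometres. Self-coupling (`d = 0`, weight `g`) is
#' included. Cross-hemisphere entries are multiplied by
#' `params$interhemi_factor`. If `params$prune_fraction > 0`, that fraction
#' of the non-zero off-diagonal connections of each matrix is zeroed at
#' random and the surviving weights are divided by `1 - prune_fraction`, so
#' the expected total coupling is preserved.
#'
#' Weights below `cutoff * g` are truncated to zero and the matrices are
#' stored sparse; with the short-range excitatory kernel this makes the
#' excitatory matrix extremely sparse.
#'
#' @param neurons A neuron table from [generate_positions()] (needs columns
#'   `x`, `y`, `z`, `hemisphere`).
#' @param params A [model_params()] object.
#' @param seed Seed for the pruning draw (only used if
#'   `prune_fraction > 0`).
#' @param cutoff Relative sparsity cutoff (default `1e-6`).
#' @return A list with sparse matrices `E` and `I` (class `dgCMatrix`,
#'   neurons x neurons, entry `[i, j]` = weight from presynaptic `i` to
#'   postsynaptic `j`).
#' @examples
#' nt <- generate_positions(50, seed = 1)
#' W <- build_coupling(nt, optimized_params())
#' dim(W$E)
#' @export
build_coupling <- function(neurons, params, seed = 1L, cutoff = 1e-6) {
  if (nrow(neurons) == 0L) abort("`neurons` is empty")
  pts <- as.matrix(neurons[, c("x", "y", "z")])
  if (!all(is.finite(pts))) abort("neuron positions must be finite")
  n <- nrow(pts)
  cross <- outer(neurons$hemisphere, neurons$hemisphere, `!=`)
  kernel_mat <- function(g, sigma) {
    if (g == 0) {
      return(Matrix(0, n, n, sparse = TRUE))
    }
    # blockwise over columns to bound memory on large networks
    block <- max(1L, floor(2e7 / n))
    triplets_i <- vector("list", 0L)
    triplets_j <- vector("list", 0L)
    triplets_x <- vector("list", 0L)
    for (start in seq(1L, n, by = block)) {
      cols <- start:min(start + block - 1L, n)
      d2 <- outer(pts[, 1]^2 + pts[, 2]^2 + pts[, 3]^2,
                  rep(1, length(cols))) +
        outer(rep(1, n), pts[cols, 1]^2 + pts[cols, 2]^2 + pts[cols, 3]^2) -
        2 * pts %*% t(pts[cols, , drop = FALSE])
      d2[d2 < 0] <- 0
      w <- if (params$kernel_shape == "gaussian") {
        g * exp(-d2 / (2 * sigma^2))
      } else {
        g * exp(-sqrt(d2) / sigma)
      }
      w[cross[, cols, drop = FALSE]] <-
        w[cross[, cols, drop = FALSE]] * params$interhemi_factor
      keep <- which(w >= cutoff * g, arr.ind = TRUE)
      triplets_i[[length(triplets_i) + 1L]] <- keep[, 1L]
      triplets_j[[length(triplets_j) + 1L]] <- cols[keep[, 2L]]
      triplets_x[[length(triplets_x) + 1L]] <- w[keep]
    }
    sparseMatrix(i = unlist(triplets_i), j = unlist(triplets_j),
                 x = unlist(triplets_x), dims = c(n, n))
  }
  E <- kernel_mat(params$g_e, params$sigma_e)
  I <- kernel_mat(params$g_i, params$sigma_i)
  if (params$prune_fraction > 0) {
    E <- prune_matrix(E, params$prune_fraction, child_seed(seed, 11L))
    I <- prune_matrix(I, params$prune_fraction, child_seed(seed, 12L))
  }
  list(E = E, I = I)
}

# Zero a random fraction of the off-diagonal non-zero entries and rescale
# survivors by 1 / (1 - p).
prune_matrix <- function(W, p, seed) {
  W <- methods::as(W, "TsparseMatrix")
  off <- which(W@i != W@j)
  n_drop <- round(length(off) * p)
  with_seed(seed, {
    drop <- sample(off, n_drop)
    keep <- setdiff(seq_along(W@x), drop)
    out <- sparseMatrix(i = W@i[keep] + 1L, j = W@j[keep] + 1L,
                        x = W@x[keep] / (1 - p), dims = dim(W))
    out
  })
}
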