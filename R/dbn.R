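#' Energy of a restricted Boltzmann machine configuration
#'
#' For a joint configuration of binary visible vector `v` and hidden vector
#' `h`, the energy is \eqn{E(v,h) = -a^T v - b^T h - v^T W h}: low energy
#' means high probability under the model's Boltzmann distribution.
#'
#' @param rbm an [RBM].
#' @param v binary visible vector (length `nrow(W)`).
#' @param h binary hidden vector (length `ncol(W)`).
#' @return a single real number.
#' @export
rbmEnergy <- function(rbm, v, h) {
  .checkBinaryVec(v, nrow(rbm@W), "v")
  .checkBinaryVec(h, ncol(rbm@W), "h")
  -sum(rbm@visibleBias * v) - sum(rbm@hiddenBias * h) -
    drop(v %*% rbm@W %*% h)
}

.checkBinaryVec <- function(x, len, what) {
  if (length(x) != len)
    stop(sprintf("%s must have length %d (got %d)", what, len, length(x)),
         call. = FALSE)
  if (!all(x %in% c(0, 1)))
    stop(what, " must be binary", call. = FALSE)
  invisible(TRUE)
}

## all binary vectors of length n as rows of a 2^n x n matrix
## (first unit fastest)
.binaryGrid <- function(n) {
  if (n == 0L) return(matrix(0, 1, 0))
  g <- as.matrix(expand.grid(replicate(n, c(0, 1), simplify = FALSE)))
  dimnames(g) <- NULL
  g
}

#' Exhaustive joint probability table of a small RBM
#'
#' Enumerates all `2^(m+n)` configurations and normalizes
#' `exp(-E(v, h))` by the partition function Z. Only feasible for tiny
#' models; the guard refuses `m + n > 16`. This is the package's exact
#' reference for checking the factorized conditionals and marginals.
#'
#' @param rbm an [RBM] with `m + n <= 16` units.
#' @return a list with `vConfigs` (`2^m x m`), `hConfigs` (`2^n x n`),
#'   `prob` (`2^m x 2^n` joint probabilities), `energy` (same shape)
#'   and `logZ`.
#' @export
rbmJointTable <- function(rbm) {
  m <- nrow(rbm@W); n <- ncol(rbm@W)
  if (m + n > 16L)
    stop("exhaustive enumeration refused for m + n > 16 units",
         call. = FALSE)
  V <- .binaryGrid(m); H <- .binaryGrid(n)
  ## E[v,h] = -(a.v) - (b.h) - v W h, vectorized over the two grids
  E <- -outer(drop(V %*% rbm@visibleBias), drop(H %*% rbm@hiddenBias), "+") -
    V %*% rbm@W %*% t(H)
  lw <- -E
  logZ <- max(lw) + log(sum(exp(lw - max(lw))))
  list(vConfigs = V, hConfigs = H, prob = exp(lw - logZ), energy = E,
       logZ = logZ)
}

#' Factorized RBM conditionals
#'
#' Because the RBM graph is bipartite, hidden units are conditionally
#' independent given the visibles (and vice versa):
#' `P(h_j = 1 | v) = logistic(b_j + sum_i v_i W_ij)` and symmetrically for
#' the visibles. Inputs may be a single vector or a matrix with one
#' configuration per row.
#'
#' @param rbm an [RBM].
#' @param v,h binary vector or matrix of configurations (rows).
#' @return vector (or matrix of rows) of unit-wise activation
#'   probabilities, all strictly inside (0, 1).
#' @rdname conditionals
#' @export
conditionalHidden <- function(rbm, v) {
  if (is.matrix(v)) {
    if (ncol(v) != nrow(rbm@W)) stop("shape mismatch", call. = FALSE)
    .sigmoid(sweep(v %*% rbm@W, 2, rbm@hiddenBias, "+"))
  } else {
    if (length(v) != nrow(rbm@W)) stop("shape mismatch", call. = FALSE)
    .sigmoid(drop(v %*% rbm@W) + rbm@hiddenBias)
  }
}

#' @rdname conditionals
#' @export
conditionalVisible <- function(rbm, h) {
  if (is.matrix(h)) {
    if (ncol(h) != ncol(rbm@W)) stop("shape mismatch", call. = FALSE)
    .sigmoid(sweep(h %*% t(rbm@W), 2, rbm@visibleBias, "+"))
  } else {
    if (length(h) != ncol(rbm@W)) stop("shape mismatch", call. = FALSE)
    .sigmoid(drop(rbm@W %*% h) + rbm@visibleBias)
  }
}

#' Train one RBM by single-step contrastive divergence
#'
#' Minibatch CD-1: sample hidden states from the data, reconstruct visible
#' means, recompute hidden means from the reconstruction, and take the
#' difference of the two outer products as the (approximate) gradient of
#' the log-likelihood. Weights start at small Gaussian values, biases at
#' zero. Fully deterministic under `seed`.
#'
#' @param data binary matrix, one training case per row.
#' @param nHidden number of hidden units.
#' @param lr learning rate (default 0.05).
#' @param batchSize minibatch size (default 32).
#' @param epochs number of sweeps through the data (default 100).
#' @param seed integer seed.
#' @return an [RBM].
#' @export
trainRBM <- function(data, nHidden, lr = 0.05, batchSize = 32L,
                     epochs = 100L, seed = 1L) {
  if (!is.matrix(data) || !all(data %in% c(0, 1)))
    stop("training data must be a binary matrix", call. = FALSE)
  stopifnot(nHidden >= 1L)
  m <- ncol(data); nc <- nrow(data)
  .withSeed(seed, {
    W <- matrix(stats::rnorm(m * nHidden, sd = 0.01), m, nHidden)
    a <- numeric(m); b <- numeric(nHidden)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nc)
      for (start in seq(1L, nc, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, nc)]
        V0 <- data[idx, , drop = FALSE]
        k <- nrow(V0)
        Ph0 <- .sigmoid(sweep(V0 %*% W, 2, b, "+"))
        H0 <- (matrix(stats::runif(k * nHidden), k) < Ph0) * 1
        V1 <- .sigmoid(sweep(H0 %*% t(W), 2, a, "+"))
        Ph1 <- .sigmoid(sweep(V1 %*% W, 2, b, "+"))
        W <- W + lr * (crossprod(V0, Ph0) - crossprod(V1, Ph1)) / k
        a <- a + lr * colMeans(V0 - V1)
        b <- b + lr * colMeans(Ph0 - Ph1)
      }
    }
    new("RBM", W = W, visibleBias = a, hiddenBias = b)
  })
}

#' Greedily train a stacked-RBM deep belief network
#'
#' Trains three RBM layers bottom-up: each layer learns to model the
#' (sampled) hidden states of the layer below. Requested layer sizes are
#' clipped so no layer is wider than its input. The trained stack is used
#' as a deterministic encoder (see [encodeFeatures()]).
#'
#' @param data binary matrix of visible configurations (rows).
#' @param layerSizes hidden sizes of the three layers, default
#'   `c(256, 128, 64)` before clipping.
#' @param lr,batchSize,epochs contrastive-divergence hyperparameters,
#'   shared across layers.
#' @param seed integer seed.
#' @return a [DBN].
#' @export
trainDBN <- function(data, layerSizes = c(256L, 128L, 64L), lr = 0.05,
                     batchSize = 32L, epochs = 100L, seed = 1L) {
  if (!is.matrix(data) || !all(data %in% c(0, 1)))
    stop("training data must be a binary matrix", call. = FALSE)
  stopifnot(length(layerSizes) == 3L)
  layers <- vector("list", 3L)
  input <- data
  sizes <- integer(3L)
  for (k in 1:3) {
    nh <- min(as.integer(layerSizes[k]), ncol(input))
    nh <- max(nh, 1L)
    sizes[k] <- nh
    layers[[k]] <- trainRBM(input, nh, lr = lr, batchSize = batchSize,
                            epochs = epochs, seed = seed + k)
    ## next layer trains on sampled binary hidden states, keeping the
    ## binary-visible contract of CD
    Ph <- conditionalHidden(layers[[k]], input)
    input <- .withSeed(seed, offset = 7000L + k,
                       (matrix(stats::runif(length(Ph)), nrow(Ph)) < Ph) * 1)
  }
  new("DBN", layers = layers, trained = rep(TRUE, 3L),
      hyperparams = list(layerSizes = sizes, lr = lr,
                         batchSize = as.integer(batchSize),
                         epochs = as.integer(epochs),
                         seed = as.integer(seed)))
}

#' Encode features through a trained deep belief network
#'
#' Deterministic mean-field forward pass: each layer maps its input through
#' the factorized hidden conditional and passes on the activation
#' probabilities (no sampling), so identical inputs always yield identical
#' codes in `(0, 1)`.
#'
#' @param dbn a trained [DBN].
#' @param features a [FeatureMatrix] or binary matrix whose columns match
#'   the first layer's visible size.
#' @return a real matrix, rows aligned with the input rows, with as many
#'   columns as the top layer has hidden units.
#' @export
encodeFeatures <- function(dbn, features) {
  if (!length(dbn@layers) || !all(dbn@trained))
    stop("DBN is not trained", call. = FALSE)
  X <- if (is(features, "FeatureMatrix")) features@values else features
  if (ncol(X) != nrow(dbn@layers[[1]]@W))
    stop(sprintf("feature columns (%d) do not match DBN visible size (%d)",
                 ncol(X), nrow(dbn@layers[[1]]@W)), call. = FALSE)
  H <- X
  for (layer in dbn@layers) H <- conditionalHidden(layer, H)
  rownames(H) <- rownames(X)
  H
}
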