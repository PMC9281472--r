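#' Reduce gene and disease features to a shared low-dimensional space
#'
#' All three reducers operate on the row-concatenation of the disease and
#' gene feature matrices (possible because both share one miRNA column
#' universe), so both node types land in a single embedding space:
#'
#' * `"dbn"` — the deep belief network ([trainDBN()] then
#'   [encodeFeatures()]); output dimension is the top layer's size.
#' * `"pca"` — principal components (centered, unscaled), truncated to
#'   `dim` components.
#' * `"tsne"` — the package's exact t-SNE, fixed at 2 output dimensions;
#'   t-SNE has no out-of-sample transform, so the map is fitted on all
#'   rows jointly (transductive) and downstream reports flag this.
#'
#' @param diseaseFeatures,geneFeatures [FeatureMatrix] objects sharing the
#'   same columns.
#' @param method `"dbn"`, `"pca"` or `"tsne"`.
#' @param dim target dimension for dbn/pca (default 64; clipped to the
#'   available dimensions). Ignored by t-SNE, which is 2-dimensional.
#' @param seed integer seed.
#' @param dbnLayerSizes,dbnEpochs,dbnLr,dbnBatch DBN hyperparameters,
#'   defaults `c(256, 128, dim)`, 100 epochs, learning rate 0.05, batch 32.
#' @return a real matrix with one row per node (diseases first, then
#'   genes; rownames carry the ids).
#' @export
reduceFeatures <- function(diseaseFeatures, geneFeatures,
                           method = c("dbn", "pca", "tsne"), dim = 64L,
                           seed = 1L,
                           dbnLayerSizes = c(256L, 128L, dim),
                           dbnEpochs = 100L, dbnLr = 0.05,
                           dbnBatch = 32L) {
  method <- match.arg(method)
  stopifnot(identical(colIds(diseaseFeatures), colIds(geneFeatures)))
  X <- rbind(featureValues(diseaseFeatures), featureValues(geneFeatures))
  switch(method,
    dbn = {
      dbn <- trainDBN(X, layerSizes = dbnLayerSizes, lr = dbnLr,
                      batchSize = dbnBatch, epochs = dbnEpochs,
                      seed = seed)
      encodeFeatures(dbn, X)
    },
    pca = {
      k <- min(dim, ncol(X), nrow(X) - 1L)
      pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
      out <- pc$x[, seq_len(k), drop = FALSE]
      rownames(out) <- rownames(X)
      out
    },
    tsne = tsneReduce(X, dims = 2L, seed = seed)
  )
}

#' Exact t-distributed stochastic neighbor embedding
#'
#' A compact O(n^2) implementation of the standard algorithm: Gaussian
#' input affinities with per-point bandwidths calibrated by bisection to a
#' target perplexity, symmetrized and exaggerated early; Student-t output
#' affinities; gradient descent with momentum. Intended for the desk-scale
#' node sets this package works with (hundreds of rows).
#'
#' @param X numeric matrix (rows are observations).
#' @param dims output dimensionality (2 by default; the method is only
#'   meaningful at 2-3).
#' @param perplexity target perplexity (default 30, clipped to
#'   `(n - 1) / 3`).
#' @param maxIter gradient-descent iterations (default 300).
#' @param seed integer seed for the initial layout.
#' @return an n x `dims` embedding matrix (rownames preserved).
#' @export
tsneReduce <- function(X, dims = 2L, perplexity = 30, maxIter = 300L,
                       seed = 1L) {
  n <- nrow(X)
  stopifnot(n >= 4L)
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { p <- rep(1 / length(di), length(di)); break }
      p <- w / sw
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else { betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  .withSeed(seed, offset = 77L, {
    Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
    dY <- matrix(0, n, dims)
    momentum <- 0.5
    eta <- 200
    for (it in seq_len(maxIter)) {
      Pe <- if (it <= 100) P * 12 else P   # early exaggeration
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      if (it == 21) momentum <- 0.8
      dY <- momentum * dY - eta * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    rownames(Y) <- rownames(X)
    Y
  })
}
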