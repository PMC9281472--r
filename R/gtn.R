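.NORM_EPS <- 1e-12

#' Initialize a graph transformer network model
#'
#' Creates randomly initialized parameters: per-channel edge-type selection
#' logits (near-zero, i.e. near-uniform softmax), Glorot-scaled GCN weights
#' shared across channels, and a one-hidden-layer logistic head over the
#' concatenated disease/gene embedding pair.
#'
#' @param nEdgeTypes depth of the adjacency stack the model selects from.
#' @param inDim input feature dimension (columns of the reduced feature
#'   matrix X).
#' @param channels number of meta-path channels (default 2).
#' @param slots edge-type selections per channel, i.e. the meta-path length
#'   (default 2).
#' @param gcnWidth width of each GCN layer (default 64).
#' @param gcnLayers number of GCN layers (default 1; see the
#'   methods vignette for why depth 1 is the default).
#' @param headHidden hidden units of the link-prediction head (default 64).
#' @param seed integer seed for the initialization draws.
#' @return an untrained [GTNModel].
#' @export
gtnModel <- function(nEdgeTypes, inDim, channels = 2L, slots = 2L,
                     gcnWidth = 64L, gcnLayers = 1L, headHidden = 64L,
                     seed = 1L) {
  stopifnot(nEdgeTypes >= 1L, inDim >= 1L, channels >= 1L, slots >= 1L,
            gcnLayers >= 1L)
  .withSeed(seed, offset = 11L, {
    glorot <- function(nin, nout)
      matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))),
             nin, nout)
    sel <- replicate(channels,
                     matrix(stats::rnorm(slots * nEdgeTypes, sd = 0.01),
                            slots, nEdgeTypes),
                     simplify = FALSE)
    dims <- c(inDim, rep(gcnWidth, gcnLayers))
    gcn <- lapply(seq_len(gcnLayers),
                  function(l) glorot(dims[l], dims[l + 1]))
    pairDim <- 3L * channels * gcnWidth
    head <- list(V = glorot(pairDim, headHidden),
                 c0 = numeric(headHidden),
                 w = matrix(stats::rnorm(headHidden, sd = 0.01),
                            headHidden, 1),
                 b = 0)
    new("GTNModel", selectionLogits = sel, gcnWeights = gcn,
        headParams = head,
        config = list(nEdgeTypes = as.integer(nEdgeTypes),
                      inDim = as.integer(inDim),
                      channels = as.integer(channels),
                      slots = as.integer(slots),
                      gcnWidth = as.integer(gcnWidth),
                      gcnLayers = as.integer(gcnLayers),
                      headHidden = as.integer(headHidden)),
        trained = FALSE)
  })
}

#' Softmax-weighted edge-type selection
#'
#' The 1x1-convolution step of a graph transformer layer: softmax over the
#' edge-type logits yields convex combination weights, and the selected
#' matrix is the corresponding weighted sum of the adjacency stack,
#' `Q = sum_t alpha_t A_t` with `alpha = softmax(logits)`.
#'
#' @param stack list of equally sized square adjacency matrices (or a
#'   [HeterogeneousGraph], whose stack is used).
#' @param logits numeric vector, one logit per edge type.
#' @return the convex combination matrix Q.
#' @export
selectEdgeType <- function(stack, logits) {
  if (is(stack, "HeterogeneousGraph")) stack <- adjacencyStack(stack)
  if (length(logits) != length(stack))
    stop(sprintf("need %d logits, got %d", length(stack), length(logits)),
         call. = FALSE)
  alpha <- .softmax(logits)
  Q <- alpha[1] * stack[[1]]
  for (t in seq_along(stack)[-1]) Q <- Q + alpha[t] * stack[[t]]
  Q
}

#' Compose two edge-type selections into a meta-path adjacency
#'
#' The matrix product `Q1 %*% Q2` connects i to j exactly when a two-step
#' path i -> k -> j has positive weight in both factors; it is then
#' row-normalized (degree-normalized by the product's out-degree) so that
#' repeated composition cannot blow up edge magnitudes.
#'
#' @param Q1,Q2 square matrices of equal size.
#' @param normalize row-normalize the product (default `TRUE`); set to
#'   `FALSE` to inspect the raw product.
#' @return the (normalized) meta-path adjacency.
#' @export
composeMetapath <- function(Q1, Q2, normalize = TRUE) {
  if (!all(dim(Q1) == dim(Q2)) || nrow(Q1) != ncol(Q1))
    stop("Q1 and Q2 must be square matrices of equal size", call. = FALSE)
  M <- Q1 %*% Q2
  if (!normalize) return(M)
  r <- pmax(rowSums(M), .NORM_EPS)
  M / r
}

#' One graph-convolution layer
#'
#' Adds self-loops, symmetrically degree-normalizes
#' (`P = D^{-1/2} (A + I) D^{-1/2}`), propagates and applies the
#' activation: `H' = act(P H W)`. With self-loops no node can have zero
#' degree, and the propagation operator's spectral norm is at most 1.
#'
#' @param H node feature/state matrix (nodes x in_dim).
#' @param A square non-negative adjacency (e.g. a meta-path adjacency).
#' @param W weight matrix (in_dim x out_dim).
#' @param activation `"relu"` (default) or `"identity"`.
#' @return the propagated state matrix (nodes x out_dim).
#' @export
gcnLayer <- function(H, A, W, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (any(A < 0)) stop("adjacency must be non-negative", call. = FALSE)
  if (nrow(A) != ncol(A) || nrow(H) != nrow(A) || ncol(H) != nrow(W))
    stop("incompatible shapes in gcnLayer", call. = FALSE)
  P <- .gcnPropagator(A)
  S <- P %*% (H %*% W)
  if (activation == "relu") .relu(S) else S
}

## D^{-1/2} (A + I) D^{-1/2} with self-loops
.gcnPropagator <- function(A) {
  At <- A
  diag(At) <- diag(At) + 1
  s <- 1 / sqrt(rowSums(At))
  At * outer(s, s)
}

#' Encode all nodes of a heterogeneous graph
#'
#' Full forward pass of the graph transformer encoder: per channel, the two
#' (or more) selection slots pick softmax-weighted edge-type combinations,
#' their composed meta-path adjacency drives the configured number of GCN
#' layers over the reduced feature matrix, and channel outputs are
#' concatenated column-wise. Deterministic given the parameters.
#'
#' @param graph a [HeterogeneousGraph] (or plain list of square matrices).
#' @param X reduced node feature matrix, rows in graph node order.
#' @param model a [GTNModel] whose `inDim` matches `ncol(X)`.
#' @return the node embedding matrix (nodes x channels * gcnWidth).
#' @export
encodeNodes <- function(graph, X, model) {
  stack <- if (is(graph, "HeterogeneousGraph")) adjacencyStack(graph)
           else graph
  cfg <- model@config
  if (length(stack) != cfg$nEdgeTypes)
    stop("adjacency stack depth does not match the model", call. = FALSE)
  if (nrow(X) != nrow(stack[[1]]) || ncol(X) != cfg$inDim)
    stop("feature matrix does not match graph/model dimensions",
         call. = FALSE)
  out <- vector("list", cfg$channels)
  for (ch in seq_len(cfg$channels)) {
    L <- model@selectionLogits[[ch]]
    Q <- selectEdgeType(stack, L[1, ])
    for (s in seq_len(cfg$slots)[-1])
      Q <- composeMetapath(Q, selectEdgeType(stack, L[s, ]))
    H <- X
    for (W in model@gcnWeights) H <- gcnLayer(H, Q, W)
    out[[ch]] <- H
  }
  Z <- do.call(cbind, out)
  rownames(Z) <- rownames(X)
  Z
}

#' Score disease-gene pairs from node embeddings
#'
#' Link-prediction head: each pair is represented by the disease embedding,
#' the gene embedding and their elementwise product (the product block lets
#' the head express embedding similarity directly), passed through a
#' one-hidden-layer MLP with a logistic output, so scores lie strictly
#' inside (0, 1).
#'
#' @param Z node embedding matrix with node ids as rownames.
#' @param pairs data.frame with columns `disease`, `gene` (ids present in
#'   `Z`'s rownames).
#' @param head list with elements `V`, `c0`, `w`, `b` (as in
#'   [gtnModel()]'s head).
#' @return numeric vector of scores in (0, 1), one per pair row.
#' @export
scorePairs <- function(Z, pairs, head) {
  i <- match(pairs$disease, rownames(Z))
  j <- match(pairs$gene, rownames(Z))
  if (anyNA(i) || anyNA(j))
    stop("pair references node ids absent from the embedding",
         call. = FALSE)
  Zi <- Z[i, , drop = FALSE]
  Zj <- Z[j, , drop = FALSE]
  U <- cbind(Zi, Zj, Zi * Zj)
  Hh <- .relu(sweep(U %*% head$V, 2, head$c0, "+"))
  drop(.sigmoid(Hh %*% head$w + head$b))
}
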