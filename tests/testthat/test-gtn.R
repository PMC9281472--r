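test_that("edge-type selection is an exact convex combination", {
  st <- randomStack(6, nTypes = 3, seed = 2)
  ## saturated softmax picks out the first matrix
  Q <- selectEdgeType(st, c(40, -40, -40))
  expect_lt(max(abs(Q - st[[1]])), 1e-6)
  ## uniform logits average the stack
  Qu <- selectEdgeType(st, c(1, 1, 1))
  expect_lt(max(abs(Qu - Reduce(`+`, st) / 3)), 1e-12)
  ## brute-force oracle with an explicit loop
  withr::with_seed(4, logits <- rnorm(3))
  a <- exp(logits - max(logits)); a <- a / sum(a)
  ref <- matrix(0, 6, 6)
  for (t in 1:3) for (i in 1:6) for (j in 1:6)
    ref[i, j] <- ref[i, j] + a[t] * st[[t]][i, j]
  expect_lt(max(abs(selectEdgeType(st, logits) - ref)), 1e-12)
  expect_error(selectEdgeType(st, c(1, 2)), "logits")
})

test_that("meta-path composition multiplies then degree-normalizes", {
  ## identity second factor: normalized first factor comes back
  withr::with_seed(1, Q1 <- matrix(runif(16), 4, 4))
  A1 <- composeMetapath(Q1, diag(4))
  expect_equal(A1, Q1 / rowSums(Q1), tolerance = 1e-12)
  ## directed path a -> b -> c composed with itself: only (a, c) survives
  P <- matrix(0, 3, 3); P[1, 2] <- 1; P[2, 3] <- 1
  raw <- composeMetapath(P, P, normalize = FALSE)
  expect_identical(which(raw != 0), 7L)   # column-major index of (1, 3)
  expect_identical(raw[1, 3], 1)
  expect_error(composeMetapath(P, matrix(0, 2, 2)), "square")
})

test_that("cross-type composition lands in the disease x gene quadrant", {
  b <- tinyBundle(seed = 6)
  onto <- diseaseOntology(b@ontologyEdges)
  dIds <- sort(rownames(b@truthLabels)); gIds <- sort(colnames(b@truthLabels))
  g <- assembleHeterogeneousGraph(buildDiseaseNetwork(onto, dIds),
                                  b@geneEdges, b@assocEdges, geneIds = gIds)
  st <- adjacencyStack(g)
  M <- composeMetapath(st$disease_gene, st$gene_gene, normalize = FALSE)
  nd <- length(dIds); n <- nd + length(gIds)
  mask <- matrix(0, n, n); mask[seq_len(nd), (nd + 1):n] <- 1
  expect_identical(sum(M * (1 - mask)), 0)  # quadrant-mask oracle
  expect_gt(sum(M), 0)
})

test_that("the GCN layer reproduces hand-computed propagation", {
  ## no edges, identity weights: self-loop-only propagation is identity
  H <- matrix(c(2, 1, 3, 4), 2, 2)
  expect_equal(gcnLayer(H, matrix(0, 2, 2), diag(2)), H)
  ## 2-node single edge, identity features/weights:
  ## A+I = [[1,1],[1,1]], D = 2I, propagator = [[.5,.5],[.5,.5]]
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(gcnLayer(diag(2), A, diag(2)),
               matrix(0.5, 2, 2))
  expect_error(gcnLayer(diag(2), -A, diag(2)), "non-negative")
})

test_that("the normalized propagator has spectral norm at most one", {
  for (s in 1:10) {
    n <- sample(4:12, 1)
    A <- randomStack(n, 2, seed = s)[[1]]
    P <- hetGTN:::.gcnPropagator(A)
    expect_lte(max(svd(P)$d), 1 + 1e-10)
  }
})

test_that("encodeNodes honors its degenerate and concatenation contracts", {
  n <- 5; d <- 3
  zeroStack <- list(matrix(0, n, n), diag(n))
  withr::with_seed(2, X <- matrix(rnorm(n * d), n, d))
  m <- gtnModel(2, d, channels = 1, slots = 2, gcnWidth = d,
                gcnLayers = 1, seed = 1)
  m@gcnWeights[[1]] <- diag(d)
  ## all-zero adjacency: P = I regardless of selections, so Z = relu(X)
  Z <- encodeNodes(zeroStack, X, m)
  expect_equal(Z, pmax(X, 0), tolerance = 1e-12, ignore_attr = TRUE)
  ## channel concatenation contract: 2 channels of width k give 2k columns
  m2 <- gtnModel(2, d, channels = 2, slots = 2, gcnWidth = 4,
                 gcnLayers = 2, seed = 1)
  expect_identical(ncol(encodeNodes(zeroStack, X, m2)), 8L)
})

test_that("the full forward pass matches a straight-line scripted oracle", {
  n <- 8; d <- 4
  st <- randomStack(n, nTypes = 3, seed = 3)
  withr::with_seed(5, X <- matrix(runif(n * d), n, d))
  m <- gtnModel(3, d, channels = 2, slots = 2, gcnWidth = 3,
                gcnLayers = 2, seed = 9)
  ## oracle: explicit softmax -> weighted sums -> product -> normalize ->
  ## self-loops -> symmetric normalization -> two matmuls with relu
  oracle <- function() {
    out <- NULL
    for (ch in 1:2) {
      L <- m@selectionLogits[[ch]]
      mix <- function(lg) {
        a <- exp(lg - max(lg)); a <- a / sum(a)
        a[1] * st[[1]] + a[2] * st[[2]] + a[3] * st[[3]]
      }
      M <- mix(L[1, ]) %*% mix(L[2, ])
      M <- M / pmax(rowSums(M), 1e-12)
      At <- M + diag(n)
      s <- 1 / sqrt(rowSums(At))
      P <- diag(s) %*% At %*% diag(s)
      H <- pmax(P %*% X %*% m@gcnWeights[[1]], 0)
      H <- pmax(P %*% H %*% m@gcnWeights[[2]], 0)
      out <- cbind(out, H)
    }
    out
  }
  expect_lt(max(abs(encodeNodes(st, X, m) - oracle())), 1e-10)
})

test_that("node relabeling permutes the embedding rows", {
  n <- 7; d <- 3
  st <- randomStack(n, nTypes = 3, seed = 6)
  withr::with_seed(6, X <- matrix(runif(n * d), n, d))
  m <- gtnModel(3, d, channels = 2, slots = 2, gcnWidth = 4,
                gcnLayers = 2, seed = 2)
  perm <- withr::with_seed(8, sample(n))
  stP <- lapply(st, function(A) A[perm, perm])
  Z <- encodeNodes(st, X, m)
  ZP <- encodeNodes(stP, X[perm, , drop = FALSE], m)
  expect_equal(ZP, Z[perm, , drop = FALSE], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("backprop matches finite differences on a toy instance", {
  n <- 8; d <- 4
  st <- randomStack(n, nTypes = 3, seed = 12)
  withr::with_seed(13, {
    X <- matrix(runif(n * d), n, d)
    m <- gtnModel(3, d, channels = 2, slots = 2, gcnWidth = 3,
                  gcnLayers = 2, headHidden = 5, seed = 7)
    par <- list(sel = lapply(m@selectionLogits,
                             function(L) L + matrix(rnorm(length(L)),
                                                    nrow(L))),
                gcn = m@gcnWeights, head = m@headParams)
  })
  pi <- 1:4; pj <- 5:8; y <- c(1, 0, 1, 0)
  lg <- hetGTN:::.gtnLossGrad(par, st, X, pi, pj, y)
  eps <- 1e-4
  fdCheck <- function(get, set, analytic) {
    p0 <- get(par)
    fd <- p0 * 0
    for (i in seq_along(p0)) {
      pp <- set(par, `[<-`(p0, i, p0[i] + eps))
      pm <- set(par, `[<-`(p0, i, p0[i] - eps))
      fd[i] <- (hetGTN:::.gtnLossGrad(pp, st, X, pi, pj, y)$loss -
                hetGTN:::.gtnLossGrad(pm, st, X, pi, pj, y)$loss) /
               (2 * eps)
    }
    expect_lt(max(abs(fd - analytic)) / max(abs(fd), 1e-8), 1e-4)
  }
  fdCheck(function(p) p$sel[[1]],
          function(p, v) { p$sel[[1]] <- v; p }, lg$grad$sel[[1]])
  fdCheck(function(p) p$sel[[2]],
          function(p, v) { p$sel[[2]] <- v; p }, lg$grad$sel[[2]])
  fdCheck(function(p) p$gcn[[1]],
          function(p, v) { p$gcn[[1]] <- v; p }, lg$grad$gcn[[1]])
  fdCheck(function(p) p$head$w,
          function(p, v) { p$head$w <- v; p }, lg$grad$head$w)
})

test_that("softmax selection weights always sum to one", {
  for (s in 1:20) {
    withr::with_seed(s, lg <- rnorm(5, sd = s / 3))
    expect_lt(abs(sum(hetGTN:::.softmax(lg)) - 1), 1e-12)
  }
})
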