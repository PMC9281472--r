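test_that("energy matches hand cases and a triple-loop oracle", {
  ## all-zero configuration has zero energy
  rbm0 <- new("RBM", W = matrix(0, 2, 1), visibleBias = c(0.5, -1),
              hiddenBias = 2)
  expect_identical(rbmEnergy(rbm0, c(0, 0), 0), 0)
  ## W = 0, v = (1,1), a = (0.5,-1), h = 1, b = 2: E = 0.5 - 2 = -1.5
  expect_equal(rbmEnergy(rbm0, c(1, 1), 1), -1.5)

  ## elementwise-loop oracle on random instances
  loopEnergy <- function(rbm, v, h) {
    e <- 0
    for (i in seq_along(v)) e <- e - rbm@visibleBias[i] * v[i]
    for (j in seq_along(h)) e <- e - rbm@hiddenBias[j] * h[j]
    for (i in seq_along(v)) for (j in seq_along(h))
      e <- e - v[i] * rbm@W[i, j] * h[j]
    e
  }
  withr::with_seed(5, {
    for (rep in 1:5) {
      rbm <- randomRBM(5, 4, seed = rep)
      v <- rbinom(5, 1, 0.5); h <- rbinom(4, 1, 0.5)
      expect_equal(rbmEnergy(rbm, v, h), loopEnergy(rbm, v, h),
                   tolerance = 1e-12)
    }
  })
  expect_error(rbmEnergy(rbm0, c(1, 1, 1), 1), "length")
  expect_error(rbmEnergy(rbm0, c(1, 2), 1), "binary")
})

test_that("joint table normalizes, is uniform at zero params, sized-guarded", {
  rbmU <- new("RBM", W = matrix(0, 3, 2), visibleBias = numeric(3),
              hiddenBias = numeric(2))
  jt <- rbmJointTable(rbmU)
  expect_equal(sum(jt$prob), 1, tolerance = 1e-10)
  expect_equal(max(abs(jt$prob - 1 / 32)), 0, tolerance = 1e-12)

  rbm <- randomRBM(4, 3, seed = 2)
  jt <- rbmJointTable(rbm)
  expect_equal(sum(jt$prob), 1, tolerance = 1e-10)
  expect_true(all(jt$prob > 0))
  ## p proportional to exp(-E)
  expect_equal(max(abs(log(jt$prob) + jt$energy - (-jt$logZ))), 0,
               tolerance = 1e-10)

  big <- new("RBM", W = matrix(0, 10, 8), visibleBias = numeric(10),
             hiddenBias = numeric(8))
  expect_error(rbmJointTable(big), "enumeration")
})

test_that("marginal p(v) from enumeration matches the closed form", {
  rbm <- randomRBM(4, 3, seed = 7)
  jt <- rbmJointTable(rbm)
  pv <- rowSums(jt$prob)
  ## closed form: p(v) = exp(a.v) prod_j (1 + exp(b_j + v.W_j)) / Z
  closed <- apply(jt$vConfigs, 1, function(v) {
    exp(sum(rbm@visibleBias * v)) *
      prod(1 + exp(rbm@hiddenBias + drop(v %*% rbm@W)))
  })
  closed <- closed / exp(jt$logZ)
  expect_equal(pv, closed, tolerance = 1e-10)
})

test_that("factorized conditionals agree with Bayes rule on the joint", {
  rbm <- randomRBM(4, 3, seed = 9)
  jt <- rbmJointTable(rbm)
  for (vi in c(1, 7, 16)) {
    v <- jt$vConfigs[vi, ]
    pHgivenV <- jt$prob[vi, ] / sum(jt$prob[vi, ])
    ## P(h_j = 1 | v) from the enumeration
    marg <- drop(pHgivenV %*% jt$hConfigs)
    expect_equal(unname(conditionalHidden(rbm, v)), unname(marg),
                 tolerance = 1e-10)
  }
  for (hi in c(2, 5)) {
    h <- jt$hConfigs[hi, ]
    pVgivenH <- jt$prob[, hi] / sum(jt$prob[, hi])
    marg <- drop(pVgivenH %*% jt$vConfigs)
    expect_equal(unname(conditionalVisible(rbm, h)), unname(marg),
                 tolerance = 1e-10)
  }
})

test_that("conditionals reduce to plain logistics at zero coupling", {
  rbm <- new("RBM", W = matrix(0, 3, 2), visibleBias = c(1, -1, 0),
             hiddenBias = c(0.3, 0))
  expect_equal(unname(conditionalHidden(rbm, c(1, 1, 1))),
               plogis(c(0.3, 0)))
  ## b = 0 and a zero weight column: probability exactly 0.5
  expect_identical(unname(conditionalHidden(rbm, c(0, 1, 0)))[2], 0.5)
  expect_error(conditionalHidden(rbm, c(1, 1)), "shape")
})

test_that("CD-1 training is seeded, collapses on empty data, and learns", {
  withr::with_seed(1, {
    zeros <- matrix(0L, 40, 12)
    rbm <- trainRBM(zeros, 6, epochs = 50, seed = 4)
    recon <- conditionalVisible(rbm, conditionalHidden(rbm, zeros))
    expect_lt(mean(recon), 0.2)
  })
  d <- matrix(rbinom(200, 1, 0.5), 20, 10)
  expect_identical(trainRBM(d, 4, epochs = 5, seed = 2)@W,
                   trainRBM(d, 4, epochs = 5, seed = 2)@W)
  expect_error(trainRBM(d * 0.5, 4), "binary")

  ## two-prototype data: reconstruction cross-entropy must drop from its
  ## value at (near-zero) initialization, averaged over seeds
  proto <- rbind(c(rep(1, 6), rep(0, 6)), c(rep(0, 6), rep(1, 6)))
  ce <- function(rbm, X) {
    R <- conditionalVisible(rbm, conditionalHidden(rbm, X))
    -mean(X * log(R) + (1 - X) * log(1 - R))
  }
  gain <- vapply(1:3, function(s) {
    X <- withr::with_seed(s, {
      idx <- sample(1:2, 200, replace = TRUE)
      flips <- matrix(runif(200 * 12) < 0.05, 200)
      abs(proto[idx, ] - flips * 1)
    })
    init <- withr::with_seed(s, new("RBM",
      W = matrix(rnorm(12 * 8, sd = 0.01), 12, 8),
      visibleBias = numeric(12), hiddenBias = numeric(8)))
    trained <- trainRBM(X, 8, epochs = 50, seed = s)
    ce(init, X) - ce(trained, X)
  }, 0)
  expect_gt(mean(gain), 0)
})

test_that("the DBN stack is chain-compatible and encodes deterministically", {
  withr::with_seed(3, {
    X <- matrix(rbinom(50 * 20, 1, 0.3), 50, 20)
    rownames(X) <- sprintf("n%02d", 1:50)
  })
  dbn <- trainDBN(X, layerSizes = c(30, 12, 6), epochs = 5, seed = 1)
  ## layer 1 clipped to the 20-dim input
  expect_identical(dbn@hyperparams$layerSizes, c(20L, 12L, 6L))
  expect_true(validObject(dbn))
  Z <- encodeFeatures(dbn, X)
  expect_identical(dim(Z), c(50L, 6L))
  expect_true(all(Z > 0 & Z < 1))
  ## identical rows encode identically
  X2 <- X; X2[2, ] <- X2[1, ]
  Z2 <- encodeFeatures(dbn, X2)
  expect_equal(unname(Z2[1, ]), unname(Z2[2, ]))
  ## nearby inputs encode closer than distant ones
  Xa <- X[1, , drop = FALSE]
  Xb <- Xa; Xb[, 1:10] <- 1 - Xb[, 1:10]
  za <- encodeFeatures(dbn, Xa); zb <- encodeFeatures(dbn, Xb)
  expect_gt(sqrt(sum((za - zb)^2)), 0)
  expect_error(encodeFeatures(dbn, X[, 1:10]), "visible size")
  untrained <- new("DBN", layers = dbn@layers, trained = rep(FALSE, 3),
                   hyperparams = list())
  expect_error(encodeFeatures(untrained, X), "not trained")
})

test_that("DBN checkpoints round-trip exactly", {
  withr::with_seed(8, X <- matrix(rbinom(30 * 10, 1, 0.4), 30, 10))
  dbn <- trainDBN(X, layerSizes = c(8, 6, 4), epochs = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  writeDBN(dbn, path)
  back <- readDBN(path)
  for (k in 1:3) {
    expect_identical(back@layers[[k]]@W, dbn@layers[[k]]@W)
    expect_identical(back@layers[[k]]@visibleBias,
                     dbn@layers[[k]]@visibleBias)
    expect_identical(back@layers[[k]]@hiddenBias,
                     dbn@layers[[k]]@hiddenBias)
  }
  expect_identical(encodeFeatures(back, X), encodeFeatures(dbn, X))
})
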