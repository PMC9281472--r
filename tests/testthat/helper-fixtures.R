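## shared fixture builders; everything is generated in code at test time

tinyConfig <- function(seed = 3L, ...) {
  args <- list(nDiseases = 8L, nGenes = 30L, nMirnas = 40L, nAssoc = 20L,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthConfig, args)
}

tinyBundle <- function(seed = 3L, ...) simulateBundle(tinyConfig(seed, ...))

## the 5-term ontology used for the hand-computed Lin similarity:
## root -> {x, y}, x -> {d1, d2}
fiveTermOntology <- function() {
  diseaseOntology(data.frame(child = c("x", "y", "d1", "d2"),
                             parent = c("root", "root", "x", "x")))
}

randomRBM <- function(m, n, seed = 1L, sd = 1) {
  withr::with_seed(seed, {
    new("RBM", W = matrix(rnorm(m * n, sd = sd), m, n),
        visibleBias = rnorm(m, sd = sd), hiddenBias = rnorm(n, sd = sd))
  })
}

## random small adjacency stack of symmetric binary matrices plus identity
randomStack <- function(n, nTypes = 3L, seed = 1L) {
  withr::with_seed(seed, {
    stack <- lapply(seq_len(nTypes - 1L), function(t) {
      A <- (matrix(runif(n * n), n, n) < 0.4) * 1
      ((A + t(A)) > 0) * 1
    })
    c(stack, list(diag(n)))
  })
}

expect_identical_matrix <- function(a, b, tol = 0) {
  if (tol == 0) expect_identical(unname(a), unname(b))
  else expect_lt(max(abs(a - b)), tol)
}
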