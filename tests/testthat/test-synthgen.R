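test_that("config invariants are enforced", {
  expect_error(synthConfig(pSignal = 0.2, pNoise = 0.5), "pNoise")
  expect_error(synthConfig(nDiseases = 0), "positive")
  expect_error(synthConfig(nDiseases = 3, nGenes = 4, nAssoc = 13),
               "nAssoc")
  expect_s4_class(tinyConfig(), "SynthConfig")
})

test_that("ontology generation gives a rooted DAG, deterministically", {
  cfg2 <- synthConfig(nDiseases = 2, nGenes = 10, nMirnas = 10, nAssoc = 5)
  e <- generateOntology(cfg2)
  expect_identical(nrow(e), 1L)           # minimal rooted tree

  cfg <- synthConfig(nDiseases = 50, nGenes = 10, nMirnas = 10,
                     nAssoc = 5, ontologyBranching = 3, seed = 7)
  e1 <- generateOntology(cfg)
  e2 <- generateOntology(cfg)
  expect_identical(e1, e2)

  ## topological-sort oracle: child -> parent edges must form a DAG with
  ## a single zero-out-degree node (the root)
  g <- igraph::graph_from_data_frame(e1)
  expect_true(igraph::is_dag(g))
  outDeg <- igraph::degree(g, mode = "out")
  expect_identical(sum(outDeg == 0), 1L)
  expect_true(all(sort(unique(c(e1$child, e1$parent))) ==
                  sprintf("D%04d", 1:50)))
  ## every non-root node has at least one parent
  root <- names(outDeg)[outDeg == 0]
  expect_true(all(setdiff(sprintf("D%04d", 1:50), root) %in% e1$child))
})

test_that("gene network is connected, simple, with the attachment edge count", {
  cfg <- synthConfig(nDiseases = 5, nGenes = 3, nMirnas = 10, nAssoc = 5,
                     geneNetAttach = 1)
  e <- generateGeneNetwork(cfg)
  expect_identical(nrow(e), 2L)           # tree on 3 nodes

  cfg <- synthConfig(nDiseases = 5, nGenes = 300, nMirnas = 10,
                     nAssoc = 5, geneNetAttach = 2, seed = 11)
  e1 <- generateGeneNetwork(cfg)
  expect_identical(e1, generateGeneNetwork(cfg))
  ## each added node beyond the first two contributes exactly `attach`
  ## edges; node 2 can only attach one
  expect_identical(nrow(e1), 1L + 2L * (300L - 2L))
  expect_true(all(e1$gene1 != e1$gene2))
  expect_false(anyDuplicated(paste(e1$gene1, e1$gene2)) > 0)
  g <- igraph::graph_from_data_frame(e1, directed = FALSE)
  expect_true(igraph::is_connected(g))
  ## preferential attachment yields a heavy right tail
  deg <- igraph::degree(g)
  expect_gt(max(deg), 6 * mean(deg))
})

test_that("noiseless planted signal makes gene rows supersets of profiles", {
  b <- tinyBundle(pSignal = 1, pNoise = 0)
  gm <- featureValues(b@mirnaGene)
  dm <- featureValues(b@mirnaDisease)
  for (r in seq_len(nrow(b@assocEdges))) {
    d <- b@assocEdges$disease[r]; g <- b@assocEdges$gene[r]
    expect_true(all(gm[g, dm[d, ] == 1] == 1),
                label = sprintf("gene %s covers profile of %s", g, d))
  }
})

test_that("background rate of non-associated gene cells matches pNoise", {
  b <- tinyBundle(seed = 9, nGenes = 100L, nMirnas = 150L, pNoise = 0.05)
  gm <- featureValues(b@mirnaGene)
  free <- setdiff(rownames(gm), unique(b@assocEdges$gene))
  cells <- gm[free, , drop = FALSE]
  expect_gt(length(cells), 1e4)
  se <- sqrt(0.05 * 0.95 / length(cells))
  expect_lt(abs(mean(cells) - 0.05), 3 * se)
})

test_that("bundles are reproducible and signal grows with pSignal", {
  expect_identical(tinyBundle(seed = 5)@mirnaGene@values,
                   tinyBundle(seed = 5)@mirnaGene@values)
  jac <- vapply(c(0.1, 0.5, 0.9), function(ps) {
    b <- tinyBundle(seed = 21, pSignal = ps, pNoise = 0.05)
    gm <- featureValues(b@mirnaGene); dm <- featureValues(b@mirnaDisease)
    mean(vapply(seq_len(nrow(b@assocEdges)), function(r) {
      u <- gm[b@assocEdges$gene[r], ]; v <- dm[b@assocEdges$disease[r], ]
      sum(u & v) / sum(u | v)
    }, 0))
  }, 0)
  expect_true(all(diff(jac) > 0))
})

test_that("truth labels agree exactly with the planted association list", {
  b <- tinyBundle(seed = 13)
  expect_identical(sum(b@truthLabels), nrow(b@assocEdges))
  expect_true(all(b@truthLabels[cbind(b@assocEdges$disease,
                                      b@assocEdges$gene)] == 1))
  expect_true(validObject(b))
})
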