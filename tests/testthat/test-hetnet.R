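test_that("information content follows the descendant-count definition", {
  ## root with 3 leaf children: leaves cover 1 of 4 terms
  onto <- diseaseOntology(data.frame(child = c("a", "b", "c"),
                                     parent = "root"))
  ic <- informationContent(onto)
  expect_equal(unname(ic["root"]), 0)
  expect_equal(unname(ic[c("a", "b", "c")]), rep(-log(1 / 4), 3))

  ## chain a -> b -> c: IC non-decreasing towards the leaf
  chain <- diseaseOntology(data.frame(child = c("b", "c"),
                                      parent = c("a", "b")))
  icc <- informationContent(chain)
  expect_equal(unname(icc["a"]), 0)
  expect_true(icc["a"] <= icc["b"] && icc["b"] <= icc["c"])
})

test_that("ontology validity rejects cycles and multiple roots", {
  expect_error(diseaseOntology(data.frame(child = c("a", "b"),
                                          parent = c("b", "a"))),
               "root|cycle")
  expect_error(diseaseOntology(data.frame(child = c("a", "b"),
                                          parent = c("r1", "r2"))),
               "root")
})

test_that("Lin similarity reproduces the 5-term hand computation", {
  onto <- fiveTermOntology()
  s <- diseaseSimilarity("d1", "d2", onto)
  expect_equal(s, log(5 / 3) / log(5), tolerance = 1e-12)
  ## identity and root-only-ancestor cases
  expect_identical(diseaseSimilarity("d1", "d1", onto), 1)
  expect_identical(diseaseSimilarity("d1", "y", onto), 0)
  expect_error(diseaseSimilarity("d1", "zz", onto), "unknown")
})

test_that("similarity is symmetric and bounded on random ontologies", {
  for (i in 1:40) {
    cfg <- synthConfig(nDiseases = sample(4:12, 1), nGenes = 5,
                       nMirnas = 5, nAssoc = 3, seed = i)
    onto <- diseaseOntology(generateOntology(cfg))
    ts <- ontologyTerms(onto)
    pick <- sample(ts, 2)
    s12 <- diseaseSimilarity(pick[1], pick[2], onto)
    s21 <- diseaseSimilarity(pick[2], pick[1], onto)
    expect_equal(s12, s21, tolerance = 1e-12)
    expect_gte(s12, 0); expect_lte(s12, 1)
  }
})

test_that("annotation mode scores Jaccard overlap", {
  onto <- diseaseOntology(
    data.frame(child = c("d1", "d2"), parent = "root"),
    annotations = list(d1 = c("g1", "g2", "g3"), d2 = c("g2", "g3", "g4")))
  expect_equal(diseaseSimilarity("d1", "d2", onto, method = "annotation"),
               2 / 4)
})

test_that("disease network thresholding matches the similarity values", {
  onto <- fiveTermOntology()
  leaves <- c("d1", "d2", "y")
  ## tau just below the known d1-d2 similarity keeps exactly that edge
  A <- buildDiseaseNetwork(onto, leaves, tau = 0.3)
  expect_identical(sum(A), 2)                 # one undirected edge
  expect_identical(A["d1", "d2"], 1)
  expect_identical(unname(diag(A)), rep(0, 3))
  ## impossible threshold empties the network
  expect_identical(sum(buildDiseaseNetwork(onto, leaves, tau = 1.01)), 0)
  ## tau = 0 links any pair sharing a non-root ancestor
  A0 <- buildDiseaseNetwork(onto, leaves, tau = 0)
  expect_identical(A0["d1", "y"], 1)
})

test_that("heterogeneous graph assembly respects block structure", {
  b <- tinyBundle(seed = 4)
  onto <- diseaseOntology(b@ontologyEdges)
  dIds <- sort(rownames(b@truthLabels))
  gIds <- sort(colnames(b@truthLabels))
  dAdj <- buildDiseaseNetwork(onto, dIds)
  g <- assembleHeterogeneousGraph(dAdj, b@geneEdges, b@assocEdges,
                                  geneIds = gIds)
  expect_identical(edgeTypes(g),
                   c("disease_disease", "gene_gene", "disease_gene",
                     "gene_disease", "identity"))
  st <- adjacencyStack(g)
  nd <- length(dIds); n <- nd + length(gIds)
  dQ <- seq_len(nd); gQ <- (nd + 1):n
  ## quadrant-mask oracle: mass only in designated blocks
  expect_identical(sum(st$disease_disease[gQ, ]) +
                   sum(st$disease_disease[, gQ]), 0)
  expect_identical(sum(st$gene_gene[dQ, ]) + sum(st$gene_gene[, dQ]), 0)
  expect_identical(sum(st$disease_gene) -
                   sum(st$disease_gene[dQ, gQ]), 0)
  expect_identical_matrix(st$disease_gene, t(st$gene_disease))
  expect_identical_matrix(st$identity, diag(n))
  expect_equal(sum(st$disease_gene), nrow(b@assocEdges))
})

test_that("assembly fails loudly on unknown ids and handles empty links", {
  dAdj <- matrix(0, 1, 1, dimnames = list("d1", "d1"))
  geneEdges <- data.frame(gene1 = "g1", gene2 = "g2")
  expect_error(
    assembleHeterogeneousGraph(dAdj, geneEdges,
                               data.frame(disease = "dX", gene = "g1")),
    "unknown ids")
  g <- assembleHeterogeneousGraph(dAdj, geneEdges,
                                  data.frame(disease = character(),
                                             gene = character()))
  expect_identical(sum(adjacencyStack(g)$disease_gene), 0)
  ## 1 disease + 1 gene + 1 association: 2x2 matrices, cross transposes
  g2 <- assembleHeterogeneousGraph(dAdj,
                                   data.frame(gene1 = character(),
                                              gene2 = character()),
                                   data.frame(disease = "d1", gene = "g1"),
                                   geneIds = "g1")
  st <- adjacencyStack(g2)
  expect_identical(dim(st$disease_gene), c(2L, 2L))
  expect_identical_matrix(st$disease_gene, t(st$gene_disease))
})
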