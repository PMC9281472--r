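test_that("indicator cells are set exactly where pairs are attested", {
  fm <- buildFeatureMatrices(
    data.frame(mirna = c("m1", "m2"), gene = "g1"),
    data.frame(mirna = "m3", disease = "d1"),
    geneIds = c("g1", "g2"), diseaseIds = "d1")
  expect_identical(colIds(fm$gene), c("m1", "m2", "m3"))
  expect_identical(colIds(fm$gene), colIds(fm$disease))
  expect_identical(unname(featureValues(fm$gene)["g1", ]), c(1L, 1L, 0L))
  expect_identical(unname(featureValues(fm$gene)["g2", ]), c(0L, 0L, 0L))
  expect_identical(unname(featureValues(fm$disease)["d1", ]),
                   c(0L, 0L, 1L))
})

test_that("duplicates are idempotent and row order is irrelevant", {
  gp <- data.frame(mirna = c("m2", "m1", "m1", "m2"),
                   gene = c("g2", "g1", "g1", "g2"))
  dp <- data.frame(mirna = c("m1", "m1"), disease = c("d1", "d1"))
  ids <- list(geneIds = c("g1", "g2"), diseaseIds = "d1")
  a <- do.call(buildFeatureMatrices, c(list(gp, dp), ids))
  b <- do.call(buildFeatureMatrices,
               c(list(gp[c(3, 1, 2, 4), ], dp[2, , drop = FALSE]), ids))
  expect_identical(featureValues(a$gene), featureValues(b$gene))
  expect_identical(featureValues(a$disease), featureValues(b$disease))
  ## row sums equal de-duplicated per-node pair counts
  expect_identical(unname(rowSums(featureValues(a$gene))), c(1, 1))
})

test_that("empty pair lists give zero-column matrices that stay usable", {
  fm <- suppressMessages(buildFeatureMatrices(
    data.frame(mirna = character(), gene = character()),
    data.frame(mirna = character(), disease = character()),
    geneIds = c("g1", "g2"), diseaseIds = "d1"))
  expect_identical(dim(fm$gene), c(2L, 0L))
  expect_identical(dim(fm$disease), c(1L, 0L))
})

test_that("unknown node ids are rejected and zero rows reported", {
  expect_error(buildFeatureMatrices(
    data.frame(mirna = "m1", gene = "gX"),
    data.frame(mirna = "m1", disease = "d1"),
    geneIds = "g1", diseaseIds = "d1"), "unknown nodes")
  expect_message(buildFeatureMatrices(
    data.frame(mirna = "m1", gene = "g1"),
    data.frame(mirna = "m1", disease = "d1"),
    geneIds = c("g1", "g2"), diseaseIds = "d1"), "all-zero")
})
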