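#' Build aligned binary miRNA feature matrices for genes and diseases
#'
#' Every miRNA seen in either pair list becomes one feature dimension; a
#' cell is 1 exactly when the (miRNA, node) pair is attested. The two
#' matrices share one sorted miRNA column universe, so gene and disease
#' features live in the same visible space — a prerequisite for reducing
#' both through one deep belief network. Nodes with no attested miRNA keep
#' an all-zero row (dropping them would desynchronize the feature matrices
#' from the graph); they are reported via a message. Duplicate input pairs
#' are idempotent and input row order is irrelevant.
#'
#' @param mirnaGenePairs data.frame with columns `mirna`, `gene`.
#' @param mirnaDiseasePairs data.frame with columns `mirna`, `disease`.
#' @param geneIds,diseaseIds the node universes (rows of the outputs, kept
#'   in the given order after de-duplication).
#' @return list with elements `gene` and `disease`, both [FeatureMatrix]
#'   objects with identical `colIds`.
#' @examples
#' fm <- buildFeatureMatrices(
#'   data.frame(mirna = c("m1", "m2"), gene = "g1"),
#'   data.frame(mirna = "m1", disease = "d1"),
#'   geneIds = c("g1", "g2"), diseaseIds = "d1")
#' featureValues(fm$gene)
#' @export
buildFeatureMatrices <- function(mirnaGenePairs, mirnaDiseasePairs,
                                 geneIds, diseaseIds) {
  stopifnot(all(c("mirna", "gene") %in% names(mirnaGenePairs)),
            all(c("mirna", "disease") %in% names(mirnaDiseasePairs)))
  geneIds <- unique(geneIds); diseaseIds <- unique(diseaseIds)
  badG <- setdiff(mirnaGenePairs$gene, geneIds)
  badD <- setdiff(mirnaDiseasePairs$disease, diseaseIds)
  if (length(badG) || length(badD))
    stop("pair lists reference unknown nodes: ",
         paste(c(badG, badD), collapse = ", "), call. = FALSE)

  mirnas <- sort(unique(c(mirnaGenePairs$mirna, mirnaDiseasePairs$mirna)))
  fill <- function(pairs, nodeCol, nodeIds) {
    m <- matrix(0L, length(nodeIds), length(mirnas),
                dimnames = list(nodeIds, mirnas))
    if (nrow(pairs) && length(mirnas))
      m[cbind(match(pairs[[nodeCol]], nodeIds),
              match(pairs$mirna, mirnas))] <- 1L
    m
  }
  gm <- fill(mirnaGenePairs, "gene", geneIds)
  dm <- fill(mirnaDiseasePairs, "disease", diseaseIds)
  nZero <- sum(rowSums(gm) == 0) + sum(rowSums(dm) == 0)
  if (nZero > 0)
    message(nZero, " node(s) have no attested miRNA; all-zero rows kept")
  list(gene = new("FeatureMatrix", values = gm),
       disease = new("FeatureMatrix", values = dm))
}
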