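#' Construct a disease ontology from a parent edge list
#'
#' @param edges data.frame with columns `child`, `parent`; terms are the
#'   union of both columns. The relation must be acyclic with a single root.
#' @param annotations optional named list mapping term ids to character
#'   vectors of annotation-entity ids (used by the annotation-overlap
#'   similarity mode).
#' @return a [DiseaseOntology].
#' @examples
#' onto <- diseaseOntology(data.frame(child = c("d1", "d2"),
#'                                    parent = c("root", "root")))
#' @export
diseaseOntology <- function(edges, annotations = NULL) {
  stopifnot(all(c("child", "parent") %in% names(edges)))
  terms <- sort(unique(c(edges$child, edges$parent)))
  pm <- split(edges$parent, factor(edges$child, levels = terms))
  pm <- lapply(pm, function(p) sort(unique(as.character(p))))
  names(pm) <- terms
  new("DiseaseOntology", terms = terms, parentMap = pm,
      annotationMap = if (is.null(annotations)) list() else annotations)
}

## children map derived from the parent map
.childMap <- function(onto) {
  cm <- stats::setNames(vector("list", length(onto@terms)), onto@terms)
  for (t in onto@terms)
    for (p in onto@parentMap[[t]]) cm[[p]] <- c(cm[[p]], t)
  cm
}

## ancestors of each term, including the term itself (memoized recursion)
.ancestorSets <- function(onto) {
  anc <- new.env(parent = emptyenv())
  get1 <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    res <- t
    for (p in onto@parentMap[[t]]) res <- union(res, get1(p))
    anc[[t]] <- res
    res
  }
  stats::setNames(lapply(onto@terms, get1), onto@terms)
}

#' Information content of every ontology term
#'
#' The information content of a term is the negative log of the fraction of
#' terms at or below it: `IC(t) = -log(|descendants(t) + t| / |terms|)`.
#' The root covers everything, so `IC(root) = 0`, and IC is non-decreasing
#' from root to leaves along parent links: rarer, more specific diseases
#' carry more information.
#'
#' @param onto a [DiseaseOntology].
#' @return a named numeric vector of IC values over all terms.
#' @examples
#' onto <- diseaseOntology(data.frame(child = c("d1", "d2", "d3"),
#'                                    parent = "root"))
#' informationContent(onto)  # leaves get -log(1/4)
#' @export
informationContent <- function(onto) {
  stopifnot(is(onto, "DiseaseOntology"))
  validObject(onto)
  nT <- length(onto@terms)
  cm <- .childMap(onto)
  desc <- new.env(parent = emptyenv())
  count <- function(t) {
    if (!is.null(desc[[t]])) return(desc[[t]])
    res <- t
    for (ch in cm[[t]]) res <- union(res, count(ch))
    desc[[t]] <- res
    res
  }
  ic <- vapply(onto@terms, function(t) -log(length(count(t)) / nT), 0)
  names(ic) <- onto@terms
  ic
}

#' Semantic similarity between two disease terms
#'
#' Default mode is Lin similarity over ontology information content:
#' `2 * IC(MICA) / (IC(d1) + IC(d2))`, where MICA is the common ancestor
#' with maximal IC. Two diseases sharing a specific ancestor score high;
#' when the only common ancestor is the root (IC 0) — or either input is the
#' root so the denominator vanishes — the score is 0. A term's similarity to
#' itself is defined as 1. The `"annotation"` mode instead scores the
#' Jaccard overlap of the two terms' annotation-entity sets.
#'
#' @param d1,d2 term ids present in the ontology.
#' @param onto a [DiseaseOntology].
#' @param method `"lin"` (default) or `"annotation"`.
#' @param ic optional precomputed [informationContent()] vector (avoids
#'   recomputation inside pairwise loops).
#' @return a similarity in `[0, 1]`.
#' @export
diseaseSimilarity <- function(d1, d2, onto, method = c("lin", "annotation"),
                              ic = NULL) {
  method <- match.arg(method)
  if (!d1 %in% onto@terms || !d2 %in% onto@terms)
    stop("unknown disease term: ",
         paste(setdiff(c(d1, d2), onto@terms), collapse = ", "),
         call. = FALSE)
  if (d1 == d2) return(1)
  if (method == "annotation") {
    a1 <- onto@annotationMap[[d1]]; a2 <- onto@annotationMap[[d2]]
    u <- union(a1, a2)
    return(if (length(u) == 0L) 0 else length(intersect(a1, a2)) / length(u))
  }
  if (is.null(ic)) ic <- informationContent(onto)
  anc <- .ancestorSets(onto)
  common <- intersect(anc[[d1]], anc[[d2]])
  mica <- max(ic[common])
  denom <- ic[[d1]] + ic[[d2]]
  if (denom == 0 || mica == 0) return(0)
  unname(2 * mica / denom)
}

#' Threshold pairwise disease similarity into a network
#'
#' Computes all pairwise similarities among the requested diseases and keeps
#' an (unweighted, symmetric) edge wherever the similarity reaches `tau`.
#' The diagonal is zero.
#'
#' @param onto a [DiseaseOntology].
#' @param diseases ordered character vector of disease ids (must be terms).
#' @param tau similarity threshold in `[0, 1]`; default 0.3.
#' @param method passed to [diseaseSimilarity()].
#' @return a binary symmetric matrix with `diseases` as dimnames.
#' @export
buildDiseaseNetwork <- function(onto, diseases, tau = 0.3,
                                method = c("lin", "annotation")) {
  method <- match.arg(method)
  stopifnot(tau >= 0, tau <= 1.01)
  if (!all(diseases %in% onto@terms))
    stop("unknown disease term: ",
         paste(setdiff(diseases, onto@terms), collapse = ", "),
         call. = FALSE)
  n <- length(diseases)
  A <- matrix(0, n, n, dimnames = list(diseases, diseases))
  if (n < 2) return(A)
  if (method == "lin") {
    ic <- informationContent(onto)
    anc <- .ancestorSets(onto)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        common <- intersect(anc[[diseases[i]]], anc[[diseases[j]]])
        mica <- max(ic[common])
        denom <- ic[[diseases[i]]] + ic[[diseases[j]]]
        s <- if (denom == 0 || mica == 0) 0 else 2 * mica / denom
        if (s >= tau) A[i, j] <- A[j, i] <- 1
      }
    }
  } else {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        s <- diseaseSimilarity(diseases[i], diseases[j], onto,
                               method = "annotation")
        if (s >= tau) A[i, j] <- A[j, i] <- 1
      }
    }
  }
  A
}

#' Assemble the typed disease-gene heterogeneous graph
#'
#' Joins the disease similarity network, the gene interaction network and
#' the disease-gene association cross-links into one node universe (diseases
#' first, then genes, each stably sorted by id) and one adjacency matrix per
#' edge type, plus an identity type. Association ids absent from the node
#' universes are a referential-integrity error, never silently dropped.
#'
#' @param diseaseAdj symmetric binary disease x disease matrix with disease
#'   ids as dimnames (e.g. from [buildDiseaseNetwork()]).
#' @param geneEdges data.frame with columns `gene1`, `gene2`.
#' @param assocEdges data.frame with columns `disease`, `gene`; may have
#'   zero rows.
#' @param geneIds optional full gene universe; defaults to the ids seen in
#'   `geneEdges`.
#' @return a [HeterogeneousGraph].
#' @export
assembleHeterogeneousGraph <- function(diseaseAdj, geneEdges, assocEdges,
                                       geneIds = NULL) {
  dIds <- sort(rownames(diseaseAdj))
  gIds <- if (is.null(geneIds))
    sort(unique(c(geneEdges$gene1, geneEdges$gene2))) else sort(geneIds)
  badD <- setdiff(assocEdges$disease, dIds)
  badG <- setdiff(assocEdges$gene, gIds)
  if (length(badD) || length(badG))
    stop("association list references unknown ids: ",
         paste(c(badD, badG), collapse = ", "), call. = FALSE)
  badE <- setdiff(c(geneEdges$gene1, geneEdges$gene2), gIds)
  if (length(badE))
    stop("gene edge list references unknown genes: ",
         paste(badE, collapse = ", "), call. = FALSE)

  nd <- length(dIds); ng <- length(gIds); n <- nd + ng
  nodes <- c(dIds, gIds)
  empty <- function() matrix(0, n, n, dimnames = list(nodes, nodes))

  Add <- empty()
  Add[dIds, dIds] <- diseaseAdj[dIds, dIds]
  Agg <- empty()
  if (nrow(geneEdges)) {
    i <- match(geneEdges$gene1, nodes); j <- match(geneEdges$gene2, nodes)
    Agg[cbind(i, j)] <- 1; Agg[cbind(j, i)] <- 1
  }
  Adg <- empty()
  if (nrow(assocEdges)) {
    i <- match(assocEdges$disease, nodes); j <- match(assocEdges$gene, nodes)
    Adg[cbind(i, j)] <- 1
  }
  Agd <- t(Adg)
  I <- empty(); diag(I) <- 1

  new("HeterogeneousGraph", diseaseIds = dIds, geneIds = gIds,
      adjacency = list(disease_disease = Add, gene_gene = Agg,
                       disease_gene = Adg, gene_disease = Agd,
                       identity = I))
}
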