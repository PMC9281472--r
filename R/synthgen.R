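#' Build a validated synthetic-data configuration
#'
#' The defaults define the package's reference study conditions: 50 diseases,
#' 300 genes, 200 miRNAs and 400 planted associations, with a strong planted
#' signal (`pSignal = 0.8`) over a sparse background (`pNoise = 0.05`).
#'
#' @param nDiseases,nGenes,nMirnas sizes of the three id universes.
#' @param nAssoc number of planted disease-gene associations.
#' @param pSignal probability that an associated gene copies any given miRNA
#'   of its disease's latent profile. Must satisfy
#'   `0 <= pNoise <= pSignal <= 1`.
#' @param pNoise background probability of any indicator cell firing.
#' @param ontologyBranching target mean children per ontology node.
#' @param geneNetAttach edges attached per new gene node (preferential
#'   attachment); must be `< nGenes`.
#' @param seed integer RNG seed; every random draw in the bundle flows from
#'   it.
#' @return a [SynthConfig].
#' @examples
#' cfg <- synthConfig(nDiseases = 10, nGenes = 40, nMirnas = 30, nAssoc = 20)
#' @export
synthConfig <- function(nDiseases = 50L, nGenes = 300L, nMirnas = 200L,
                        nAssoc = 400L, pSignal = 0.8, pNoise = 0.05,
                        ontologyBranching = 3, geneNetAttach = 2L,
                        seed = 1L) {
  new("SynthConfig",
      nDiseases = as.integer(nDiseases), nGenes = as.integer(nGenes),
      nMirnas = as.integer(nMirnas), nAssoc = as.integer(nAssoc),
      pSignal = as.numeric(pSignal), pNoise = as.numeric(pNoise),
      ontologyBranching = as.numeric(ontologyBranching),
      geneNetAttach = as.integer(geneNetAttach), seed = as.integer(seed))
}

.diseaseLabels <- function(n) sprintf("D%04d", seq_len(n))
.geneLabels <- function(n) sprintf("G%05d", seq_len(n))
.mirnaLabels <- function(n) sprintf("M%04d", seq_len(n))

#' Generate a rooted disease-ontology DAG
#'
#' Grows a random recursive tree node by node: each new term attaches to a
#' parent drawn uniformly among earlier terms that still have fewer than
#' `ontologyBranching` children (falling back to all earlier terms once every
#' slot is full). With probability 0.1 a term additionally receives a second,
#' distinct parent among earlier terms, which turns the tree into a genuine
#' multi-ancestor DAG as real disease ontologies are. The first term is the
#' single root.
#'
#' @param cfg a [SynthConfig]; `nDiseases` must be at least 2.
#' @return a data.frame with columns `child`, `parent` (one row per parent
#'   link), deterministic under `cfg@seed`.
#' @export
generateOntology <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  validObject(cfg)
  if (cfg@nDiseases < 2L)
    stop("generateOntology() needs at least 2 diseases", call. = FALSE)
  ids <- .diseaseLabels(cfg@nDiseases)
  .withSeed(cfg@seed, offset = 101L, {
    childCount <- integer(cfg@nDiseases)
    child <- character(0); parent <- character(0)
    for (i in 2:cfg@nDiseases) {
      open <- which(childCount[seq_len(i - 1L)] < cfg@ontologyBranching)
      if (!length(open)) open <- seq_len(i - 1L)
      p <- if (length(open) == 1L) open else sample(open, 1L)
      childCount[p] <- childCount[p] + 1L
      child <- c(child, ids[i]); parent <- c(parent, ids[p])
      if (i > 2L && stats::runif(1) < 0.1) {
        cand <- setdiff(seq_len(i - 1L), p)
        p2 <- if (length(cand) == 1L) cand else sample(cand, 1L)
        child <- c(child, ids[i]); parent <- c(parent, ids[p2])
      }
    }
    data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
  })
}

#' Generate a scale-free gene interaction network
#'
#' Preferential attachment (Barabasi-Albert) with `geneNetAttach` edges per
#' new node, giving the heavy-tailed degree distribution typical of curated
#' gene functional networks. The result is a connected simple undirected
#' graph.
#'
#' @param cfg a [SynthConfig]; requires `nGenes > geneNetAttach`.
#' @return a data.frame with columns `gene1`, `gene2`, one row per
#'   undirected edge, deterministic under `cfg@seed`.
#' @export
generateGeneNetwork <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  validObject(cfg)
  if (cfg@nGenes <= cfg@geneNetAttach)
    stop("nGenes must exceed geneNetAttach", call. = FALSE)
  ids <- .geneLabels(cfg@nGenes)
  .withSeed(cfg@seed, offset = 202L, {
    g <- igraph::sample_pa(cfg@nGenes, m = cfg@geneNetAttach,
                           directed = FALSE, algorithm = "psumtree")
    e <- igraph::as_edgelist(g, names = FALSE)
    ## canonical order: smaller index first, then sorted, for byte-stable
    ## output
    a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
    o <- order(a, b)
    data.frame(gene1 = ids[a[o]], gene2 = ids[b[o]],
               stringsAsFactors = FALSE)
  })
}

#' Plant associations and draw miRNA indicator features
#'
#' Samples `nAssoc` disease-gene pairs uniformly without replacement as
#' ground-truth positives, draws a fixed-size latent miRNA profile per
#' disease (size `max(5, nMirnas / 20)`), and builds the two binary
#' indicator matrices. A disease's row carries its profile (plus background
#' noise on the remaining cells). For a gene, the *signal cells* are the
#' union of the profiles of its associated diseases: signal cells fire with
#' probability `pSignal`, every other cell with the background probability
#' `pNoise`. Signal replaces (rather than stacks on) the background, so at
#' `pSignal == pNoise` every gene row is i.i.d. Bernoulli(`pNoise`) and the
#' features carry exactly no information about the planted associations.
#'
#' @param cfg a [SynthConfig].
#' @param ontologyEdges output of [generateOntology()] under the same config.
#' @param geneEdges output of [generateGeneNetwork()] under the same config.
#' @return a [SynthBundle]; deterministic under `cfg@seed`.
#' @export
plantAssociations <- function(cfg, ontologyEdges, geneEdges) {
  stopifnot(is(cfg, "SynthConfig"))
  validObject(cfg)
  dIds <- .diseaseLabels(cfg@nDiseases)
  gIds <- .geneLabels(cfg@nGenes)
  mIds <- .mirnaLabels(cfg@nMirnas)
  .withSeed(cfg@seed, offset = 303L, {
    pairIdx <- sample.int(cfg@nDiseases * cfg@nGenes, cfg@nAssoc)
    di <- (pairIdx - 1L) %% cfg@nDiseases + 1L
    gi <- (pairIdx - 1L) %/% cfg@nDiseases + 1L
    o <- order(di, gi)
    di <- di[o]; gi <- gi[o]

    profSize <- max(5L, as.integer(round(cfg@nMirnas / 20)))
    profiles <- lapply(seq_len(cfg@nDiseases),
                       function(i) sample.int(cfg@nMirnas, profSize))

    ## disease rows: profile cells on, background elsewhere
    mdis <- matrix((stats::runif(cfg@nDiseases * cfg@nMirnas) <
                      cfg@pNoise) * 1L,
                   cfg@nDiseases, cfg@nMirnas,
                   dimnames = list(dIds, mIds))
    for (i in seq_len(cfg@nDiseases)) mdis[i, profiles[[i]]] <- 1L

    ## gene rows: signal cells (union of associated diseases' profiles)
    ## fire at pSignal, all other cells at the background rate; signal
    ## replaces the background so pSignal == pNoise is an exact null
    mgene <- matrix((stats::runif(cfg@nGenes * cfg@nMirnas) <
                       cfg@pNoise) * 1L,
                    cfg@nGenes, cfg@nMirnas,
                    dimnames = list(gIds, mIds))
    sigCells <- vector("list", cfg@nGenes)
    for (k in seq_len(cfg@nAssoc))
      sigCells[[gi[k]]] <- union(sigCells[[gi[k]]], profiles[[di[k]]])
    for (gidx in which(lengths(sigCells) > 0)) {
      cells <- sigCells[[gidx]]
      mgene[gidx, cells] <- (stats::runif(length(cells)) <
                               cfg@pSignal) * 1L
    }

    truth <- matrix(0L, cfg@nDiseases, cfg@nGenes,
                    dimnames = list(dIds, gIds))
    truth[cbind(di, gi)] <- 1L

    new("SynthBundle", config = cfg,
        ontologyEdges = ontologyEdges, geneEdges = geneEdges,
        assocEdges = data.frame(disease = dIds[di], gene = gIds[gi],
                                stringsAsFactors = FALSE),
        mirnaGene = new("FeatureMatrix", values = mgene),
        mirnaDisease = new("FeatureMatrix", values = mdis),
        truthLabels = truth)
  })
}

#' Generate a complete synthetic input bundle
#'
#' Convenience wrapper running [generateOntology()],
#' [generateGeneNetwork()] and [plantAssociations()] under one config.
#' Identical configs (including seed) give identical bundles.
#'
#' @param cfg a [SynthConfig].
#' @return a [SynthBundle].
#' @examples
#' b <- simulateBundle(synthConfig(nDiseases = 8, nGenes = 30, nMirnas = 40,
#'                                 nAssoc = 16, seed = 3))
#' b
#' @export
simulateBundle <- function(cfg) {
  onto <- generateOntology(cfg)
  net <- generateGeneNetwork(cfg)
  plantAssociations(cfg, onto, net)
}
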