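#' @import methods
NULL

.EDGE_TYPES <- c("disease_disease", "gene_gene", "disease_gene",
                 "gene_disease", "identity")

#' Configuration of the synthetic-data generator
#'
#' Holds every knob of the synthetic input generator: the sizes of the three
#' node universes, the number of planted disease-gene associations, the
#' planted-signal and background-noise probabilities of the binary miRNA
#' indicators, the shape parameters of the disease ontology and the gene
#' interaction network, and the RNG seed. All randomness in a bundle flows
#' from `seed`; no global RNG state is consumed.
#'
#' @slot nDiseases number of disease terms (the ontology size).
#' @slot nGenes number of genes.
#' @slot nMirnas number of miRNAs, i.e. the binary feature dimension.
#' @slot nAssoc number of planted disease-gene associations.
#' @slot pSignal probability that an associated gene copies any given miRNA
#'   of its disease's latent profile.
#' @slot pNoise background probability that any indicator cell fires.
#' @slot ontologyBranching target mean number of children per ontology node.
#' @slot geneNetAttach edges added per new gene in preferential attachment.
#' @slot seed integer RNG seed.
#'
#' @seealso [synthConfig()] for the validated constructor.
#' @export
setClass("SynthConfig",
  representation(
    nDiseases = "integer", nGenes = "integer", nMirnas = "integer",
    nAssoc = "integer", pSignal = "numeric", pNoise = "numeric",
    ontologyBranching = "numeric", geneNetAttach = "integer",
    seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  counts <- c(nDiseases = object@nDiseases, nGenes = object@nGenes,
              nMirnas = object@nMirnas, nAssoc = object@nAssoc,
              geneNetAttach = object@geneNetAttach)
  if (any(counts <= 0L))
    msg <- c(msg, sprintf("all counts must be positive (%s)",
                          paste(names(counts)[counts <= 0L], collapse = ", ")))
  if (object@pNoise < 0 || object@pSignal > 1 ||
      object@pNoise > object@pSignal)
    msg <- c(msg, "need 0 <= pNoise <= pSignal <= 1")
  if (object@nAssoc > object@nDiseases * object@nGenes)
    msg <- c(msg, "nAssoc exceeds the number of disease x gene pairs")
  if (object@ontologyBranching < 1)
    msg <- c(msg, "ontologyBranching must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Binary miRNA-indicator feature matrix
#'
#' A node-by-miRNA 0/1 matrix. Row names are node (gene or disease) ids,
#' column names are miRNA ids; both are duplicate-free. Gene and disease
#' matrices built together share one identical miRNA column ordering so that
#' both node types live in the same visible space of the deep belief network.
#'
#' @slot values binary matrix with node rownames and miRNA colnames.
#' @export
setClass("FeatureMatrix", representation(values = "matrix"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (length(v) && !all(v %in% c(0, 1)))
    msg <- c(msg, "feature values must be 0/1")
  if (is.null(rownames(v)) && nrow(v) > 0)
    msg <- c(msg, "row ids (rownames) required")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicate row ids")
  if (anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicate column ids")
  if (length(msg)) msg else TRUE
})

#' Disease ontology as a rooted parent DAG
#'
#' Terms plus a child-to-parents map. The parent relation must be acyclic and
#' every term must reach a (single) root, mirroring how disease ontologies
#' organise terms under one top node. An optional annotation map (term to
#' annotation-entity ids) supports the annotation-overlap similarity mode.
#'
#' @slot terms character vector of term ids.
#' @slot parentMap named list: term id -> character vector of parent ids
#'   (empty for the root).
#' @slot annotationMap named list: term id -> character vector of annotation
#'   entity ids; may be empty.
#' @export
setClass("DiseaseOntology",
  representation(terms = "character", parentMap = "list",
                 annotationMap = "list"),
  prototype(annotationMap = list())
)

setValidity("DiseaseOntology", function(object) {
  msg <- character()
  if (anyDuplicated(object@terms)) msg <- c(msg, "duplicate term ids")
  if (!setequal(names(object@parentMap), object@terms))
    msg <- c(msg, "parentMap names must equal the term set")
  else {
    par <- unlist(object@parentMap, use.names = FALSE)
    if (length(par) && !all(par %in% object@terms))
      msg <- c(msg, "parentMap references unknown terms")
    roots <- object@terms[vapply(object@parentMap[object@terms], length,
                                 1L) == 0L]
    if (length(roots) != 1L)
      msg <- c(msg, sprintf("ontology must have exactly one root (found %d)",
                            length(roots)))
    if (!length(msg) && .ontoHasCycle(object@parentMap))
      msg <- c(msg, "parent relation contains a cycle")
  }
  if (length(msg)) msg else TRUE
})

#' Typed disease-gene heterogeneous graph
#'
#' A two-type node set (diseases then genes, each stably sorted by id) and a
#' stack of per-edge-type square adjacency matrices over the unified node
#' ordering. The stack always holds the five edge types
#' `disease_disease`, `gene_gene`, `disease_gene`, `gene_disease` and
#' `identity`, in that order. Each matrix is nonzero only in its designated
#' quadrant; the homogeneous matrices are symmetric and the two cross-type
#' matrices are each other's transpose. The identity type lets the graph
#' transformer express meta-paths shorter than its layer count.
#'
#' @slot diseaseIds ordered disease ids.
#' @slot geneIds ordered gene ids.
#' @slot adjacency named list of `(|D|+|G|)` square non-negative matrices.
#' @export
setClass("HeterogeneousGraph",
  representation(diseaseIds = "character", geneIds = "character",
                 adjacency = "list")
)

setValidity("HeterogeneousGraph", function(object) {
  nd <- length(object@diseaseIds); ng <- length(object@geneIds)
  n <- nd + ng
  msg <- character()
  if (anyDuplicated(c(object@diseaseIds, object@geneIds)))
    msg <- c(msg, "node ids must be globally unique")
  if (!identical(names(object@adjacency), .EDGE_TYPES))
    return(sprintf("adjacency stack must hold edge types: %s",
                   paste(.EDGE_TYPES, collapse = ", ")))
  dIdx <- seq_len(nd); gIdx <- nd + seq_len(ng)
  for (ty in .EDGE_TYPES) {
    A <- object@adjacency[[ty]]
    if (!is.matrix(A) || nrow(A) != n || ncol(A) != n)
      return(sprintf("'%s' matrix must be %d x %d", ty, n, n))
    if (any(A < 0)) msg <- c(msg, sprintf("'%s' has negative entries", ty))
    out <- switch(ty,
      disease_disease = sum(A[gIdx, , drop = FALSE]) +
                        sum(A[, gIdx, drop = FALSE]),
      gene_gene       = sum(A[dIdx, , drop = FALSE]) +
                        sum(A[, dIdx, drop = FALSE]),
      disease_gene    = sum(A) - sum(A[dIdx, gIdx, drop = FALSE]),
      gene_disease    = sum(A) - sum(A[gIdx, dIdx, drop = FALSE]),
      identity        = sum(abs(A - diag(n))))
    if (isTRUE(out > 0))
      msg <- c(msg, sprintf("'%s' has mass outside its quadrant", ty))
  }
  if (!isTRUE(all.equal(object@adjacency$disease_disease,
                        t(object@adjacency$disease_disease))))
    msg <- c(msg, "disease_disease matrix must be symmetric")
  if (!isTRUE(all.equal(object@adjacency$gene_gene,
                        t(object@adjacency$gene_gene))))
    msg <- c(msg, "gene_gene matrix must be symmetric")
  if (!isTRUE(all.equal(object@adjacency$disease_gene,
                        t(object@adjacency$gene_disease))))
    msg <- c(msg, "disease_gene must be the transpose of gene_disease")
  if (length(msg)) msg else TRUE
})

#' Parameters of one restricted Boltzmann machine
#'
#' Weights and biases of a binary-binary RBM with energy
#' \eqn{E(v,h) = -a^T v - b^T h - v^T W h}: `W` is m visible x n hidden,
#' `visibleBias` (a) has length m and `hiddenBias` (b) length n.
#'
#' @slot W real weight matrix, visible x hidden.
#' @slot visibleBias visible bias vector a.
#' @slot hiddenBias hidden bias vector b.
#' @export
setClass("RBM",
  representation(W = "matrix", visibleBias = "numeric", hiddenBias = "numeric")
)

setValidity("RBM", function(object) {
  msg <- character()
  if (nrow(object@W) != length(object@visibleBias))
    msg <- c(msg, "nrow(W) must equal length(visibleBias)")
  if (ncol(object@W) != length(object@hiddenBias))
    msg <- c(msg, "ncol(W) must equal length(hiddenBias)")
  if (!all(is.finite(object@W)) || !all(is.finite(object@visibleBias)) ||
      !all(is.finite(object@hiddenBias)))
    msg <- c(msg, "all parameters must be finite")
  if (length(msg)) msg else TRUE
})

#' Stacked-RBM deep belief network
#'
#' An ordered stack of three RBM layers trained greedily by contrastive
#' divergence; layer k's visible size equals layer k-1's hidden size. After
#' pretraining the stack acts as a deterministic encoder via mean-field
#' hidden activations.
#'
#' @slot layers list of [RBM] objects (length 3 by construction).
#' @slot trained logical flag per layer.
#' @slot hyperparams list of training hyperparameters (lr, batch, epochs,
#'   layer sizes, seed).
#' @export
setClass("DBN",
  representation(layers = "list", trained = "logical", hyperparams = "list"),
  prototype(layers = list(), trained = logical(), hyperparams = list())
)

setValidity("DBN", function(object) {
  if (!all(vapply(object@layers, is, TRUE, class2 = "RBM")))
    return("layers must all be RBM objects")
  if (length(object@trained) != length(object@layers))
    return("one trained flag per layer required")
  if (length(object@layers) > 1) {
    for (k in 2:length(object@layers)) {
      if (nrow(object@layers[[k]]@W) != ncol(object@layers[[k - 1]]@W))
        return(sprintf("layer %d visible size != layer %d hidden size",
                       k, k - 1))
    }
  }
  TRUE
})

#' Graph transformer network model
#'
#' Learnable parameters of the heterogeneous-network encoder plus the
#' link-prediction head. Each channel owns one edge-type selection logit
#' vector per selection slot; softmax over the edge-type axis turns the
#' logits into convex combination weights. Meta-path adjacencies are the
#' (degree-normalized) product of the selected combinations and feed a stack
#' of graph-convolution layers whose weights are shared across channels;
#' channel outputs are concatenated column-wise. The head is a one-hidden-
#' layer logistic MLP over the concatenated disease and gene embeddings.
#'
#' @slot selectionLogits list (one per channel) of slots x edge-types logit
#'   matrices.
#' @slot gcnWeights list of GCN weight matrices, chain-compatible.
#' @slot headParams list with elements `V`, `c0` (hidden layer) and `w`, `b`
#'   (output unit).
#' @slot config list of architecture settings (channels, slots, widths,
#'   edge types).
#' @slot trained logical scalar.
#' @export
setClass("GTNModel",
  representation(selectionLogits = "list", gcnWeights = "list",
                 headParams = "list", config = "list", trained = "logical"),
  prototype(trained = FALSE)
)

setValidity("GTNModel", function(object) {
  cfg <- object@config
  if (length(object@selectionLogits) != cfg$channels)
    return("one selection-logit matrix per channel required")
  for (L in object@selectionLogits) {
    if (!is.matrix(L) || nrow(L) != cfg$slots ||
        ncol(L) != cfg$nEdgeTypes)
      return("selection logits must be slots x nEdgeTypes matrices")
  }
  if (length(object@gcnWeights) >= 2) {
    for (k in 2:length(object@gcnWeights))
      if (ncol(object@gcnWeights[[k - 1]]) != nrow(object@gcnWeights[[k]]))
        return("GCN weight shapes are not chain-compatible")
  }
  TRUE
})

#' Cross-validated split plan for link prediction
#'
#' Labeled disease-gene pairs (known positives plus sampled negatives) with
#' stratified fold assignments. Negatives are sampled per disease from genes
#' not known to be associated with it, so they are disjoint from the
#' positives by construction.
#'
#' @slot pairs data.frame with columns disease, gene, label (0/1), fold.
#' @slot ratio negative:positive sampling ratio.
#' @slot seed integer seed the negatives and folds were drawn under.
#' @export
setClass("SplitPlan",
  representation(pairs = "data.frame", ratio = "numeric", seed = "integer")
)

setValidity("SplitPlan", function(object) {
  p <- object@pairs
  req <- c("disease", "gene", "label", "fold")
  if (!all(req %in% names(p)))
    return(sprintf("pairs needs columns: %s", paste(req, collapse = ", ")))
  if (!all(p$label %in% c(0, 1))) return("labels must be 0/1")
  key <- paste(p$disease, p$gene)
  if (anyDuplicated(key)) return("pairs must be unique")
  TRUE
})

#' Evaluation report for one method
#'
#' Pooled cross-validated AUC and AUPR with per-fold values, the seed list
#' and a fingerprint of the configuration that produced them, so reports are
#' comparable across methods and reproducible runs map to identical reports.
#'
#' @slot method method label, e.g. `"dbn-gtn"` or `"svm"`.
#' @slot auc pooled area under the ROC curve, in `[0, 1]`.
#' @slot aupr pooled area under the precision-recall curve, in `[0, 1]`.
#' @slot folds data.frame of per-fold auc/aupr.
#' @slot seeds integer seeds used.
#' @slot fingerprint configuration fingerprint string.
#' @slot notes free-text caveats (e.g. transductive t-SNE flag).
#' @export
setClass("EvalReport",
  representation(method = "character", auc = "numeric", aupr = "numeric",
                 folds = "data.frame", seeds = "integer",
                 fingerprint = "character", notes = "character"),
  prototype(notes = character())
)

setValidity("EvalReport", function(object) {
  if (length(object@auc) != 1L || object@auc < 0 || object@auc > 1)
    return("auc must be a single value in [0, 1]")
  if (length(object@aupr) != 1L || object@aupr < 0 || object@aupr > 1)
    return("aupr must be a single value in [0, 1]")
  TRUE
})

#' Synthetic input bundle
#'
#' Everything the pipeline consumes, generated with a planted association
#' signal: the disease-ontology edge list, the gene interaction network, the
#' ground-truth disease-gene associations, the two binary miRNA feature
#' matrices (sharing one miRNA column universe) and the full disease x gene
#' truth-label matrix.
#'
#' @slot config the [SynthConfig] the bundle was drawn under.
#' @slot ontologyEdges data.frame(child, parent).
#' @slot geneEdges data.frame(gene1, gene2), simple undirected.
#' @slot assocEdges data.frame(disease, gene), the planted positives.
#' @slot mirnaGene gene [FeatureMatrix].
#' @slot mirnaDisease disease [FeatureMatrix].
#' @slot truthLabels binary disease x gene matrix.
#' @export
setClass("SynthBundle",
  representation(config = "SynthConfig", ontologyEdges = "data.frame",
                 geneEdges = "data.frame", assocEdges = "data.frame",
                 mirnaGene = "FeatureMatrix", mirnaDisease = "FeatureMatrix",
                 truthLabels = "matrix")
)

setValidity("SynthBundle", function(object) {
  msg <- character()
  g <- object@geneEdges
  if (any(g$gene1 == g$gene2)) msg <- c(msg, "gene graph has self-loops")
  key <- paste(pmin(g$gene1, g$gene2), pmax(g$gene1, g$gene2))
  if (anyDuplicated(key)) msg <- c(msg, "gene graph has duplicate edges")
  pos <- which(object@truthLabels == 1, arr.ind = TRUE)
  posKey <- paste(rownames(object@truthLabels)[pos[, 1]],
                  colnames(object@truthLabels)[pos[, 2]])
  assocKey <- paste(object@assocEdges$disease, object@assocEdges$gene)
  if (!setequal(posKey, assocKey))
    msg <- c(msg, "truthLabels positives must equal assocEdges exactly")
  if (length(msg)) msg else TRUE
})
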