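#' @rdname HeterogeneousGraph-class
#' @export
setMethod("diseaseIds", "HeterogeneousGraph", function(x) x@diseaseIds)

#' @rdname HeterogeneousGraph-class
#' @export
setMethod("geneIds", "HeterogeneousGraph", function(x) x@geneIds)

#' @rdname HeterogeneousGraph-class
#' @export
setMethod("nodeIds", "HeterogeneousGraph",
          function(x) c(x@diseaseIds, x@geneIds))

#' @rdname HeterogeneousGraph-class
#' @export
setMethod("adjacencyStack", "HeterogeneousGraph", function(x) x@adjacency)

#' @rdname HeterogeneousGraph-class
#' @export
setMethod("edgeTypes", "HeterogeneousGraph", function(x) names(x@adjacency))

setMethod("show", "HeterogeneousGraph", function(object) {
  nd <- length(object@diseaseIds); ng <- length(object@geneIds)
  cat("HeterogeneousGraph:", nd, "diseases +", ng, "genes\n")
  for (ty in names(object@adjacency)) {
    A <- object@adjacency[[ty]]
    nz <- sum(A != 0)
    cat(sprintf("  %-16s %d nonzero entries\n", ty, nz))
  }
})

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix-class
#' @export
setMethod("rowIds", "FeatureMatrix", function(x) rownames(x@values))

#' @rdname FeatureMatrix-class
#' @export
setMethod("colIds", "FeatureMatrix", function(x) colnames(x@values))

#' @rdname FeatureMatrix-class
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d nodes x %d miRNAs, density %.3f\n",
              nrow(object@values), ncol(object@values),
              if (length(object@values)) mean(object@values) else 0))
})

#' @rdname DiseaseOntology-class
#' @export
setMethod("ontologyTerms", "DiseaseOntology", function(x) x@terms)

#' @rdname DiseaseOntology-class
#' @export
setMethod("parentMap", "DiseaseOntology", function(x) x@parentMap)

setMethod("show", "DiseaseOntology", function(object) {
  nEdge <- sum(lengths(object@parentMap))
  cat("DiseaseOntology:", length(object@terms), "terms,",
      nEdge, "parent links\n")
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:",
      sprintf("%d diseases, %d genes, %d miRNAs, %d associations",
              object@nDiseases, object@nGenes, object@nMirnas,
              object@nAssoc), "\n")
  cat(sprintf("  pSignal=%.3g pNoise=%.3g branching=%.3g attach=%d seed=%d\n",
              object@pSignal, object@pNoise, object@ontologyBranching,
              object@geneNetAttach, object@seed))
})

setMethod("show", "SynthBundle", function(object) {
  cat("SynthBundle generated under seed", object@config@seed, "\n")
  cat("  ontology edges:", nrow(object@ontologyEdges),
      "| gene edges:", nrow(object@geneEdges),
      "| associations:", nrow(object@assocEdges), "\n")
  show(object@mirnaGene)
  show(object@mirnaDisease)
})

setMethod("show", "RBM", function(object) {
  cat(sprintf("RBM: %d visible x %d hidden units\n",
              nrow(object@W), ncol(object@W)))
})

setMethod("show", "DBN", function(object) {
  sizes <- vapply(object@layers, function(l) ncol(l@W), 1L)
  vis <- if (length(object@layers)) nrow(object@layers[[1]]@W) else 0L
  cat("DBN:", paste(c(vis, sizes), collapse = " -> "),
      if (all(object@trained)) "(trained)" else "(untrained)", "\n")
})

setMethod("show", "GTNModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "GTNModel: %d channel(s), %d selection slot(s), %d edge types, GCN %s\n",
    cfg$channels, cfg$slots, cfg$nEdgeTypes,
    paste(vapply(object@gcnWeights, ncol, 1L), collapse = " -> ")))
  cat(" ", if (object@trained) "trained" else "untrained", "\n")
})

setMethod("show", "SplitPlan", function(object) {
  p <- object@pairs
  cat(sprintf("SplitPlan: %d pairs (%d pos / %d neg), %d folds, seed %d\n",
              nrow(p), sum(p$label == 1), sum(p$label == 0),
              length(unique(p$fold)), object@seed))
})

#' @rdname EvalReport-accessors
#' @export
setMethod("reportAUC", "EvalReport", function(x) x@auc)

#' @rdname EvalReport-accessors
#' @export
setMethod("reportAUPR", "EvalReport", function(x) x@aupr)

#' @rdname EvalReport-accessors
#' @export
setMethod("foldMetrics", "EvalReport", function(x) x@folds)

#' @rdname EvalReport-accessors
#' @export
setMethod("methodLabel", "EvalReport", function(x) x@method)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport [%s]: AUC %.4f, AUPR %.4f (%d folds)\n",
              object@method, object@auc, object@aupr, nrow(object@folds)))
  if (length(object@notes)) cat("  note:", object@notes, "\n")
})
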