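#' @rdname HeterogeneousGraph-class
#' @param x,object an object.
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' @rdname HeterogeneousGraph-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname HeterogeneousGraph-class
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname HeterogeneousGraph-class
#' @export
setGeneric("adjacencyStack", function(x) standardGeneric("adjacencyStack"))

#' @rdname HeterogeneousGraph-class
#' @export
setGeneric("edgeTypes", function(x) standardGeneric("edgeTypes"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("rowIds", function(x) standardGeneric("rowIds"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("colIds", function(x) standardGeneric("colIds"))

#' @rdname DiseaseOntology-class
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))

#' @rdname DiseaseOntology-class
#' @export
setGeneric("parentMap", function(x) standardGeneric("parentMap"))

#' Accessors for evaluation reports
#'
#' @param x an [EvalReport].
#' @return `reportAUC`/`reportAUPR` return the pooled metric; `foldMetrics`
#'   the per-fold data.frame; `methodLabel` the method string.
#' @rdname EvalReport-accessors
#' @export
setGeneric("reportAUC", function(x) standardGeneric("reportAUC"))

#' @rdname EvalReport-accessors
#' @export
setGeneric("reportAUPR", function(x) standardGeneric("reportAUPR"))

#' @rdname EvalReport-accessors
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))

#' @rdname EvalReport-accessors
#' @export
setGeneric("methodLabel", function(x) standardGeneric("methodLabel"))
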