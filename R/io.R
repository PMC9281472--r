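#' Read a headered TSV edge list
#'
#' Strict reader for the two-column (optionally more) tab-separated inputs:
#' the header must contain every expected column (extra columns are
#' ignored), values are whitespace-trimmed, duplicate rows collapsed, and
#' original line numbers are kept as an attribute for error reporting. An
#' empty body yields an empty list with a warning rather than an error.
#'
#' @param path file path.
#' @param expectedColumns character vector of required column names.
#' @return data.frame with the expected columns (attribute `"line"` holds
#'   the 1-based source line of each kept row).
#' @export
readEdgeTable <- function(path, expectedColumns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE, blank.lines.skip = FALSE)
  missing <- setdiff(expectedColumns, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- df[, expectedColumns, drop = FALSE]
  for (cn in expectedColumns) df[[cn]] <- trimws(df[[cn]])
  keep <- rowSums(df != "" & !is.na(df)) == length(expectedColumns)
  df <- df[keep, , drop = FALSE]
  line <- which(keep) + 1L           # +1 for the header line
  dup <- duplicated(df)
  df <- df[!dup, , drop = FALSE]
  line <- line[!dup]
  rownames(df) <- NULL
  if (nrow(df) == 0L)
    warning(path, ": no data rows", call. = FALSE)
  attr(df, "line") <- line
  df
}

#' Write a synthetic bundle as the five standard input TSVs
#'
#' Emits exactly the formats the real-data readers consume — ontology
#' (child/parent), gene network (gene1/gene2), disease-gene associations
#' (disease/gene), miRNA-gene and miRNA-disease pair lists — plus a
#' truth-labels TSV for evaluation.
#'
#' @param bundle a [SynthBundle].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }
  pairsOf <- function(fm, nodeCol) {
    v <- featureValues(fm)
    idx <- which(v == 1, arr.ind = TRUE)
    df <- data.frame(mirna = colnames(v)[idx[, 2]],
                     node = rownames(v)[idx[, 1]],
                     stringsAsFactors = FALSE)
    names(df)[2] <- nodeCol
    df[order(df$mirna, df[[nodeCol]]), , drop = FALSE]
  }
  truth <- bundle@truthLabels
  truthLong <- data.frame(
    disease = rep(rownames(truth), times = ncol(truth)),
    gene = rep(colnames(truth), each = nrow(truth)),
    label = as.integer(truth),
    stringsAsFactors = FALSE)
  paths <- c(
    ontology = w(bundle@ontologyEdges, "ontology.tsv"),
    gene_network = w(bundle@geneEdges, "gene_network.tsv"),
    disease_gene = w(bundle@assocEdges, "disease_gene.tsv"),
    mirna_gene = w(pairsOf(bundle@mirnaGene, "gene"), "mirna_gene.tsv"),
    mirna_disease = w(pairsOf(bundle@mirnaDisease, "disease"),
                      "mirna_disease.tsv"),
    truth_labels = w(truthLong, "truth_labels.tsv"))
  invisible(paths)
}

#' Read the five standard input TSVs from a directory
#'
#' Counterpart of [writeBundle()] and the entry point for real-data-shaped
#' inputs: returns validated edge and pair lists ready for
#' [diseaseOntology()], [assembleHeterogeneousGraph()] and
#' [buildFeatureMatrices()].
#'
#' @param dir directory holding `ontology.tsv`, `gene_network.tsv`,
#'   `disease_gene.tsv`, `mirna_gene.tsv`, `mirna_disease.tsv` and
#'   optionally `truth_labels.tsv`.
#' @return named list of data.frames (`truthLabels` is `NULL` when the
#'   optional file is absent).
#' @export
readBundleDir <- function(dir) {
  rd <- function(name, cols)
    readEdgeTable(file.path(dir, name), cols)
  truthPath <- file.path(dir, "truth_labels.tsv")
  list(
    ontologyEdges = rd("ontology.tsv", c("child", "parent")),
    geneEdges = rd("gene_network.tsv", c("gene1", "gene2")),
    assocEdges = rd("disease_gene.tsv", c("disease", "gene")),
    mirnaGenePairs = rd("mirna_gene.tsv", c("mirna", "gene")),
    mirnaDiseasePairs = rd("mirna_disease.tsv", c("mirna", "disease")),
    truthLabels = if (file.exists(truthPath))
      readEdgeTable(truthPath, c("disease", "gene", "label")) else NULL)
}

#' Serialize / restore an evaluation report
#'
#' Reports round-trip exactly: numeric values are written with full
#' precision, and reading back reproduces the object.
#'
#' @param report an [EvalReport].
#' @param path JSON file path.
#' @return `writeReport` returns `path` invisibly; `readReport` the
#'   restored [EvalReport].
#' @rdname report-io
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "EvalReport"))
  ## metrics go through %.17g strings: 17 significant digits reproduce an
  ## IEEE double exactly, which JSON number emission does not guarantee
  obj <- list(method = report@method,
              auc = sprintf("%.17g", report@auc),
              aupr = sprintf("%.17g", report@aupr),
              folds = list(fold = report@folds$fold,
                           auc = sprintf("%.17g", report@folds$auc),
                           aupr = sprintf("%.17g", report@folds$aupr)),
              seeds = report@seeds, fingerprint = report@fingerprint,
              notes = report@notes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname report-io
#' @export
readReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- data.frame(fold = as.integer(obj$folds$fold),
                      auc = as.numeric(obj$folds$auc),
                      aupr = as.numeric(obj$folds$aupr))
  new("EvalReport", method = obj$method, auc = as.numeric(obj$auc),
      aupr = as.numeric(obj$aupr),
      folds = folds, seeds = as.integer(obj$seeds),
      fingerprint = obj$fingerprint,
      notes = if (length(obj$notes)) obj$notes else character())
}

#' Write / read a ranked-gene table
#'
#' Fixed column order `gene_id`, `score`, `rank`.
#'
#' @param ranking data.frame from [rankCandidates()].
#' @param path TSV file path.
#' @rdname ranking-io
#' @export
writeRankedGenes <- function(ranking, path) {
  stopifnot(all(c("gene_id", "score", "rank") %in% names(ranking)))
  utils::write.table(ranking[, c("gene_id", "score", "rank")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ranking-io
#' @export
readRankedGenes <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "numeric",
                                               "integer"))
  stopifnot(identical(names(df), c("gene_id", "score", "rank")))
  df
}

## flat named-array container shared by the DBN and link-model
## checkpoints. Values are stored as %.17g strings: 17 significant digits
## are sufficient to reproduce every IEEE double bit-for-bit, which plain
## JSON numbers do not guarantee.
.arraysToJSON <- function(arrays, meta, path) {
  enc <- lapply(arrays, function(a) {
    if (is.matrix(a)) list(dim = dim(a), data = sprintf("%.17g", a))
    else list(dim = length(a), data = sprintf("%.17g", a))
  })
  jsonlite::write_json(list(meta = meta, arrays = enc), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.arraysFromJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arrays <- lapply(obj$arrays, function(a) {
    if (length(a$dim) == 2L) matrix(as.numeric(a$data), a$dim[1], a$dim[2])
    else as.numeric(a$data)
  })
  list(meta = obj$meta, arrays = arrays)
}

#' Checkpoint a trained deep belief network
#'
#' Writes every layer's weight matrix and bias vectors plus the training
#' hyperparameters to one flat JSON container; numbers keep full precision
#' so the checkpoint round-trips exactly.
#'
#' @param dbn a [DBN].
#' @param path JSON file path.
#' @rdname dbn-io
#' @export
writeDBN <- function(dbn, path) {
  arrays <- list()
  for (k in seq_along(dbn@layers)) {
    arrays[[sprintf("W%d", k)]] <- dbn@layers[[k]]@W
    arrays[[sprintf("a%d", k)]] <- dbn@layers[[k]]@visibleBias
    arrays[[sprintf("b%d", k)]] <- dbn@layers[[k]]@hiddenBias
  }
  .arraysToJSON(arrays, c(dbn@hyperparams,
                          list(nLayers = length(dbn@layers))), path)
}

#' @rdname dbn-io
#' @export
readDBN <- function(path) {
  obj <- .arraysFromJSON(path)
  nL <- obj$meta$nLayers
  layers <- lapply(seq_len(nL), function(k)
    new("RBM", W = obj$arrays[[sprintf("W%d", k)]],
        visibleBias = obj$arrays[[sprintf("a%d", k)]],
        hiddenBias = obj$arrays[[sprintf("b%d", k)]]))
  hp <- obj$meta
  hp$nLayers <- NULL
  new("DBN", layers = layers, trained = rep(TRUE, nL), hyperparams = hp)
}

#' Validate a run configuration list
#'
#' A run configuration either points at the five real-data input TSVs
#' (`paths` block) or embeds a `simulate` block of [synthConfig()] fields
#' — never both. Unknown keys are rejected so typos fail loudly before
#' any computation starts.
#'
#' @param config named list, e.g. from [yaml::read_yaml()].
#' @return the validated config (with a `fingerprint` attached).
#' @export
validateRunConfig <- function(config) {
  known <- c("paths", "simulate", "tau", "reducer", "encoder",
             "reducedDim", "k", "negativeRatio", "seed", "dbnEpochs",
             "fit", "outdir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$paths) == is.null(config$simulate))
    stop("config must have exactly one of 'paths' or 'simulate'",
         call. = FALSE)
  if (!is.null(config$paths)) {
    need <- c("ontology", "gene_network", "disease_gene", "mirna_gene",
              "mirna_disease")
    missing <- setdiff(need, names(config$paths))
    if (length(missing))
      stop("paths block missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(config$simulate)) {
    scKnown <- c("nDiseases", "nGenes", "nMirnas", "nAssoc", "pSignal",
                 "pNoise", "ontologyBranching", "geneNetAttach", "seed")
    unknown <- setdiff(names(config$simulate), scKnown)
    if (length(unknown))
      stop("unknown simulate key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  attr(config, "fingerprint") <- configFingerprint(config)
  config
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file path.
#' @return validated config list, see [validateRunConfig()].
#' @export
readRunConfig <- function(path) {
  validateRunConfig(yaml::read_yaml(path))
}

#' Read an ontology TSV with optional annotations
#'
#' The ontology file is a child/parent TSV; an optional third column
#' `annotations` carries semicolon-separated annotation-entity ids per
#' child term (used by the annotation-overlap similarity mode).
#'
#' @param path TSV file path with header columns `child`, `parent` and
#'   optionally `annotations`.
#' @return a [DiseaseOntology].
#' @export
readOntologyFile <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  hasAnn <- "annotations" %in% hdr
  cols <- c("child", "parent", if (hasAnn) "annotations")
  df <- readEdgeTable(path, cols)
  ann <- NULL
  if (hasAnn) {
    ann <- lapply(split(df$annotations, df$child), function(x) {
      unique(unlist(strsplit(x[nzchar(x)], ";", fixed = TRUE)))
    })
    ann <- ann[lengths(ann) > 0]
  }
  diseaseOntology(df[, c("child", "parent")], annotations = ann)
}

#' Checkpoint a fitted link model
#'
#' Shares the flat named-array container of [writeDBN()]: every selection
#' logit matrix, GCN weight and head parameter is stored with full
#' precision alongside the architecture configuration, and reading back
#' reproduces scores exactly.
#'
#' @param fit a `linkModelFit` from [fitLinkModel()].
#' @param path JSON file path.
#' @rdname linkmodel-io
#' @export
writeLinkModel <- function(fit, path) {
  stopifnot(inherits(fit, "linkModelFit"))
  arrays <- list()
  if (fit$encoder == "gtn") {
    for (ch in seq_along(fit$par$sel))
      arrays[[sprintf("sel%d", ch)]] <- fit$par$sel[[ch]]
    for (l in seq_along(fit$par$gcn))
      arrays[[sprintf("gcnW%d", l)]] <- fit$par$gcn[[l]]
  } else {
    for (l in seq_along(fit$par$gcnD)) {
      arrays[[sprintf("gcnD%d", l)]] <- fit$par$gcnD[[l]]
      arrays[[sprintf("gcnG%d", l)]] <- fit$par$gcnG[[l]]
    }
  }
  arrays$headV <- fit$par$head$V
  arrays$headC0 <- fit$par$head$c0
  arrays$headW <- fit$par$head$w
  arrays$headB <- fit$par$head$b
  if (!is.null(fit$scaling)) {
    arrays$scaleCenter <- fit$scaling$center
    arrays$scaleScale <- fit$scaling$scale
  }
  .arraysToJSON(arrays, c(fit$config, list(encoder = fit$encoder)), path)
}

#' @rdname linkmodel-io
#' @export
readLinkModel <- function(path) {
  obj <- .arraysFromJSON(path)
  meta <- obj$meta
  a <- obj$arrays
  par <- list(head = list(V = a$headV, c0 = a$headC0,
                          w = a$headW, b = a$headB))
  if (meta$encoder == "gtn") {
    par$sel <- a[grep("^sel[0-9]+$", names(a))]
    names(par$sel) <- NULL
    par$gcn <- a[grep("^gcnW[0-9]+$", names(a))]
    names(par$gcn) <- NULL
  } else {
    par$gcnD <- a[grep("^gcnD[0-9]+$", names(a))]
    par$gcnG <- a[grep("^gcnG[0-9]+$", names(a))]
    names(par$gcnD) <- names(par$gcnG) <- NULL
  }
  scaling <- NULL
  if (!is.null(a$scaleCenter))
    scaling <- list(center = a$scaleCenter, scale = a$scaleScale)
  cfg <- meta
  cfg$encoder <- NULL
  fit <- list(encoder = meta$encoder, par = par, scaling = scaling,
              config = cfg, history = data.frame())
  class(fit) <- "linkModelFit"
  fit
}
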