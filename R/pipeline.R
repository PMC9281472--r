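#' Sample negative disease-gene pairs
#'
#' For each disease carrying positives, draws `floor(ratio * k)` genes
#' uniformly without replacement from the genes not known to be associated
#' with it, so negatives are disjoint from the positives by construction.
#'
#' @param positives data.frame with columns `disease`, `gene`.
#' @param geneUniverse character vector of all candidate gene ids.
#' @param ratio negative:positive ratio (> 0), default 1.
#' @param seed integer seed.
#' @return data.frame with columns `disease`, `gene`.
#' @export
sampleNegatives <- function(positives, geneUniverse, ratio = 1, seed = 1L) {
  stopifnot(ratio > 0)
  .withSeed(seed, offset = 401L, {
    out <- lapply(split(positives$gene, positives$disease), function(g) g)
    res <- vector("list", length(out))
    diseases <- names(out)
    for (i in seq_along(out)) {
      pool <- setdiff(geneUniverse, out[[i]])
      need <- floor(ratio * length(out[[i]]))
      if (length(pool) < need)
        stop(sprintf(
          "cannot sample %d negatives for %s: only %d non-positive genes",
          need, diseases[i], length(pool)), call. = FALSE)
      drawn <- if (length(pool) == 1L) pool else sample(pool, need)
      res[[i]] <- data.frame(disease = diseases[i], gene = drawn,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, c(res, list(make.row.names = FALSE)))
  })
}

#' Build a disease-and-label stratified cross-validation split plan
#'
#' Pools the positives and negatives and deals the pairs of every
#' (disease, label) cell round-robin over the folds, starting at a random
#' offset. Stratifying by disease as well as by label matters because the
#' negatives are sampled 1:1 per disease: under plain label stratification
#' a disease whose training pairs happen to be positive-heavy necessarily
#' has negative-heavy held-out pairs (its totals are balanced), and any
#' classifier that memorizes disease identity then scores systematically
#' away from chance even on signal-free data. Dealing each disease's
#' positives and negatives evenly across folds removes that
#' complementarity while keeping folds label-balanced. Folds partition
#' all labeled pairs; no pair is in two folds.
#'
#' @param positives,negatives data.frames with columns `disease`, `gene`.
#' @param k number of folds (default 5).
#' @param ratio recorded negative:positive ratio (metadata only).
#' @param seed integer seed for the shuffles.
#' @return a [SplitPlan].
#' @export
makeSplitPlan <- function(positives, negatives, k = 5L, ratio = 1,
                          seed = 1L) {
  k <- as.integer(k)
  pos <- data.frame(disease = positives$disease, gene = positives$gene,
                    label = 1, stringsAsFactors = FALSE)
  neg <- data.frame(disease = negatives$disease, gene = negatives$gene,
                    label = 0, stringsAsFactors = FALSE)
  pairs <- rbind(pos, neg)
  .withSeed(seed, offset = 402L, {
    fold <- integer(nrow(pairs))
    strata <- split(seq_len(nrow(pairs)),
                    list(pairs$disease, pairs$label), drop = TRUE)
    for (idx in strata) {
      idx <- idx[sample.int(length(idx))]
      offset <- sample.int(k, 1L)
      fold[idx] <- (offset + seq_along(idx) - 2L) %% k + 1L
    }
    pairs$fold <- fold
  })
  new("SplitPlan", pairs = pairs, ratio = as.numeric(ratio),
      seed = as.integer(seed))
}

#' AUC and AUPR of a score vector
#'
#' AUC is computed as the normalized Mann-Whitney statistic with half
#' credit for ties (via midranks); AUPR as average precision, i.e. the
#' mean of the precision values at the rank of each positive when scores
#' are sorted decreasingly (ties broken by input position, making the
#' value deterministic).
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length with both classes present.
#' @return named numeric vector `c(auc = ..., aupr = ...)`.
#' @examples
#' evaluateScores(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))  # auc 0.75
#' @export
evaluateScores <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0L || nn == 0L)
    stop("need at least one positive and one negative label",
         call. = FALSE)
  r <- rank(scores)   # midranks give ties half credit
  auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  aupr <- sum(prec[lab == 1]) / np
  c(auc = auc, aupr = aupr)
}

## internal: stratified carve-out of a validation set from training pairs
.carveValidation <- function(pairs, frac = 0.1, seed = 1L) {
  .withSeed(seed, offset = 403L, {
    valIdx <- integer(0)
    for (lab in c(0, 1)) {
      idx <- which(pairs$label == lab)
      nVal <- max(1L, floor(frac * length(idx)))
      valIdx <- c(valIdx, sample(idx, nVal))
    }
    list(train = pairs[-valIdx, , drop = FALSE],
         val = pairs[valIdx, , drop = FALSE])
  })
}

## internal: assemble the fold graph using only training positives as
## cross-links (fold hygiene: held-out links never enter the graph)
.foldGraph <- function(diseaseAdj, geneEdges, trainPositives, geneIds) {
  assembleHeterogeneousGraph(diseaseAdj, geneEdges, trainPositives,
                             geneIds = geneIds)
}

#' Cross-validated evaluation of a reducer/encoder combination
#'
#' Runs the full pipeline on a synthetic bundle: disease similarity
#' network from the bundle's ontology, feature reduction (fitted once,
#' unsupervised), then per fold a heterogeneous graph holding only that
#' fold's training positives as cross-links, joint encoder+head training
#' with early stopping on a stratified validation carve-out, and scoring
#' of the held-out fold. AUC/AUPR are pooled over all held-out scores.
#'
#' @param bundle a [SynthBundle].
#' @param reducer `"dbn"`, `"pca"` or `"tsne"`.
#' @param encoder `"gtn"` or `"gcn"`.
#' @param splits optional [SplitPlan]; by default negatives are sampled at
#'   `negativeRatio` and a `k`-fold plan is drawn under `seed`.
#' @param tau disease-similarity threshold (default 0.3).
#' @param reducedDim target reduced dimension for dbn/pca (default 64).
#' @param k folds (default 5).
#' @param negativeRatio negative:positive ratio (default 1).
#' @param seed integer seed governing sampling, folds, initialization.
#' @param dbnEpochs DBN pretraining epochs (default 100).
#' @param fitArgs named list of overrides passed to [fitLinkModel()]
#'   (e.g. `list(epochs = 80)`).
#' @return an [EvalReport]; the per-fold table is in [foldMetrics()].
#' @export
crossValidate <- function(bundle, reducer = c("dbn", "pca", "tsne"),
                          encoder = c("gtn", "gcn"), splits = NULL,
                          tau = 0.3, reducedDim = 64L, k = 5L,
                          negativeRatio = 1, seed = 1L,
                          dbnEpochs = 100L, fitArgs = list()) {
  reducer <- match.arg(reducer)
  encoder <- match.arg(encoder)
  stopifnot(is(bundle, "SynthBundle"))

  onto <- diseaseOntology(bundle@ontologyEdges)
  dIds <- sort(rownames(bundle@truthLabels))
  gIds <- sort(colnames(bundle@truthLabels))
  dAdj <- buildDiseaseNetwork(onto, dIds, tau = tau)
  X <- reduceFeatures(bundle@mirnaDisease, bundle@mirnaGene,
                      method = reducer, dim = reducedDim, seed = seed,
                      dbnEpochs = dbnEpochs)

  if (is.null(splits)) {
    negatives <- sampleNegatives(bundle@assocEdges, gIds,
                                 ratio = negativeRatio, seed = seed)
    splits <- makeSplitPlan(bundle@assocEdges, negatives, k = k,
                            ratio = negativeRatio, seed = seed)
  }
  pairs <- splits@pairs
  folds <- sort(unique(pairs$fold))

  allScores <- numeric(nrow(pairs))
  foldTab <- data.frame(fold = integer(), auc = numeric(),
                        aupr = numeric())
  for (f in folds) {
    testIdx <- which(pairs$fold == f)
    trainAll <- pairs[-testIdx, , drop = FALSE]
    cv <- .carveValidation(trainAll, seed = seed + f)
    trainPos <- trainAll[trainAll$label == 1, c("disease", "gene")]
    g <- .foldGraph(dAdj, bundle@geneEdges, trainPos, gIds)
    fit <- do.call(fitLinkModel, c(
      list(graph = g, X = X, trainPairs = cv$train, valPairs = cv$val,
           encoder = encoder, seed = seed + 100L * f),
      fitArgs))
    sc <- predictPairs(fit, g, X, pairs[testIdx, , drop = FALSE])
    allScores[testIdx] <- sc
    m <- evaluateScores(sc, pairs$label[testIdx])
    foldTab <- rbind(foldTab,
                     data.frame(fold = f, auc = m["auc"],
                                aupr = m["aupr"], row.names = NULL))
  }
  pooled <- evaluateScores(allScores, pairs$label)
  cfg <- list(reducer = reducer, encoder = encoder, tau = tau,
              reducedDim = as.integer(reducedDim), k = as.integer(k),
              negativeRatio = negativeRatio, dbnEpochs = as.integer(dbnEpochs),
              fitArgs = fitArgs)
  new("EvalReport", method = paste0(reducer, "-", encoder),
      auc = unname(pooled["auc"]), aupr = unname(pooled["aupr"]),
      folds = foldTab, seeds = as.integer(seed),
      fingerprint = configFingerprint(cfg),
      notes = if (reducer == "tsne")
        "t-SNE reduction fitted transductively on all nodes"
      else character())
}

#' Evaluate a classical baseline on concatenated pair features
#'
#' The baselines cannot encode a network, so each labeled pair is
#' represented by the concatenation of the raw binary disease and gene
#' feature rows; the named classifier is fitted per fold and the held-out
#' scores are pooled into AUC/AUPR.
#'
#' @param method one of `"svm"` (RBF kernel), `"bp-ann"` (one-hidden-layer
#'   perceptron, 64 units), `"naive-bayes"` (Bernoulli, Laplace-smoothed)
#'   or `"random-forest"` (200 trees).
#' @param geneFeatures,diseaseFeatures [FeatureMatrix] objects.
#' @param splits a [SplitPlan].
#' @param seed integer seed (per-fold classifier randomness).
#' @return an [EvalReport].
#' @export
runBaseline <- function(method, geneFeatures, diseaseFeatures, splits,
                        seed = 1L) {
  ok <- c("svm", "bp-ann", "naive-bayes", "random-forest")
  if (!method %in% ok)
    stop("unknown baseline method '", method, "'; expected one of: ",
         paste(ok, collapse = ", "), call. = FALSE)
  pairs <- splits@pairs
  Dv <- featureValues(diseaseFeatures)
  Gv <- featureValues(geneFeatures)
  U <- cbind(Dv[match(pairs$disease, rownames(Dv)), , drop = FALSE],
             Gv[match(pairs$gene, rownames(Gv)), , drop = FALSE])
  colnames(U) <- sprintf("f%04d", seq_len(ncol(U)))
  y <- pairs$label
  folds <- sort(unique(pairs$fold))
  allScores <- numeric(nrow(pairs))
  foldTab <- data.frame(fold = integer(), auc = numeric(),
                        aupr = numeric())
  for (f in folds) {
    te <- which(pairs$fold == f)
    trn <- setdiff(seq_len(nrow(pairs)), te)
    sc <- .withSeed(seed, offset = 500L + f,
                    .fitBaseline(method, U[trn, , drop = FALSE], y[trn],
                                 U[te, , drop = FALSE]))
    allScores[te] <- sc
    m <- evaluateScores(sc, y[te])
    foldTab <- rbind(foldTab,
                     data.frame(fold = f, auc = m["auc"],
                                aupr = m["aupr"], row.names = NULL))
  }
  pooled <- evaluateScores(allScores, y)
  new("EvalReport", method = method, auc = unname(pooled["auc"]),
      aupr = unname(pooled["aupr"]), folds = foldTab,
      seeds = as.integer(seed),
      fingerprint = configFingerprint(list(method = method,
                                           seed = as.integer(seed))))
}

.fitBaseline <- function(method, Xtr, ytr, Xte) {
  switch(method,
    "svm" = {
      ## constant-column scale warnings are expected on sparse binary
      ## features and harmless
      fit <- suppressWarnings(
        e1071::svm(Xtr, factor(ytr, levels = c(0, 1)),
                   kernel = "radial", probability = TRUE))
      pr <- stats::predict(fit, Xte, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    "bp-ann" = .trainPerceptron(Xtr, ytr, Xte),
    "naive-bayes" = {
      toFac <- function(M)
        as.data.frame(lapply(as.data.frame(M),
                             function(col) factor(col, levels = c(0, 1))))
      fit <- e1071::naiveBayes(toFac(Xtr), factor(ytr, levels = c(0, 1)),
                               laplace = 1)
      stats::predict(fit, toFac(Xte), type = "raw")[, "1"]
    },
    "random-forest" = {
      fit <- randomForest::randomForest(Xtr, factor(ytr, levels = c(0, 1)),
                                        ntree = 200L)
      stats::predict(fit, Xte, type = "prob")[, "1"]
    })
}

## one-hidden-layer backprop perceptron (the BP-ANN baseline): 64 hidden
## units, logistic output, full-batch Adam on cross-entropy. Quasi-Newton
## fitters scale poorly past a few thousand weights, so the baseline uses
## plain backpropagation (which is also what the method's name promises).
.trainPerceptron <- function(Xtr, ytr, Xte, hidden = 64L, lr = 0.01,
                             epochs = 200L, decay = 1e-4) {
  nIn <- ncol(Xtr)
  par <- list(V = matrix(stats::rnorm(nIn * hidden,
                                      sd = sqrt(2 / (nIn + hidden))),
                         nIn, hidden),
              c0 = numeric(hidden),
              w = matrix(stats::rnorm(hidden, sd = 0.01), hidden, 1),
              b = 0)
  state <- .adamInit(par)
  n <- nrow(Xtr)
  for (ep in seq_len(epochs)) {
    S <- sweep(Xtr %*% par$V, 2, par$c0, "+")
    H <- .relu(S)
    p <- .sigmoid(drop(H %*% par$w) + par$b)
    dlogit <- (p - ytr) / n
    gw <- crossprod(H, dlogit)
    gb <- sum(dlogit)
    dH <- tcrossprod(dlogit, drop(par$w))
    dS <- dH * (S > 0)
    grad <- list(V = crossprod(Xtr, dS), c0 = colSums(dS), w = gw, b = gb)
    st <- .adamStep(par, grad, state, lr, wd = decay)
    par <- st$par; state <- st$state
  }
  S <- sweep(Xte %*% par$V, 2, par$c0, "+")
  drop(.sigmoid(.relu(S) %*% par$w + par$b))
}

#' Run the reducer/encoder ablation grid
#'
#' Evaluates all combinations of feature reducer (dbn, pca, t-SNE) and
#' network encoder (heterogeneous-graph transformer vs one GCN per
#' homogeneous network) on a shared split plan: 6 reports. PCA reduces to
#' the same dimension as the DBN; t-SNE to 2 (it cannot go higher
#' meaningfully) and is fitted transductively.
#'
#' @param bundle a [SynthBundle].
#' @param splits optional shared [SplitPlan] (drawn under `seed` if
#'   missing).
#' @param seed integer seed.
#' @param ... passed on to [crossValidate()] (e.g. `reducedDim`,
#'   `fitArgs`).
#' @return named list of six [EvalReport] objects, e.g. `$`dbn-gtn``.
#' @export
runAblations <- function(bundle, splits = NULL, seed = 1L, ...) {
  if (is.null(splits)) {
    gIds <- sort(colnames(bundle@truthLabels))
    negatives <- sampleNegatives(bundle@assocEdges, gIds, seed = seed)
    splits <- makeSplitPlan(bundle@assocEdges, negatives, seed = seed)
  }
  out <- list()
  for (red in c("dbn", "pca", "tsne")) {
    for (enc in c("gtn", "gcn")) {
      out[[paste0(red, "-", enc)]] <-
        crossValidate(bundle, reducer = red, encoder = enc,
                      splits = splits, seed = seed, ...)
    }
  }
  out
}

#' Rank candidate genes for a query disease
#'
#' Scores every gene not already linked to the query disease in the given
#' graph and returns them sorted by decreasing score; ties are broken by
#' gene id, making the ranking stable.
#'
#' @param fit a `linkModelFit` from [fitLinkModel()].
#' @param graph the [HeterogeneousGraph] carrying the known associations.
#' @param X reduced feature matrix in graph node order.
#' @param queryDisease a disease id present in the graph.
#' @return data.frame with columns `gene_id`, `score`, `rank`.
#' @export
rankCandidates <- function(fit, graph, X, queryDisease) {
  if (!queryDisease %in% diseaseIds(graph))
    stop("unknown disease: ", queryDisease, call. = FALSE)
  nodes <- nodeIds(graph)
  Adg <- adjacencyStack(graph)$disease_gene
  qRow <- Adg[match(queryDisease, nodes), ]
  known <- nodes[qRow > 0]
  candidates <- setdiff(geneIds(graph), known)
  if (!length(candidates))
    return(data.frame(gene_id = character(), score = numeric(),
                      rank = integer()))
  sc <- predictPairs(fit, graph, X,
                     data.frame(disease = queryDisease,
                                gene = candidates,
                                stringsAsFactors = FALSE))
  o <- order(-sc, candidates)
  data.frame(gene_id = candidates[o], score = sc[o],
             rank = seq_along(o), stringsAsFactors = FALSE)
}
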