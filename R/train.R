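## Joint training of the graph encoder and the link-prediction head by
## full-batch Adam on binary cross-entropy. The backward pass is written
## out analytically (including the path through the softmax edge-type
## selection, the meta-path product and both degree normalizations) and is
## verified against finite differences in the test suite.

## ---- forward/backward for the graph transformer encoder -----------------

## par: list(sel = list per channel (slots x T logits),
##           gcn = list of weight matrices,
##           head = list(V, c0, w, b))
.gtnForward <- function(par, stack, X, pi, pj) {
  channels <- length(par$sel)
  cache <- list(channels = vector("list", channels))
  Zs <- vector("list", channels)
  for (ch in seq_len(channels)) {
    L <- par$sel[[ch]]
    slots <- nrow(L)
    alphas <- lapply(seq_len(slots), function(s) .softmax(L[s, ]))
    Qs <- lapply(alphas, function(a) {
      Q <- a[1] * stack[[1]]
      for (t in seq_along(stack)[-1]) Q <- Q + a[t] * stack[[t]]
      Q
    })
    ## chain of normalized products C_s
    Cs <- vector("list", slots)
    Ms <- vector("list", slots)   # raw products
    rs <- vector("list", slots)   # row sums (clamped)
    act <- vector("list", slots)  # active-row masks
    Cs[[1]] <- Qs[[1]]
    if (slots > 1) {
      for (s in 2:slots) {
        M <- Cs[[s - 1]] %*% Qs[[s]]
        rraw <- rowSums(M)
        r <- pmax(rraw, .NORM_EPS)
        Ms[[s]] <- M; rs[[s]] <- r; act[[s]] <- rraw > .NORM_EPS
        Cs[[s]] <- M / r
      }
    }
    A <- Cs[[slots]]
    At <- A; diag(At) <- diag(At) + 1
    dd <- rowSums(At)
    sv <- 1 / sqrt(dd)
    P <- At * outer(sv, sv)
    ## GCN chain
    nl <- length(par$gcn)
    Hs <- vector("list", nl + 1); Hs[[1]] <- X
    Ss <- vector("list", nl); Bs <- vector("list", nl)
    for (l in seq_len(nl)) {
      Bs[[l]] <- Hs[[l]] %*% par$gcn[[l]]
      Ss[[l]] <- P %*% Bs[[l]]
      Hs[[l + 1]] <- .relu(Ss[[l]])
    }
    Zs[[ch]] <- Hs[[nl + 1]]
    cache$channels[[ch]] <- list(alphas = alphas, Qs = Qs, Cs = Cs,
                                 Ms = Ms, rs = rs, act = act, At = At,
                                 dd = dd, sv = sv, P = P, Hs = Hs,
                                 Ss = Ss, Bs = Bs)
  }
  Z <- do.call(cbind, Zs)
  hd <- .headForward(par$head, Z, pi, pj)
  c(list(Z = Z), hd, cache)
}

.headForward <- function(head, Z, pi, pj) {
  Zi <- Z[pi, , drop = FALSE]
  Zj <- Z[pj, , drop = FALSE]
  U <- cbind(Zi, Zj, Zi * Zj)
  Sh <- sweep(U %*% head$V, 2, head$c0, "+")
  Hh <- .relu(Sh)
  logit <- drop(Hh %*% head$w) + head$b
  list(U = U, Sh = Sh, Hh = Hh, logit = logit, p = .sigmoid(logit))
}

.bceLoss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

## head backward shared by both encoders; returns head grads and dZ.
## The pair representation is [z_i, z_j, z_i * z_j], so the gradient of the
## product block flows to both endpoint embeddings.
.headBackward <- function(head, fw, y, pi, pj, nNodes, embDim) {
  n <- length(y)
  dlogit <- (fw$p - y) / n
  gw <- crossprod(fw$Hh, dlogit)
  gb <- sum(dlogit)
  dHh <- tcrossprod(dlogit, drop(head$w))
  dSh <- dHh * (fw$Sh > 0)
  gV <- crossprod(fw$U, dSh)
  gc0 <- colSums(dSh)
  dU <- tcrossprod(dSh, head$V)
  Zi <- fw$U[, seq_len(embDim), drop = FALSE]
  Zj <- fw$U[, embDim + seq_len(embDim), drop = FALSE]
  dU3 <- dU[, 2L * embDim + seq_len(embDim), drop = FALSE]
  dZ <- matrix(0, nNodes, embDim)
  dZi <- dU[, seq_len(embDim), drop = FALSE] + dU3 * Zj
  dZj <- dU[, embDim + seq_len(embDim), drop = FALSE] + dU3 * Zi
  for (g in split(seq_len(n), pi))
    dZ[pi[g[1]], ] <- dZ[pi[g[1]], ] + colSums(dZi[g, , drop = FALSE])
  for (g in split(seq_len(n), pj))
    dZ[pj[g[1]], ] <- dZ[pj[g[1]], ] + colSums(dZj[g, , drop = FALSE])
  list(head = list(V = gV, c0 = gc0, w = gw, b = gb), dZ = dZ)
}

## loss + full gradient for the GTN encoder
.gtnLossGrad <- function(par, stack, X, pi, pj, y) {
  fw <- .gtnForward(par, stack, X, pi, pj)
  loss <- .bceLoss(fw$p, y)
  channels <- length(par$sel)
  width <- ncol(fw$channels[[1]]$Hs[[length(par$gcn) + 1]])
  hb <- .headBackward(par$head, fw, y, pi, pj, nrow(X), channels * width)
  gSel <- vector("list", channels)
  gGcn <- lapply(par$gcn, function(W) W * 0)
  for (ch in seq_len(channels)) {
    cc <- fw$channels[[ch]]
    dH <- hb$dZ[, (ch - 1) * width + seq_len(width), drop = FALSE]
    nl <- length(par$gcn)
    dP <- matrix(0, nrow(X), nrow(X))
    for (l in rev(seq_len(nl))) {
      dS <- dH * (cc$Ss[[l]] > 0)
      PtdS <- crossprod(cc$P, dS)
      gGcn[[l]] <- gGcn[[l]] + crossprod(cc$Hs[[l]], PtdS)
      dP <- dP + tcrossprod(dS, cc$Bs[[l]])
      dH <- tcrossprod(PtdS, par$gcn[[l]])
    }
    ## back through P = D^{-1/2} (A + I) D^{-1/2}
    GA <- dP * cc$At
    dsv <- GA %*% cc$sv + crossprod(GA, cc$sv)
    dAt <- dP * outer(cc$sv, cc$sv)
    ddd <- -0.5 * drop(dsv) * cc$dd^(-1.5)
    dAt <- dAt + ddd          # row-constant broadcast
    dC <- dAt                 # self-loop addition passes through
    ## back through the normalized-product chain
    L <- par$sel[[ch]]
    slots <- nrow(L)
    dQs <- vector("list", slots)
    for (s in rev(seq_len(slots))) {
      if (s > 1) {
        tI <- rowSums(dC * cc$Cs[[s]])
        dM <- (dC - cc$act[[s]] * tI) / cc$rs[[s]]
        dQs[[s]] <- crossprod(cc$Cs[[s - 1]], dM)
        dC <- tcrossprod(dM, cc$Qs[[s]])
      } else {
        dQs[[1]] <- dC
      }
    }
    gL <- matrix(0, slots, length(stack))
    for (s in seq_len(slots)) {
      da <- vapply(stack, function(A) sum(dQs[[s]] * A), 0)
      a <- cc$alphas[[s]]
      gL[s, ] <- a * (da - sum(a * da))
    }
    gSel[[ch]] <- gL
  }
  list(loss = loss, p = fw$p,
       grad = list(sel = gSel, gcn = gGcn, head = hb$head))
}

## ---- forward/backward for the per-homogeneous-network GCN encoder -------

## par: list(gcnD = list of W, gcnG = list of W, head)
.gcnHomoForward <- function(par, Pd, Pg, Xd, Xg, pi, pj) {
  run <- function(P, X, Ws) {
    nl <- length(Ws)
    Hs <- vector("list", nl + 1); Hs[[1]] <- X
    Ss <- vector("list", nl)
    for (l in seq_len(nl)) {
      Ss[[l]] <- P %*% (Hs[[l]] %*% Ws[[l]])
      Hs[[l + 1]] <- .relu(Ss[[l]])
    }
    list(Hs = Hs, Ss = Ss)
  }
  fd <- run(Pd, Xd, par$gcnD)
  fg <- run(Pg, Xg, par$gcnG)
  Zd <- fd$Hs[[length(par$gcnD) + 1]]
  Zg <- fg$Hs[[length(par$gcnG) + 1]]
  Ui <- Zd[pi, , drop = FALSE]
  Uj <- Zg[pj, , drop = FALSE]
  U <- cbind(Ui, Uj, Ui * Uj)
  Sh <- sweep(U %*% par$head$V, 2, par$head$c0, "+")
  Hh <- .relu(Sh)
  logit <- drop(Hh %*% par$head$w) + par$head$b
  list(fd = fd, fg = fg, Zd = Zd, Zg = Zg, U = U, Sh = Sh, Hh = Hh,
       logit = logit, p = .sigmoid(logit))
}

.gcnHomoLossGrad <- function(par, Pd, Pg, Xd, Xg, pi, pj, y) {
  fw <- .gcnHomoForward(par, Pd, Pg, Xd, Xg, pi, pj)
  loss <- .bceLoss(fw$p, y)
  n <- length(y)
  k <- ncol(fw$Zd)
  dlogit <- (fw$p - y) / n
  gw <- crossprod(fw$Hh, dlogit)
  gb <- sum(dlogit)
  dHh <- tcrossprod(dlogit, drop(par$head$w))
  dSh <- dHh * (fw$Sh > 0)
  gV <- crossprod(fw$U, dSh)
  gc0 <- colSums(dSh)
  dU <- tcrossprod(dSh, par$head$V)
  dZd <- matrix(0, nrow(Xd), k)
  dZg <- matrix(0, nrow(Xg), k)
  Ui <- fw$U[, seq_len(k), drop = FALSE]
  Uj <- fw$U[, k + seq_len(k), drop = FALSE]
  dU3 <- dU[, 2L * k + seq_len(k), drop = FALSE]
  dUd <- dU[, seq_len(k), drop = FALSE] + dU3 * Uj
  dUg <- dU[, k + seq_len(k), drop = FALSE] + dU3 * Ui
  for (g in split(seq_len(n), pi))
    dZd[pi[g[1]], ] <- dZd[pi[g[1]], ] + colSums(dUd[g, , drop = FALSE])
  for (g in split(seq_len(n), pj))
    dZg[pj[g[1]], ] <- dZg[pj[g[1]], ] + colSums(dUg[g, , drop = FALSE])
  backGcn <- function(P, fwd, Ws, dH) {
    gW <- lapply(Ws, function(W) W * 0)
    for (l in rev(seq_along(Ws))) {
      dS <- dH * (fwd$Ss[[l]] > 0)
      PtdS <- crossprod(P, dS)
      gW[[l]] <- crossprod(fwd$Hs[[l]], PtdS)
      dH <- tcrossprod(PtdS, Ws[[l]])
    }
    gW
  }
  list(loss = loss, p = fw$p,
       grad = list(gcnD = backGcn(Pd, fw$fd, par$gcnD, dZd),
                   gcnG = backGcn(Pg, fw$fg, par$gcnG, dZg),
                   head = list(V = gV, c0 = gc0, w = gw, b = gb)))
}

## ---- Adam over an arbitrarily nested parameter list ---------------------

.adamInit <- function(par) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(par), v = zero(par), t = 0L)
}

.adamStep <- function(par, grad, state, lr, wd = 0, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p))
      return(.adamRecurse(p, g, m, v, upd))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * (mh / (sqrt(vh) + eps) + wd * p), m = m, v = v)
  }
  res <- upd(par, grad, state$m, state$v)
  list(par = res$p, state = list(m = res$m, v = res$v, t = t))
}

## recursive zip over four parallel lists
.adamRecurse <- function(p, g, m, v, f) {
  out <- list(p = p, m = m, v = v)
  for (k in seq_along(p)) {
    r <- f(p[[k]], g[[k]], m[[k]], v[[k]])
    out$p[[k]] <- r$p; out$m[[k]] <- r$m; out$v[[k]] <- r$v
  }
  out
}

## ---- public trainer ------------------------------------------------------

.applyScaling <- function(X, scaling) {
  out <- sweep(X, 2, scaling$center)
  sweep(out, 2, scaling$scale, "/")
}

#' Fit the link-prediction model on a heterogeneous graph
#'
#' Jointly trains the graph encoder and the logistic head by full-batch
#' Adam on binary cross-entropy over the given labeled pairs. With
#' `encoder = "gtn"` the heterogeneous graph is encoded through learned
#' meta-path channels; with `encoder = "gcn"` the disease similarity and
#' gene interaction networks are encoded by two separate GCNs (the
#' ablation variant) and only the embeddings are concatenated at the head.
#' If validation pairs are supplied, AUPR on them is monitored every
#' `evalEvery` epochs and training stops after `patience` evaluations
#' without improvement, restoring the best parameters.
#'
#' @param graph a [HeterogeneousGraph] whose cross-links contain only
#'   training-fold positives (test links must not leak into the graph).
#' @param X reduced feature matrix over all nodes, rows in graph node
#'   order.
#' @param trainPairs data.frame with columns `disease`, `gene`, `label`.
#' @param valPairs optional data.frame of the same shape for early
#'   stopping.
#' @param encoder `"gtn"` (default) or `"gcn"`.
#' @param channels,slots,gcnWidth,gcnLayers,headHidden architecture knobs,
#'   see [gtnModel()].
#' @param lr Adam learning rate (default 0.01).
#' @param epochs maximum training epochs (default 200).
#' @param evalEvery,patience early-stopping cadence and tolerance.
#' @param weightDecay decoupled (AdamW-style) weight-decay coefficient
#'   (default 0).
#' @param standardize standardize the columns of `X` (zero mean, unit
#'   variance) before encoding; the transform is stored in the fit and
#'   re-applied by [predictPairs()] (default `TRUE`). Mean-field codes
#'   share a large common offset across nodes; removing it lets the
#'   head's product block measure correlation rather than shared level.
#' @param seed integer seed (initialization).
#' @return a list of class `linkModelFit`: `encoder`, `par`, `config`,
#'   `history` (epoch/loss/valAUPR), and for `"gtn"` a trained
#'   [GTNModel] in `$model`.
#' @export
fitLinkModel <- function(graph, X, trainPairs, valPairs = NULL,
                         encoder = c("gtn", "gcn"), channels = 2L,
                         slots = 2L, gcnWidth = 64L, gcnLayers = 1L,
                         headHidden = 64L, lr = 0.01, epochs = 200L,
                         standardize = TRUE,
                         evalEvery = 20L, patience = 4L, weightDecay = 0,
                         seed = 1L) {
  encoder <- match.arg(encoder)
  stopifnot(is(graph, "HeterogeneousGraph"))
  nodes <- nodeIds(graph)
  if (!identical(rownames(X), nodes))
    X <- X[nodes, , drop = FALSE]
  scaling <- NULL
  if (standardize) {
    scaling <- list(center = colMeans(X),
                    scale = pmax(apply(X, 2, stats::sd), 1e-8))
    X <- .applyScaling(X, scaling)
  }
  nd <- length(diseaseIds(graph))
  toIdx <- function(pairs) {
    pi <- match(pairs$disease, nodes)
    pj <- match(pairs$gene, nodes)
    if (anyNA(pi) || anyNA(pj))
      stop("pairs reference unknown nodes", call. = FALSE)
    list(pi = pi, pj = pj, y = as.numeric(pairs$label))
  }
  tr <- toIdx(trainPairs)
  va <- if (!is.null(valPairs)) toIdx(valPairs)

  if (encoder == "gtn") {
    stack <- adjacencyStack(graph)
    init <- gtnModel(length(stack), ncol(X), channels = channels,
                     slots = slots, gcnWidth = gcnWidth,
                     gcnLayers = gcnLayers, headHidden = headHidden,
                     seed = seed)
    par <- list(sel = init@selectionLogits, gcn = init@gcnWeights,
                head = init@headParams)
    lossGrad <- function(par)
      .gtnLossGrad(par, stack, X, tr$pi, tr$pj, tr$y)
    valScore <- function(par) {
      fw <- .gtnForward(par, stack, X, va$pi, va$pj)
      evaluateScores(fw$p, va$y)
    }
  } else {
    Pd <- .gcnPropagator(
      adjacencyStack(graph)$disease_disease[seq_len(nd), seq_len(nd),
                                            drop = FALSE])
    ngIdx <- nd + seq_len(length(geneIds(graph)))
    Pg <- .gcnPropagator(
      adjacencyStack(graph)$gene_gene[ngIdx, ngIdx, drop = FALSE])
    Xd <- X[seq_len(nd), , drop = FALSE]
    Xg <- X[ngIdx, , drop = FALSE]
    trD <- tr; trD$pj <- tr$pj - nd
    vaD <- if (!is.null(va)) { v <- va; v$pj <- va$pj - nd; v }
    par <- .withSeed(seed, offset = 23L, {
      glorot <- function(nin, nout)
        matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))),
               nin, nout)
      dims <- c(ncol(X), rep(gcnWidth, gcnLayers))
      mk <- function() lapply(seq_len(gcnLayers),
                              function(l) glorot(dims[l], dims[l + 1]))
      list(gcnD = mk(), gcnG = mk(),
           head = list(V = glorot(3L * gcnWidth, headHidden),
                       c0 = numeric(headHidden),
                       w = matrix(stats::rnorm(headHidden, sd = 0.01),
                                  headHidden, 1),
                       b = 0))
    })
    lossGrad <- function(par)
      .gcnHomoLossGrad(par, Pd, Pg, Xd, Xg, trD$pi, trD$pj, trD$y)
    valScore <- function(par) {
      fw <- .gcnHomoForward(par, Pd, Pg, Xd, Xg, vaD$pi, vaD$pj)
      evaluateScores(fw$p, vaD$y)
    }
  }

  state <- .adamInit(par)
  best <- list(par = par, aupr = -Inf, since = 0L)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        valAUPR = numeric())
  for (ep in seq_len(epochs)) {
    lg <- lossGrad(par)
    stepRes <- .adamStep(par, lg$grad, state, lr, wd = weightDecay)
    par <- stepRes$par; state <- stepRes$state
    valAUPR <- NA_real_
    if (!is.null(va) && (ep %% evalEvery == 0L || ep == epochs)) {
      valAUPR <- valScore(par)["aupr"]
      if (valAUPR > best$aupr + 1e-6) {
        best$par <- par; best$aupr <- valAUPR; best$since <- 0L
      } else {
        best$since <- best$since + 1L
      }
      history <- rbind(history, data.frame(epoch = ep, loss = lg$loss,
                                           valAUPR = valAUPR))
      if (best$since >= patience) break
    }
  }
  if (!is.null(va) && is.finite(best$aupr)) par <- best$par

  fit <- list(encoder = encoder, par = par, scaling = scaling,
              config = list(channels = as.integer(channels),
                            slots = as.integer(slots),
                            gcnWidth = as.integer(gcnWidth),
                            gcnLayers = as.integer(gcnLayers),
                            headHidden = as.integer(headHidden),
                            lr = lr, epochs = as.integer(epochs),
                            weightDecay = weightDecay,
                            seed = as.integer(seed)),
              history = history)
  if (encoder == "gtn") {
    model <- gtnModel(length(adjacencyStack(graph)), ncol(X),
                      channels = channels, slots = slots,
                      gcnWidth = gcnWidth, gcnLayers = gcnLayers,
                      headHidden = headHidden, seed = seed)
    model@selectionLogits <- par$sel
    model@gcnWeights <- par$gcn
    model@headParams <- par$head
    model@trained <- TRUE
    fit$model <- model
  }
  class(fit) <- "linkModelFit"
  fit
}

#' Score disease-gene pairs with a fitted link model
#'
#' @param fit a `linkModelFit` from [fitLinkModel()].
#' @param graph the [HeterogeneousGraph] to encode (its cross-links should
#'   exclude the pairs being scored when evaluating held-out data).
#' @param X reduced feature matrix in graph node order.
#' @param pairs data.frame with columns `disease`, `gene`.
#' @return numeric scores in (0, 1).
#' @export
predictPairs <- function(fit, graph, X, pairs) {
  stopifnot(inherits(fit, "linkModelFit"))
  nodes <- nodeIds(graph)
  if (!identical(rownames(X), nodes)) X <- X[nodes, , drop = FALSE]
  if (!is.null(fit$scaling)) X <- .applyScaling(X, fit$scaling)
  pi <- match(pairs$disease, nodes)
  pj <- match(pairs$gene, nodes)
  if (anyNA(pi) || anyNA(pj))
    stop("pairs reference unknown nodes", call. = FALSE)
  if (fit$encoder == "gtn") {
    fw <- .gtnForward(fit$par, adjacencyStack(graph), X, pi, pj)
    fw$p
  } else {
    nd <- length(diseaseIds(graph))
    ngIdx <- nd + seq_len(length(geneIds(graph)))
    Pd <- .gcnPropagator(
      adjacencyStack(graph)$disease_disease[seq_len(nd), seq_len(nd),
                                            drop = FALSE])
    Pg <- .gcnPropagator(
      adjacencyStack(graph)$gene_gene[ngIdx, ngIdx, drop = FALSE])
    fw <- .gcnHomoForward(fit$par, Pd, Pg,
                          X[seq_len(nd), , drop = FALSE],
                          X[ngIdx, , drop = FALSE], pi, pj - nd)
    fw$p
  }
}
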