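## Full model: intra-domain hypergraph convolution with channel attention,
## edge-aware bipartite convolution over known associations, optional
## protein-mediated attention branch, skip connection, bilinear scoring, and
## Adam training of the class-balanced cross-entropy on all pairs.

#' Model configuration
#'
#' @param k1,k2 hidden widths of the two layers (defaults 256 / 128).
#' @param lr Adam learning rate (default 0.002).
#' @param beta feature dropout rate applied to the fused embeddings of each
#'   layer during training (default 0.4).
#' @param gamma edge dropout rate applied per epoch to the association edges
#'   and the protein edge sets (default 0.1).
#' @param epochs number of full-graph training epochs.
#' @param K hypergraph neighbourhood size (default 15, clamped to Nv - 1).
#' @param ecaKernel attention kernel length (odd, default 3).
#' @param seed integer seed controlling initialization and dropout.
#' @param useHgcn hypergraph convolution for the intra-domain branch; when
#'   FALSE a plain symmetric-normalized graph convolution over the KNN graph
#'   is used instead (ablation).
#' @param useMultiviewAttention use all similarity views with channel
#'   attention; when FALSE only `initialViewIndex` is used (ablation).
#' @param useProteinBranch enable the protein-mediated branch (ignored when
#'   the network has no protein layer).
#' @param unsmoothedDrugProjection use the combined (not yet PPI-smoothed)
#'   protein embedding for the protein-to-drug back-projection, while the
#'   disease side always receives the smoothed one.
#' @param initialViewIndex which drug view seeds the initial input (default 1).
#' @param equalWidths when TRUE and k1 == k2, the skip connection is a literal
#'   sum; otherwise a learnable k1 -> k2 projection precedes it.
#' @param leakySlope negative slope of the attention leaky rectifier.
#' @param weightDecay L2 penalty coefficient on all weight matrices (default
#'   0); useful against memorization on small networks.
#' @param hiddenActivation apply the rectifier to the hidden (first-layer)
#'   intra- and inter-domain embeddings (default TRUE); with FALSE the
#'   propagation stack is linear up to the attention stages.
#' @return named list of class `modelConfig`.
#' @export
modelConfig <- function(k1 = 256, k2 = 128, lr = 0.002, beta = 0.4,
                        gamma = 0.1, epochs = 1000, K = 15, ecaKernel = 3,
                        seed = 1, useHgcn = TRUE, useMultiviewAttention = TRUE,
                        useProteinBranch = TRUE, unsmoothedDrugProjection = FALSE,
                        initialViewIndex = 1, equalWidths = FALSE,
                        leakySlope = 0.2, weightDecay = 0,
                        hiddenActivation = TRUE) {
  stopifnot(k1 >= 1, k2 >= 1, lr > 0, beta >= 0, beta < 1, gamma >= 0,
            gamma < 1, epochs >= 0, K >= 1, ecaKernel %% 2 == 1,
            weightDecay >= 0)
  if (equalWidths && k1 != k2) stop("equalWidths requires k1 == k2")
  cfg <- list(k1 = as.integer(k1), k2 = as.integer(k2), lr = lr, beta = beta,
              gamma = gamma, epochs = as.integer(epochs), K = as.integer(K),
              ecaKernel = as.integer(ecaKernel), seed = as.integer(seed),
              useHgcn = useHgcn, useMultiviewAttention = useMultiviewAttention,
              useProteinBranch = useProteinBranch, unsmoothedDrugProjection = unsmoothedDrugProjection,
              initialViewIndex = as.integer(initialViewIndex),
              equalWidths = equalWidths, leakySlope = leakySlope,
              weightDecay = weightDecay, hiddenActivation = hiddenActivation)
  class(cfg) <- "modelConfig"
  cfg
}

.gcnOperator <- function(H) {
  A <- 1 * ((H + t(H)) > 0)      # KNN graph adjacency incl. self-loops
  d <- rowSums(A)
  s <- 1 / sqrt(d)
  (s * A) * rep(s, each = nrow(A))
}

#' Precompute the training-invariant model inputs
#'
#' Builds the KNN hypergraphs of every drug view and of the disease
#' similarity, caches their normalized operators (or plain GCN operators under
#' the ablation toggle), sets the initial inputs (the incidence matrix of the
#' configured drug view and the disease incidence matrix, seeding both the
#' intra- and inter-domain branches), the protein initial profile
#' `[Arp' | Adp']`, and the protein edge index matrices.
#'
#' @param network a \linkS4class{HeteroNetwork}.
#' @param cfg a [modelConfig()].
#' @return list of precomputed inputs (class `modelPrep`).
#' @export
prepareModel <- function(network, cfg) {
  M <- nDrugs(network); N <- nDiseases(network); S <- nViews(network)
  if (cfg$initialViewIndex < 1 || cfg$initialViewIndex > S)
    stop("initialViewIndex out of range")
  viewIdx <- if (cfg$useMultiviewAttention) seq_len(S) else cfg$initialViewIndex
  drugHgs <- lapply(viewIdx, function(s)
    suppressWarnings(buildKnnHypergraph(network@drugViews@views[[s]], cfg$K)))
  diseaseHg <- suppressWarnings(buildKnnHypergraph(network@diseaseSim, cfg$K))
  opOf <- function(hg) if (cfg$useHgcn) hg@operator else .gcnOperator(hg@incidence)
  initHg <- if (cfg$useMultiviewAttention) drugHgs[[cfg$initialViewIndex]]
            else drugHgs[[1]]
  useProt <- cfg$useProteinBranch && hasProteinLayer(network)
  prep <- list(M = M, N = N, S = length(viewIdx),
               drugOps = lapply(drugHgs, opOf), diseaseOp = opOf(diseaseHg),
               Xr0 = initHg@incidence, Xd0 = diseaseHg@incidence,
               A = network@assoc@adj, useProtein = useProt,
               drugIds = drugIds(network), diseaseIds = diseaseIds(network))
  if (useProt) {
    ei <- proteinEdgeIndices(network)
    P <- nProteins(network)
    Arp <- matrix(0, M, P); Arp[ei$drugToProtein] <- 1
    Adp <- matrix(0, N, P); Adp[ei$diseaseToProtein] <- 1
    prep$P <- P
    prep$Xp0 <- cbind(t(Arp), t(Adp))   # P x (M + N) association profile
    prep$edges <- ei
  }
  class(prep) <- "modelPrep"
  prep
}

#' Initial inputs of both branches
#'
#' @param network a \linkS4class{HeteroNetwork}.
#' @param cfg a [modelConfig()].
#' @return list with `Xr0` (M x M incidence of the configured drug view) and
#'   `Xd0` (N x N disease incidence); the same matrices seed the intra- and
#'   inter-domain branches.
#' @export
initialInputs <- function(network, cfg) {
  prep <- prepareModel(network, cfg)
  list(Xr0 = prep$Xr0, Xd0 = prep$Xd0)
}

.glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

.gatParamShapes <- function(fsrc, fdst, k) {
  list(Wv = c(fsrc, k), Wu = c(fdst, k), a1 = c(k, 1), a2 = c(k, 1))
}

## deterministic parameter order; all parameters are matrices
.paramShapes <- function(prep, cfg) {
  M <- prep$M; N <- prep$N
  k1 <- cfg$k1; k2 <- cfg$k2
  sh <- list(
    th_r1 = c(M, k1), th_d1 = c(N, k1), th_r2 = c(k1, k2), th_d2 = c(k1, k2),
    wer1 = c(M, 1), wed1 = c(N, 1), wer2 = c(k1, 1), wed2 = c(k1, 1),
    Wd2r1 = c(N, k1), Wr2d1 = c(M, k1), Wd2r2 = c(k1, k2), Wr2d2 = c(k1, k2))
  if (prep$S > 1) {
    sh$eca1 <- c(cfg$ecaKernel, 1)
    sh$eca2 <- c(cfg$ecaKernel, 1)
  }
  if (!cfg$equalWidths) {
    sh$skip_r <- c(k1, k2)
    sh$skip_d <- c(k1, k2)
  }
  if (prep$useProtein) {
    fp0 <- M + N
    for (l in 1:2) {
      kin_r <- if (l == 1) M else k1
      kin_d <- if (l == 1) N else k1
      fp <- if (l == 1) fp0 else k1
      k <- if (l == 1) k1 else k2
      pre <- sprintf("g%d_", l)
      add <- function(sh, tag, s) { for (nm in names(s)) sh[[paste0(pre, tag, "_", nm)]] <- s[[nm]]; sh }
      sh <- add(sh, "rp", .gatParamShapes(kin_r, fp, k))
      sh <- add(sh, "dp", .gatParamShapes(kin_d, fp, k))
      sh[[paste0(pre, "comb")]] <- c(2 * k, k)
      sh <- add(sh, "pp", .gatParamShapes(k, k, k))
      sh <- add(sh, "pr", .gatParamShapes(k, kin_r, k))
      sh <- add(sh, "pd", .gatParamShapes(k, kin_d, k))
    }
  }
  sh
}

#' Initialize model parameters
#'
#' Glorot-uniform for all weight matrices; the attention kernels start
#' small-uniform so the channel weights begin near 0.5 (near-uniform fusion);
#' the degree-edge vectors start at a common positive value scaled by the mean
#' association degree. Uses the current RNG state (seed it for determinism).
#'
#' @param prep output of [prepareModel()].
#' @param cfg a [modelConfig()].
#' @return named list of parameter matrices.
#' @export
initParams <- function(prep, cfg) {
  sh <- .paramShapes(prep, cfg)
  meanDeg <- mean(rowSums(prep$A)) + 1
  params <- list()
  for (nm in names(sh)) {
    d <- sh[[nm]]
    params[[nm]] <- if (grepl("^eca", nm)) {
      matrix(stats::runif(d[1], -0.1, 0.1), d[1], d[2])
    } else if (grepl("^we", nm)) {
      matrix(1 / sqrt(meanDeg), d[1], d[2])
    } else .glorot(d[1], d[2])
  }
  params
}

.adGatStage <- function(srcNode, dstNode, edges, pn, prefix, nDst, slope) {
  if (nrow(edges) == 0)
    return(adConst(srcNode$tape, matrix(0, nDst, ncol(pn[[paste0(prefix, "_Wv")]]$val))))
  Hv <- adMM(srcNode, pn[[paste0(prefix, "_Wv")]])
  Hu <- adMM(dstNode, pn[[paste0(prefix, "_Wu")]])
  p <- adMM(Hu, pn[[paste0(prefix, "_a1")]])
  q <- adMM(Hv, pn[[paste0(prefix, "_a2")]])
  sc <- adAdd(adGatherRows(p, edges[, 2]), adGatherRows(q, edges[, 1]))
  al <- adSegSoftmax(adLeaky(sc, slope), edges[, 2], nDst)
  adRelu(adEdgeAgg(al, Hv, edges[, 1], edges[, 2], nDst))
}

## builds the whole forward computation on a tape; masks == NULL -> eval mode
.buildTape <- function(prep, params, cfg, masks = NULL) {
  tape <- adTape()
  pn <- list()
  for (nm in names(params)) pn[[nm]] <- adParam(tape, params[[nm]], nm)

  training <- !is.null(masks)
  A <- if (training) masks$A else prep$A
  An <- .bipartiteNorm(A)
  AnC <- adConst(tape, An)
  AnTC <- adConst(tape, t(An))
  degR <- rowSums(A); degD <- colSums(A)
  opC <- lapply(prep$drugOps, adConst, tape = tape)
  opDC <- adConst(tape, prep$diseaseOp)
  if (prep$useProtein) {
    ed <- if (training) masks$edges else prep$edges
  }

  Xr <- adConst(tape, prep$Xr0)
  Xd <- adConst(tape, prep$Xd0)
  if (prep$useProtein) Xp <- adConst(tape, prep$Xp0)
  omega <- list()
  layerOut <- list()

  for (l in 1:2) {
    # hidden layer rectified (configurable), final layer linear
    act1 <- l == 1 && isTRUE(cfg$hiddenActivation)
    thR <- pn[[sprintf("th_r%d", l)]]; thD <- pn[[sprintf("th_d%d", l)]]
    chans <- lapply(opC, function(op) {
      h <- adMM(adMM(op, Xr), thR)
      if (act1) adRelu(h) else h
    })
    if (prep$S > 1) {
      w <- adSigmoid(adConv1d(adGap(chans), pn[[sprintf("eca%d", l)]]))
      XintraR <- adChanFuse(chans, w)
      omega[[l]] <- drop(w$val)
    } else {
      XintraR <- chans[[1]]
      omega[[l]] <- 1
    }
    hD <- adMM(adMM(opDC, Xd), thD)
    XintraD <- if (act1) adRelu(hD) else hD

    XeR <- adOuterDeg(tape, degR, pn[[sprintf("wer%d", l)]])
    XeD <- adOuterDeg(tape, degD, pn[[sprintf("wed%d", l)]])
    XinterR <- adMM(adMM(AnC, adEMul(Xd, XeD)), pn[[sprintf("Wd2r%d", l)]])
    XinterD <- adMM(adMM(AnTC, adEMul(Xr, XeR)), pn[[sprintf("Wr2d%d", l)]])
    if (act1) { XinterR <- adRelu(XinterR); XinterD <- adRelu(XinterD) }

    partsR <- list(XintraR, XinterR)
    partsD <- list(XintraD, XinterD)
    if (prep$useProtein) {
      pre <- sprintf("g%d", l)
      Erp <- .adGatStage(Xr, Xp, ed$drugToProtein, pn, paste0(pre, "_rp"),
                         prep$P, cfg$leakySlope)
      Edp <- .adGatStage(Xd, Xp, ed$diseaseToProtein, pn, paste0(pre, "_dp"),
                         prep$P, cfg$leakySlope)
      Ep <- adMM(adCbind(Erp, Edp), pn[[paste0(pre, "_comb")]])
      EpT <- .adGatStage(Ep, Ep, ed$ppi, pn, paste0(pre, "_pp"),
                         prep$P, cfg$leakySlope)
      backSrc <- if (cfg$unsmoothedDrugProjection) Ep else EpT
      Xpr <- .adGatStage(backSrc, Xr, ed$proteinToDrug, pn, paste0(pre, "_pr"),
                         prep$M, cfg$leakySlope)
      Xpd <- .adGatStage(EpT, Xd, ed$proteinToDisease, pn, paste0(pre, "_pd"),
                         prep$N, cfg$leakySlope)
      partsR <- c(partsR, list(Xpr)); partsD <- c(partsD, list(Xpd))
      Xp <- EpT
    }
    XrNew <- adAddList(partsR)
    XdNew <- adAddList(partsD)
    if (training && cfg$beta > 0) {
      XrNew <- adEMulConst(XrNew, masks$featR[[l]])
      XdNew <- adEMulConst(XdNew, masks$featD[[l]])
    }
    layerOut[[l]] <- list(r = XrNew, d = XdNew)
    Xr <- XrNew; Xd <- XdNew
  }

  skipR <- if (cfg$equalWidths) layerOut[[1]]$r
           else adMM(layerOut[[1]]$r, pn$skip_r)
  skipD <- if (cfg$equalWidths) layerOut[[1]]$d
           else adMM(layerOut[[1]]$d, pn$skip_d)
  XhatR <- adAdd(skipR, layerOut[[2]]$r)
  XhatD <- adAdd(skipD, layerOut[[2]]$d)
  logits <- adMMT(XhatR, XhatD)
  list(tape = tape, logits = logits, omega = omega,
       embedR = XhatR, embedD = XhatD)
}

#' Forward pass in evaluation mode
#'
#' Deterministic (no dropout) scoring of every drug-disease pair.
#'
#' @param network a \linkS4class{HeteroNetwork} (or a [prepareModel()] result).
#' @param params parameter list (from [initParams()] or [trainModel()]).
#' @param cfg a [modelConfig()].
#' @return list with `scores` (M x N matrix of probabilities with id
#'   dimnames), `logits`, `omega` (per-layer channel attention weights), and
#'   the final embeddings.
#' @export
modelForward <- function(network, params, cfg) {
  prep <- if (inherits(network, "modelPrep")) network
          else prepareModel(network, cfg)
  fb <- .buildTape(prep, params, cfg, masks = NULL)
  scores <- stats::plogis(fb$logits$val)
  dimnames(scores) <- list(prep$drugIds, prep$diseaseIds)
  if (anyNA(scores)) stop("NaN detected in forward pass")
  list(scores = scores, logits = fb$logits$val, omega = fb$omega,
       embedR = fb$embedR$val, embedD = fb$embedD$val)
}

#' Predicted association probabilities of a trained model
#'
#' @param network a \linkS4class{HeteroNetwork}.
#' @param fit result of [trainModel()].
#' @return M x N probability matrix with id dimnames.
#' @export
predictScores <- function(network, fit) {
  modelForward(network, fit$params, fit$cfg)$scores
}

#' Class-balanced binary cross-entropy
#'
#' `-(1/(M*N)) * (lambda * sum_pos log(s) + sum_neg log(1 - s))` with
#' `lambda = |neg| / |pos|` computed over the usable pairs; scores are clamped
#' to `[1e-12, 1 - 1e-12]` inside the logarithms.
#'
#' @param scores M x N probability matrix.
#' @param A binary M x N association matrix (or
#'   \linkS4class{AssociationMatrix}).
#' @param mask optional 0/1 matrix of usable pairs (1 = contributes to the
#'   loss); defaults to all pairs.
#' @return scalar loss; `lambda` attached as attribute.
#' @export
weightedBceLoss <- function(scores, A, mask = NULL) {
  if (is(A, "AssociationMatrix")) A <- A@adj
  if (is.null(mask)) mask <- matrix(1, nrow(A), ncol(A))
  if (!all(dim(scores) == dim(A))) stop("shape mismatch")
  s <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  npos <- sum(A == 1 & mask > 0); nneg <- sum(A == 0 & mask > 0)
  if (npos == 0) stop("no positive pairs in mask")
  lambda <- nneg / npos
  loss <- -(lambda * sum(mask * A * log(s)) +
            sum(mask * (1 - A) * log(1 - s))) / (nrow(A) * ncol(A))
  attr(loss, "lambda") <- lambda
  loss
}

.lossWeights <- function(A, mask, cfg) {
  npos <- sum(A == 1 & mask > 0); nneg <- sum(A == 0 & mask > 0)
  if (npos == 0) stop("no positive pairs in training mask")
  lambda <- nneg / npos
  w <- mask * ifelse(A == 1, lambda, 1)
  list(w = w, lambda = lambda)
}

#' Loss and parameter gradients at a parameter point
#'
#' Builds the evaluation-mode forward computation and returns the
#' class-balanced loss with its reverse-mode gradients; used for gradient
#' verification and diagnostics.
#'
#' @param network a \linkS4class{HeteroNetwork} (or `modelPrep`).
#' @param cfg a [modelConfig()].
#' @param params parameter list.
#' @param mask optional 0/1 loss mask.
#' @return list with `loss`, `grads`, `scores`.
#' @export
lossAndGradients <- function(network, cfg, params, mask = NULL) {
  prep <- if (inherits(network, "modelPrep")) network
          else prepareModel(network, cfg)
  if (is.null(mask)) mask <- matrix(1, prep$M, prep$N)
  lw <- .lossWeights(prep$A, mask, cfg)
  fb <- .buildTape(prep, params, cfg, masks = NULL)
  lossNode <- adBceLogits(fb$logits, prep$A, lw$w, 1 / (prep$M * prep$N))
  grads <- adBackward(lossNode)
  list(loss = lossNode$val, grads = grads,
       scores = stats::plogis(fb$logits$val))
}

.dropEdges <- function(edges, gamma) {
  if (nrow(edges) == 0 || gamma <= 0) return(edges)
  keep <- stats::runif(nrow(edges)) >= gamma
  edges[keep, , drop = FALSE]
}

.epochMasks <- function(prep, cfg) {
  A <- prep$A
  if (cfg$gamma > 0) {
    pos <- which(A == 1)
    drop <- pos[stats::runif(length(pos)) < cfg$gamma]
    if (length(drop)) A[drop] <- 0
  }
  masks <- list(A = A)
  if (prep$useProtein) {
    ei <- prep$edges
    dp <- .dropEdges(ei$drugToProtein, cfg$gamma)
    ddp <- .dropEdges(ei$diseaseToProtein, cfg$gamma)
    pe <- ei$ppi[seq_len(nrow(ei$ppi) / 2), , drop = FALSE]
    pe <- .dropEdges(pe, cfg$gamma)
    masks$edges <- list(drugToProtein = dp, diseaseToProtein = ddp,
                        ppi = rbind(pe, pe[, 2:1, drop = FALSE]),
                        proteinToDrug = dp[, 2:1, drop = FALSE],
                        proteinToDisease = ddp[, 2:1, drop = FALSE])
  }
  if (cfg$beta > 0) {
    fm <- function(n, k) matrix((stats::runif(n * k) >= cfg$beta) / (1 - cfg$beta), n, k)
    masks$featR <- list(fm(prep$M, cfg$k1), fm(prep$M, cfg$k2))
    masks$featD <- list(fm(prep$N, cfg$k1), fm(prep$N, cfg$k2))
  }
  masks
}

#' Train the model
#'
#' Full-graph Adam training of the class-balanced cross-entropy over all
#' usable pairs (no negative sampling). Per epoch: association and protein
#' edges are dropped independently with probability `gamma`, features of the
#' fused embeddings with probability `beta`, then one gradient step is taken.
#' All randomness (initialization and dropout) flows from `cfg$seed`, so runs
#' are reproducible.
#'
#' @param network a \linkS4class{HeteroNetwork}; its association matrix is the
#'   training adjacency.
#' @param cfg a [modelConfig()].
#' @param lossMask optional 0/1 matrix; pairs with 0 (e.g. held-out test
#'   positives) contribute nothing to the loss.
#' @param verbose print the loss every 50 epochs.
#' @return list of class `hddaFit` with `params`, `cfg`, `log` (per-epoch
#'   loss), `lambda`, `omega` (final channel attention weights).
#' @export
trainModel <- function(network, cfg, lossMask = NULL, verbose = FALSE) {
  prep <- if (inherits(network, "modelPrep")) network
          else prepareModel(network, cfg)
  if (is.null(lossMask)) lossMask <- matrix(1, prep$M, prep$N)
  lw <- .lossWeights(prep$A, lossMask, cfg)
  scale <- 1 / (prep$M * prep$N)

  set.seed(cfg$seed)
  params <- initParams(prep, cfg)
  mAdam <- lapply(params, function(p) p * 0)
  vAdam <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lossLog <- numeric(cfg$epochs)
  omega <- NULL

  for (ep in seq_len(cfg$epochs)) {
    masks <- .epochMasks(prep, cfg)
    fb <- .buildTape(prep, params, cfg, masks = masks)
    lossNode <- adBceLogits(fb$logits, prep$A, lw$w, scale)
    if (!is.finite(lossNode$val))
      stop(sprintf("training diverged at epoch %d (loss %g)", ep, lossNode$val))
    grads <- adBackward(lossNode)
    for (nm in names(params)) {
      g <- grads[[nm]]
      if (cfg$weightDecay > 0) g <- g + 2 * cfg$weightDecay * params[[nm]]
      mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * g
      vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * g^2
      mh <- mAdam[[nm]] / (1 - b1^ep)
      vh <- vAdam[[nm]] / (1 - b2^ep)
      params[[nm]] <- params[[nm]] - cfg$lr * mh / (sqrt(vh) + eps)
    }
    lossLog[ep] <- lossNode$val
    omega <- fb$omega
    if (verbose && ep %% 50 == 0)
      message(sprintf("epoch %d: loss %.6f", ep, lossNode$val))
  }
  structure(list(params = params, cfg = cfg, lambda = lw$lambda,
                 log = data.frame(epoch = seq_len(cfg$epochs), loss = lossLog),
                 omega = omega),
            class = "hddaFit")
}

#' @export
print.hddaFit <- function(x, ...) {
  cat(sprintf("hyperDDA fit: %d epochs, final loss %.6f, lambda %.2f\n",
              nrow(x$log), if (nrow(x$log)) x$log$loss[nrow(x$log)] else NA,
              x$lambda))
  invisible(x)
}

#' Rank candidate partners for a drug or disease
#'
#' Orders the candidates of the opposite domain by descending predicted
#' score, ties broken by identifier order; optionally excludes known
#' positives.
#'
#' @param scores M x N score matrix with id dimnames (from
#'   [predictScores()]).
#' @param query a drug or disease identifier present in the dimnames.
#' @param excludeKnown drop candidates already associated in `assoc`.
#' @param assoc an \linkS4class{AssociationMatrix} (required when
#'   `excludeKnown = TRUE`).
#' @return data.frame with columns `id`, `score`, in rank order.
#' @export
rankCandidates <- function(scores, query, excludeKnown = FALSE, assoc = NULL) {
  dr <- rownames(scores); di <- colnames(scores)
  if (query %in% dr) {
    v <- scores[query, ]; ids <- di
    known <- if (excludeKnown) di[associationMatrix(assoc)[query, ] == 1] else character()
  } else if (query %in% di) {
    v <- scores[, query]; ids <- dr
    known <- if (excludeKnown) dr[associationMatrix(assoc)[, query] == 1] else character()
  } else stop("unknown identifier: ", query)
  keep <- !(ids %in% known)
  v <- v[keep]; ids <- ids[keep]
  ord <- order(-v, seq_along(v))
  data.frame(id = ids[ord], score = unname(v[ord]), stringsAsFactors = FALSE)
}

#' Write a score matrix as TSV (drug rows, disease columns)
#'
#' @param scores M x N score matrix with id dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeScoreMatrix <- function(scores, path) {
  df <- cbind(drug = rownames(scores), as.data.frame(scores))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Degree-product baseline scores
#'
#' `score_ij = rowDegree_i * colDegree_j` of the training adjacency; the
#' popularity baseline any link-prediction model must beat.
#'
#' @param A binary training adjacency (matrix or
#'   \linkS4class{AssociationMatrix}).
#' @return M x N numeric matrix.
#' @export
baselineDegreeProduct <- function(A) {
  if (is(A, "AssociationMatrix")) A <- A@adj
  outer(rowSums(A), colSums(A))
}
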