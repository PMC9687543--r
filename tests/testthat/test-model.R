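test_that("initial inputs are the configured incidence matrices", {
  net <- toyNetwork(S = 3)
  cfg <- modelConfig(k1 = 6, k2 = 4, K = 1, seed = 1)
  ii <- initialInputs(net, cfg)
  expect_equal(ii$Xr0,
               incidenceMatrix(buildKnnHypergraph(net@drugViews@views[[1]], 1)))
  expect_equal(ii$Xd0,
               incidenceMatrix(buildKnnHypergraph(net@diseaseSim, 1)))
  cfg2 <- modelConfig(k1 = 6, k2 = 4, K = 1, initialViewIndex = 2)
  expect_equal(initialInputs(net, cfg2)$Xr0,
               incidenceMatrix(buildKnnHypergraph(net@drugViews@views[[2]], 1)))
  expect_error(prepareModel(net, modelConfig(initialViewIndex = 5)),
               "out of range")
  # different domain sizes give different input widths per domain
  expect_equal(dim(ii$Xr0), c(3, 3))
  expect_equal(dim(ii$Xd0), c(4, 4))
})

test_that("zero parameters score one half everywhere", {
  net <- toyNetwork()
  cfg <- modelConfig(k1 = 5, k2 = 4, K = 1, seed = 2)
  prep <- prepareModel(net, cfg)
  set.seed(2)
  pars <- initParams(prep, cfg)
  zeros <- lapply(pars, function(p) p * 0)
  fw <- modelForward(prep, zeros, cfg)
  expect_true(all(fw$scores == 0.5))
})

test_that("the class-balanced loss has its analytic fixed points and matches a loop oracle", {
  # 2x2 with one positive: lambda = 3, constant 0.5 scores
  A <- matrix(c(1, 0, 0, 0), 2, 2)
  s <- matrix(0.5, 2, 2)
  l <- weightedBceLoss(s, A)
  expect_equal(as.numeric(l), 1.5 * log(2), tolerance = 1e-12)
  expect_equal(attr(l, "lambda"), 3)

  # confident correct predictions drive the loss to zero
  sGood <- ifelse(A == 1, 1 - 1e-9, 1e-9)
  expect_lt(as.numeric(weightedBceLoss(sGood, A)), 1e-7)

  # random instances vs a per-entry scalar loop
  set.seed(4)
  for (rep in 1:25) {
    M <- 3; N <- 3
    A <- matrix(rbinom(9, 1, 0.4), M, N)
    if (sum(A) == 0) A[1, 1] <- 1
    sc <- matrix(runif(9, 0.01, 0.99), M, N)
    lam <- sum(A == 0) / sum(A == 1)
    acc <- 0
    for (i in 1:M) for (j in 1:N)
      acc <- acc - (if (A[i, j] == 1) lam * log(sc[i, j]) else log(1 - sc[i, j]))
    expect_equal(as.numeric(weightedBceLoss(sc, A)), acc / (M * N),
                 tolerance = 1e-12)
  }
  expect_error(weightedBceLoss(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               "no positive")
})

test_that("the tape-built forward equals the composition of the module functions", {
  net <- toyNetwork(S = 2)
  cfg <- modelConfig(k1 = 5, k2 = 4, K = 1, seed = 6)
  prep <- prepareModel(net, cfg)
  set.seed(6)
  pars <- initParams(prep, cfg)
  fw <- modelForward(prep, pars, cfg)

  # manual composition through hgcnLayer / attentionFuse / neegcnPass /
  # proteinMessageRound, layer by layer
  A <- net@assoc@adj
  ei <- prep$edges
  Xr <- prep$Xr0; Xd <- prep$Xd0; Xp <- prep$Xp0
  lay <- list()
  for (l in 1:2) {
    act <- l == 1
    thR <- pars[[sprintf("th_r%d", l)]]; thD <- pars[[sprintf("th_d%d", l)]]
    stack <- multiviewHgcn(
      lapply(prep$drugOps, function(op) new("Hypergraph",
        incidence = diag(nrow(op)), vertexDegrees = rep(1, nrow(op)),
        edgeDegrees = rep(1, nrow(op)), operator = op)),
      Xr, thR, activate = act)
    ab <- attentionFuse(stack, drop(pars[[sprintf("eca%d", l)]]))
    XintraR <- ab$fused
    XintraD <- hgcnLayer(prep$diseaseOp, Xd, thD, activate = act)
    XeR <- edgeToNodeFeatures(A, drop(pars[[sprintf("wer%d", l)]]), "drug")
    XeD <- edgeToNodeFeatures(A, drop(pars[[sprintf("wed%d", l)]]), "disease")
    inter <- neegcnPass(A, Xr, Xd, XeR, XeD,
                        pars[[sprintf("Wd2r%d", l)]],
                        pars[[sprintf("Wr2d%d", l)]], activate = act)
    pp <- function(tag, nm) pars[[sprintf("g%d_%s_%s", l, tag, nm)]]
    gp <- function(tag) list(Wv = pp(tag, "Wv"), Wu = pp(tag, "Wu"),
                             a1 = pp(tag, "a1"), a2 = pp(tag, "a2"),
                             slope = cfg$leakySlope)
    prot <- proteinMessageRound(
      list(drugs = Xr, diseases = Xd, proteins = Xp), ei,
      list(rp = gp("rp"), dp = gp("dp"), comb = pars[[sprintf("g%d_comb", l)]],
           pp = gp("pp"), pr = gp("pr"), pd = gp("pd")))
    Xr <- XintraR + inter$drugs + prot$drugContrib
    Xd <- XintraD + inter$diseases + prot$diseaseContrib
    Xp <- prot$proteins
    lay[[l]] <- list(r = Xr, d = Xd)
  }
  XhatR <- lay[[1]]$r %*% pars$skip_r + lay[[2]]$r
  XhatD <- lay[[1]]$d %*% pars$skip_d + lay[[2]]$d
  manual <- plogis(XhatR %*% t(XhatD))
  expect_equal(unname(fw$scores), manual, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("reverse-mode gradients match central finite differences", {
  ds <- generateDataset(synthConfig(M = 4, N = 3, P = 5, S = 2, rank = 2,
                                    density = 0.3, seed = 7))
  cfg <- modelConfig(k1 = 5, k2 = 4, K = 2, seed = 11, beta = 0, gamma = 0)
  prep <- prepareModel(ds$network, cfg)
  set.seed(11)
  pars <- initParams(prep, cfg)
  lg <- lossAndGradients(prep, cfg, pars)
  eps <- 1e-6
  set.seed(12)
  for (nm in sample(names(pars), 10)) {
    for (i in sample(length(pars[[nm]]), min(2, length(pars[[nm]])))) {
      pp <- pars; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- pars; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (lossAndGradients(prep, cfg, pp)$loss -
             lossAndGradients(prep, cfg, pm)$loss) / (2 * eps)
      an <- lg$grads[[nm]][i]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-4)
    }
  }
})

test_that("training descends, is seed-reproducible, and 0 epochs returns the initialization", {
  ds <- generateDataset(synthConfig(M = 12, N = 14, P = 15, S = 2, rank = 2,
                                    density = 0.2, seed = 3))
  cfg <- modelConfig(k1 = 8, k2 = 6, K = 3, epochs = 40, lr = 0.01,
                     beta = 0.2, gamma = 0.1, seed = 21)
  fit <- trainModel(ds$network, cfg)
  expect_lt(fit$log$loss[40], fit$log$loss[1])
  fit2 <- trainModel(ds$network, cfg)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$log, fit2$log)

  cfg0 <- modelConfig(k1 = 8, k2 = 6, K = 3, epochs = 0, seed = 21)
  fit0 <- trainModel(ds$network, cfg0)
  prep <- prepareModel(ds$network, cfg0)
  set.seed(21)
  expect_identical(fit0$params, initParams(prep, cfg0))

  # eval-mode forward is deterministic
  s1 <- predictScores(ds$network, fit)
  s2 <- predictScores(ds$network, fit)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < 1))
})

test_that("ablation toggles rewire the computation graph as advertised", {
  ds <- generateDataset(synthConfig(M = 10, N = 12, P = 12, S = 3, rank = 2,
                                    density = 0.2, seed = 5))
  cfg <- modelConfig(k1 = 6, k2 = 4, K = 2, seed = 8)
  # disabling the protein branch removes its parameters...
  cfgNoP <- modelConfig(k1 = 6, k2 = 4, K = 2, seed = 8,
                        useProteinBranch = FALSE)
  prep <- prepareModel(ds$network, cfg)
  prepNoP <- prepareModel(ds$network, cfgNoP)
  set.seed(8); p1 <- initParams(prep, cfg)
  set.seed(8); p2 <- initParams(prepNoP, cfgNoP)
  expect_true(any(grepl("^g1_", names(p1))))
  expect_false(any(grepl("^g1_", names(p2))))
  # ...and zeroing them in the full model reproduces the reduced forward
  pz <- p1
  for (nm in grep("^g[12]_", names(pz), value = TRUE)) pz[[nm]][] <- 0
  common <- names(p2)
  pz2 <- p2; for (nm in common) pz2[[nm]] <- pz[[nm]]
  expect_equal(modelForward(prepNoP, pz2, cfgNoP)$scores,
               modelForward(prep, pz, cfg)$scores, tolerance = 1e-12)

  # single-view mode drops the attention kernel and uses the configured view
  cfg1 <- modelConfig(k1 = 6, k2 = 4, K = 2, seed = 8,
                      useMultiviewAttention = FALSE, initialViewIndex = 2)
  prep1 <- prepareModel(ds$network, cfg1)
  expect_equal(prep1$S, 1)
  expect_equal(prep1$Xr0,
               incidenceMatrix(buildKnnHypergraph(ds$network@drugViews@views[[2]], 2)))
  set.seed(8)
  expect_false("eca1" %in% names(initParams(prep1, cfg1)))

  # plain graph convolution replaces the hypergraph operator on demand
  cfgG <- modelConfig(k1 = 6, k2 = 4, K = 2, seed = 8, useHgcn = FALSE)
  prepG <- prepareModel(ds$network, cfgG)
  expect_false(isTRUE(all.equal(prepG$drugOps[[1]], prep$drugOps[[1]])))
  expect_equal(prepG$drugOps[[1]], t(prepG$drugOps[[1]]))
})

test_that("candidate ranking orders by score with deterministic ties and exclusions", {
  sc <- matrix(c(0.9, 0.1, 0.5,
                 0.2, 0.8, 0.4), 3, 2,
               dimnames = list(c("d1", "d2", "d3"), c("s1", "s2")))
  r <- rankCandidates(sc, "s1")
  expect_equal(r$id, c("d1", "d3", "d2"))
  A <- AssociationMatrix(rownames(sc), colnames(sc),
                         matrix(c(1, 0, 0, 0, 0, 0), 3, 2))
  r2 <- rankCandidates(sc, "s1", excludeKnown = TRUE, assoc = A)
  expect_equal(r2$id, c("d3", "d2"))
  # all-equal scores fall back to identifier order
  scEq <- sc; scEq[] <- 0.5
  expect_equal(rankCandidates(scEq, "s2")$id, c("d1", "d2", "d3"))
  # drug query ranks diseases
  expect_equal(rankCandidates(sc, "d2")$id, c("s2", "s1"))
  expect_error(rankCandidates(sc, "zz"), "unknown")

  # score matrix TSV export round-trips
  p <- tempfile(fileext = ".tsv")
  writeScoreMatrix(sc, p)
  back <- read.table(p, header = TRUE, sep = "\t", row.names = 1)
  expect_equal(as.matrix(back), sc, ignore_attr = TRUE)
})
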