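test_that("edge features are the degree-scaled weight vector", {
  A <- matrix(c(1, 0, 1,
                0, 1, 0), 2, 3, byrow = TRUE)
  w <- c(1, 2)
  expect_equal(edgeToNodeFeatures(A, w, "drug"),
               matrix(c(2, 4, 1, 2), 2, 2, byrow = TRUE))
  expect_equal(edgeToNodeFeatures(A, w, "disease")[2, ], c(1, 2))
  # zero-degree drug and zero weight
  A0 <- rbind(A, 0)
  expect_equal(edgeToNodeFeatures(A0, w, "drug")[3, ], c(0, 0))
  expect_true(all(edgeToNodeFeatures(A, c(0, 0), "drug") == 0))
})

test_that("the edge-aware bipartite convolution matches a literal nested-loop oracle", {
  loopPass <- function(A, Xr, Xd, XeR, XeD, Wd2r, Wr2d, act) {
    M <- nrow(A); N <- ncol(A)
    dr <- rowSums(A); dd <- colSums(A)
    outR <- matrix(0, M, ncol(Wd2r)); outD <- matrix(0, N, ncol(Wr2d))
    for (i in 1:M) {
      acc <- numeric(ncol(Xd))
      for (j in 1:N) if (A[i, j] == 1)
        acc <- acc + (Xd[j, ] * XeD[j, ]) / sqrt(dd[j] * dr[i])
      for (f in seq_len(ncol(Wd2r)))
        outR[i, f] <- sum(acc * Wd2r[, f])
    }
    for (j in 1:N) {
      acc <- numeric(ncol(Xr))
      for (i in 1:M) if (A[i, j] == 1)
        acc <- acc + (Xr[i, ] * XeR[i, ]) / sqrt(dd[j] * dr[i])
      for (f in seq_len(ncol(Wr2d)))
        outD[j, f] <- sum(acc * Wr2d[, f])
    }
    if (act) { outR[outR < 0] <- 0; outD[outD < 0] <- 0 }
    list(drugs = outR, diseases = outD)
  }
  set.seed(5)
  for (rep in 1:25) {
    M <- sample(2:4, 1); N <- sample(2:4, 1); f <- 3; fo <- 2
    A <- matrix(rbinom(M * N, 1, 0.6), M, N)
    Xr <- matrix(rnorm(M * f), M, f); Xd <- matrix(rnorm(N * f), N, f)
    XeR <- edgeToNodeFeatures(A, rnorm(f), "drug")
    XeD <- edgeToNodeFeatures(A, rnorm(f), "disease")
    Wd2r <- matrix(rnorm(f * fo), f, fo); Wr2d <- matrix(rnorm(f * fo), f, fo)
    got <- neegcnPass(A, Xr, Xd, XeR, XeD, Wd2r, Wr2d)
    want <- loopPass(A, Xr, Xd, XeR, XeD, Wd2r, Wr2d, TRUE)
    expect_equal(got$drugs, want$drugs, tolerance = 1e-10)
    expect_equal(got$diseases, want$diseases, tolerance = 1e-10)
  }
})

test_that("bipartite convolution degenerate cases and GCN reduction hold", {
  # empty adjacency propagates nothing
  A0 <- matrix(0, 3, 2)
  z <- neegcnPass(A0, matrix(1, 3, 2), matrix(1, 2, 2),
                  matrix(1, 3, 2), matrix(1, 2, 2), diag(2), diag(2))
  expect_true(all(z$drugs == 0) && all(z$diseases == 0))

  # single edge, unit degrees, identity weights, all-one edge features
  A1 <- matrix(c(1, 0, 0, 0), 2, 2)
  Xr <- matrix(abs(rnorm(4)) + 0.1, 2, 2); Xd <- matrix(abs(rnorm(4)) + 0.1, 2, 2)
  ones <- matrix(1, 2, 2)
  r <- neegcnPass(A1, Xr, Xd, ones, ones, diag(2), diag(2))
  expect_equal(r$drugs[1, ], Xd[1, ])
  expect_equal(r$diseases[1, ], Xr[1, ])
  expect_equal(r$drugs[2, ], c(0, 0))

  # with unit edge features and identity projections this is plain
  # symmetric-normalized bipartite graph convolution
  set.seed(6)
  A <- matrix(rbinom(12, 1, 0.7), 3, 4)
  Xd4 <- matrix(rnorm(12), 4, 3)
  dr <- rowSums(A); dd <- colSums(A)
  gcn <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:4) if (A[i, j] == 1)
    gcn[i, ] <- gcn[i, ] + Xd4[j, ] / sqrt(dr[i] * dd[j])
  gcn[gcn < 0] <- 0
  got <- neegcnPass(A, matrix(rnorm(9), 3, 3), Xd4,
                    matrix(1, 3, 3), matrix(1, 4, 3), diag(3), diag(3))
  expect_equal(got$drugs, gcn, tolerance = 1e-12)

  # equivariance under joint permutation of drugs and diseases
  f <- 3
  Xr3 <- matrix(rnorm(9), 3, f); XeR <- edgeToNodeFeatures(A, rnorm(f), "drug")
  XeD <- edgeToNodeFeatures(A, rnorm(f), "disease")
  W1 <- matrix(rnorm(f * 2), f, 2); W2 <- matrix(rnorm(f * 2), f, 2)
  base <- neegcnPass(A, Xr3, Xd4, XeR, XeD, W1, W2)
  pr <- sample(3); pd <- sample(4)
  permd <- neegcnPass(A[pr, pd], Xr3[pr, ], Xd4[pd, ],
                      XeR[pr, ], XeD[pd, ], W1, W2)
  expect_equal(permd$drugs, base$drugs[pr, ], tolerance = 1e-12)
  expect_equal(permd$diseases, base$diseases[pd, ], tolerance = 1e-12)
})

test_that("graph attention projection matches the softmax loop oracle", {
  set.seed(7)
  for (rep in 1:25) {
    ns <- sample(3:5, 1); nd <- sample(3:5, 1); fs <- 3; fd <- 2; k <- 3
    srcX <- matrix(rnorm(ns * fs), ns, fs)
    dstX <- matrix(rnorm(nd * fd), nd, fd)
    ne <- sample(3:7, 1)
    edges <- cbind(sample(ns, ne, replace = TRUE), sample(nd, ne, replace = TRUE))
    edges <- unique(edges)
    pars <- toyGatParams(fs, fd, k, seed = rep)
    got <- gatProject(srcX, dstX, edges, pars, empty = "zero")
    want <- gatOracle(srcX, dstX, edges, pars)
    expect_equal(unname(got[seq_len(nd), ]), want, tolerance = 1e-10,
                 ignore_attr = TRUE)
    # coefficients sum to one within every updated neighbourhood
    al <- attr(got, "alpha")
    for (u in unique(edges[, 2]))
      expect_equal(sum(al[edges[, 2] == u]), 1)
  }
})

test_that("attention degenerate cases: singleton and symmetric neighbourhoods", {
  pars <- toyGatParams(2, 2, 2, seed = 3)
  srcX <- matrix(c(1, 2, -1, 0.5), 2, 2)
  dstX <- matrix(rnorm(4), 2, 2)
  # single neighbour: alpha = 1 exactly, output = relu(Wv x)
  g1 <- gatProject(srcX, dstX, cbind(1, 1), pars)
  expect_equal(attr(g1, "alpha"), 1)
  expect_equal(g1[1, ], pmax(drop(srcX[1, ] %*% pars$Wv), 0))
  expect_equal(g1[2, ], c(0, 0))
  # two identical neighbours: alpha = (1/2, 1/2)
  src2 <- rbind(srcX[1, ], srcX[1, ])
  g2 <- gatProject(src2, dstX, cbind(1:2, 1), pars)
  expect_equal(attr(g2, "alpha"), c(0.5, 0.5))
  # passthrough keeps lonely destinations when widths match
  g3 <- gatProject(srcX, dstX, cbind(1, 1), pars, empty = "passthrough")
  expect_equal(g3[2, ], dstX[2, ])
})

test_that("the protein round composes the attention stages as specified", {
  net <- toyNetwork()
  M <- nDrugs(net); N <- nDiseases(net); P <- nProteins(net)
  fr <- 3; fd <- 3; fp <- 4; k <- 3
  set.seed(9)
  state <- list(drugs = matrix(rnorm(M * fr), M, fr),
                diseases = matrix(rnorm(N * fd), N, fd),
                proteins = matrix(rnorm(P * fp), P, fp))
  pars <- list(rp = toyGatParams(fr, fp, k, 1), dp = toyGatParams(fd, fp, k, 2),
               comb = matrix(rnorm(2 * k * k), 2 * k, k),
               pp = toyGatParams(k, k, k, 3), pr = toyGatParams(k, fr, k, 4),
               pd = toyGatParams(k, fd, k, 5))
  got <- proteinMessageRound(state, net, pars)

  # stage-by-stage compositional oracle from gatProject
  ei <- proteinEdgeIndices(net)
  Erp <- gatProject(state$drugs, state$proteins, ei$drugToProtein, pars$rp)
  Edp <- gatProject(state$diseases, state$proteins, ei$diseaseToProtein, pars$dp)
  Ep <- cbind(Erp, Edp) %*% pars$comb
  EpT <- gatProject(Ep, Ep, ei$ppi, pars$pp, empty = "passthrough")
  expect_equal(got$proteins, EpT, ignore_attr = TRUE)
  expect_equal(got$drugContrib,
               gatProject(EpT, state$drugs, ei$proteinToDrug, pars$pr),
               ignore_attr = TRUE)
  expect_equal(got$diseaseContrib,
               gatProject(EpT, state$diseases, ei$proteinToDisease, pars$pd),
               ignore_attr = TRUE)

  # asymmetric variant routes the unsmoothed embedding towards drugs
  gotF <- proteinMessageRound(state, net, pars, unsmoothedDrugProjection = TRUE)
  expect_equal(gotF$drugContrib,
               gatProject(Ep, state$drugs, ei$proteinToDrug, pars$pr),
               ignore_attr = TRUE)

  # zero drug/disease embeddings give zero back-projections
  z <- state; z$drugs[] <- 0; z$diseases[] <- 0
  gz <- proteinMessageRound(z, net, pars)
  expect_true(all(gz$drugContrib == 0) && all(gz$diseaseContrib == 0))

  # a side with no edges contributes nothing to the combined embedding
  net1 <- net
  net1@diseaseProtein@edges <- net1@diseaseProtein@edges[0, ]
  g1 <- proteinMessageRound(state, net1, pars)
  Ep1 <- cbind(Erp, matrix(0, P, k)) %*% pars$comb
  ei1 <- proteinEdgeIndices(net1)
  EpT1 <- gatProject(Ep1, Ep1, ei1$ppi, pars$pp, empty = "passthrough")
  expect_equal(g1$proteins, EpT1, ignore_attr = TRUE)
})
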