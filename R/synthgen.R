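## Synthetic heterogeneous networks with planted low-rank structure.
## Associations follow a logistic low-rank model A_ij ~ Bernoulli(logistic(U V' + b));
## similarity views are noisy logistic transforms of the drug-factor correlation
## kernel; protein links are drawn with probability increasing in the
## entity-factor / protein-direction score. Everything is a deterministic
## function of the seed.

#' Configuration for the synthetic-network generator
#'
#' @param M,N,P drug / disease / protein counts (P ignored unless the protein
#'   layer is enabled).
#' @param S number of drug similarity views.
#' @param rank latent dimension of the planted factors (<= min(M, N)).
#' @param density target positive fraction of the association matrix, in (0,1).
#' @param viewNoise standard deviation of the Gaussian noise added to the
#'   similarity kernel per view (0 = identical noiseless views).
#' @param proteinLinkProb floor probability for protein links; set `NA` to
#'   generate a network without the protein layer.
#' @param seed integer; fully determines the generated network.
#' @return a named list of class `synthConfig`.
#' @export
synthConfig <- function(M = 60, N = 80, P = 100, S = 3, rank = 4,
                        density = 0.08, viewNoise = 0.3,
                        proteinLinkProb = 0.05, seed = 1) {
  stopifnot(M >= 2, N >= 2, S >= 1, rank >= 1, rank <= min(M, N),
            density > 0, density < 1, viewNoise >= 0)
  cfg <- list(M = as.integer(M), N = as.integer(N), P = as.integer(P),
              S = as.integer(S), rank = as.integer(rank), density = density,
              viewNoise = viewNoise, proteinLinkProb = proteinLinkProb,
              seed = as.integer(seed))
  class(cfg) <- "synthConfig"
  cfg
}

#' Draw the planted latent factors and association probabilities
#'
#' Drug factors U (M x rank) and disease factors V (N x rank) are standard
#' normal under the configured seed; the association probability matrix is
#' `logistic(U V' / sqrt(rank) + b)` (unit logit variance at any rank) with
#' the scalar offset `b` calibrated by bisection so the mean probability
#' matches `cfg$density` within 1e-3.
#'
#' @param cfg a [synthConfig()].
#' @return list with `U`, `V`, `fullProb`, `offset`.
#' @export
generateLatentFactors <- function(cfg) {
  set.seed(cfg$seed)
  U <- matrix(stats::rnorm(cfg$M * cfg$rank), cfg$M, cfg$rank)
  V <- matrix(stats::rnorm(cfg$N * cfg$rank), cfg$N, cfg$rank)
  # unit logit variance regardless of rank, so no row/column is starved of
  # probability mass at any latent dimension
  G <- U %*% t(V) / sqrt(cfg$rank)
  f <- function(b) mean(stats::plogis(G + b)) - cfg$density
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) stop("density calibration failed to bracket")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (abs(f(mid)) < 1e-4) break
  }
  b <- (lo + hi) / 2
  list(U = U, V = V, fullProb = stats::plogis(G + b), offset = b)
}

#' Sample a binary association matrix from planted probabilities
#'
#' Independent Bernoulli draws per pair; if any drug row or disease column is
#' all-zero the matrix is redrawn with a shifted seed (up to 100 retries).
#'
#' @param truth output of [generateLatentFactors()].
#' @param seed integer seed for the draws.
#' @param ids optional list with `drugIds`, `diseaseIds`.
#' @return an \linkS4class{AssociationMatrix}.
#' @export
generateAssociationMatrix <- function(truth, seed, ids = NULL) {
  M <- nrow(truth$fullProb); N <- ncol(truth$fullProb)
  if (is.null(ids)) ids <- list(drugIds = sprintf("DR%04d", seq_len(M)),
                                diseaseIds = sprintf("DI%04d", seq_len(N)))
  for (try in 0:100) {
    set.seed(seed + 1000L * try)
    A <- matrix(as.double(stats::runif(M * N) < truth$fullProb), M, N)
    if (all(rowSums(A) > 0) && all(colSums(A) > 0))
      return(AssociationMatrix(ids$drugIds, ids$diseaseIds, A))
  }
  stop("could not draw an association matrix without empty rows/columns in 100 retries")
}

## correlation kernel over drug factor rows, squashed to (0,1); gain 3 spreads
## correlations in (-1,1) over roughly (0.05, 0.95)
.simKernelGain <- 3

.factorKernel <- function(U) {
  C <- suppressWarnings(stats::cor(t(U)))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C
}

#' Generate noisy drug similarity views from the planted factors
#'
#' Each view is `logistic(gain * (K + E_s))` where K is the correlation kernel
#' of the drug factor rows and E_s symmetric Gaussian noise with standard
#' deviation `cfg$viewNoise`; the result is symmetrized, given unit diagonal
#' and clipped to \[0, 1\]. Views differ only by the noise realization.
#'
#' @param truth output of [generateLatentFactors()].
#' @param cfg a [synthConfig()].
#' @param ids optional drug identifier vector.
#' @return a \linkS4class{MultiViewSimilaritySet}.
#' @export
generateSimilarityViews <- function(truth, cfg, ids = NULL) {
  M <- nrow(truth$U)
  if (is.null(ids)) ids <- sprintf("DR%04d", seq_len(M))
  K <- .factorKernel(truth$U)
  set.seed(cfg$seed + 1L)
  views <- vector("list", cfg$S)
  for (s in seq_len(cfg$S)) {
    E <- matrix(stats::rnorm(M * M, sd = 1), M, M)
    E <- (E + t(E)) / 2 * cfg$viewNoise
    P <- stats::plogis(.simKernelGain * (K + E))
    P <- (P + t(P)) / 2
    diag(P) <- 1
    P[P < 0] <- 0; P[P > 1] <- 1
    views[[s]] <- new("SimilarityView", ids = ids, sim = P)
  }
  MultiViewSimilaritySet(views)
}

#' Noiseless similarity kernel for a factor matrix
#'
#' The deterministic kernel a zero-noise view equals: the logistic-squashed
#' factor-row correlation with unit diagonal. Exposed so tests can compare a
#' generated view against a direct kernel evaluation.
#'
#' @param U factor matrix (rows = entities).
#' @return square matrix in \[0, 1\].
#' @export
similarityKernel <- function(U) {
  P <- stats::plogis(.simKernelGain * .factorKernel(U))
  diag(P) <- 1
  P
}

#' Generate the protein layer (drug-protein, disease-protein, PPI)
#'
#' Each protein gets a unit latent direction; a drug (disease) links to a
#' protein with probability `max(proteinLinkProb, logistic(1.5 * score - 4))`
#' where score is the entity factor row dotted with the protein direction.
#' PPI edges between proteins are drawn with probability
#' `logistic(6 * cosine - 5)`; isolated proteins are resampled up to 10 times
#' then attached to their most-similar partner.
#'
#' @param truth output of [generateLatentFactors()].
#' @param cfg a [synthConfig()].
#' @param ids optional list with `drugIds`, `diseaseIds`, `proteinIds`.
#' @return list with `drugProtein`, `diseaseProtein`, `ppi`.
#' @export
generateProteinLayer <- function(truth, cfg, ids = NULL) {
  M <- nrow(truth$U); N <- nrow(truth$V); P <- cfg$P
  if (P < cfg$rank) stop("need at least `rank` proteins")
  if (is.null(ids)) ids <- list(drugIds = sprintf("DR%04d", seq_len(M)),
                                diseaseIds = sprintf("DI%04d", seq_len(N)),
                                proteinIds = sprintf("PR%04d", seq_len(P)))
  set.seed(cfg$seed + 2L)
  D <- matrix(stats::rnorm(P * cfg$rank), P, cfg$rank)
  D <- D / sqrt(rowSums(D^2))
  plp <- cfg$proteinLinkProb

  linkProb <- function(score) pmax(plp, stats::plogis(1.5 * score - 4))
  drawBip <- function(score, srcIds) {
    pr <- linkProb(score)
    draw <- matrix(stats::runif(length(pr)) < pr, nrow(score), ncol(score))
    hit <- which(draw, arr.ind = TRUE)
    data.frame(source = srcIds[hit[, 1]], target = ids$proteinIds[hit[, 2]],
               stringsAsFactors = FALSE)
  }
  dpEdges <- drawBip(truth$U %*% t(D), ids$drugIds)
  ddEdges <- drawBip(truth$V %*% t(D), ids$diseaseIds)

  Tm <- D %*% t(D)
  ppiProb <- stats::plogis(6 * Tm - 5)
  Adj <- matrix(FALSE, P, P)
  up <- upper.tri(Adj)
  Adj[up] <- stats::runif(sum(up)) < ppiProb[up]
  Adj <- Adj | t(Adj)
  for (i in seq_len(P)) {
    tries <- 0
    while (sum(Adj[i, ]) == 0 && tries < 10) {
      Adj[i, -i] <- stats::runif(P - 1) < ppiProb[i, -i]
      Adj[, i] <- Adj[i, ]
      tries <- tries + 1
    }
    if (sum(Adj[i, ]) == 0) {          # deterministic fallback: nearest partner
      j <- order(Tm[i, -i], decreasing = TRUE)[1]
      j <- seq_len(P)[-i][j]
      Adj[i, j] <- Adj[j, i] <- TRUE
    }
  }
  hit <- which(Adj & up, arr.ind = TRUE)
  ppiDf <- data.frame(source = ids$proteinIds[hit[, 1]],
                      target = ids$proteinIds[hit[, 2]], stringsAsFactors = FALSE)

  list(drugProtein = new("BipartiteEdgeList", sourceDomain = "drug",
                         targetDomain = "protein", edges = dpEdges),
       diseaseProtein = new("BipartiteEdgeList", sourceDomain = "disease",
                            targetDomain = "protein", edges = ddEdges),
       ppi = PPINetwork(ids$proteinIds, ppiDf))
}

#' Generate a complete synthetic heterogeneous network
#'
#' Composes the factor, association, similarity-view and protein-layer
#' generators and assembles them through [assembleNetwork()], so the result
#' satisfies every network invariant. Set `proteinLinkProb = NA` in the config
#' for a network without the protein layer.
#'
#' @param cfg a [synthConfig()].
#' @return list with `network` (\linkS4class{HeteroNetwork}) and `truth`
#'   (planted factors and probabilities, for scoring recovery).
#' @export
generateDataset <- function(cfg) {
  truth <- generateLatentFactors(cfg)
  ids <- list(drugIds = sprintf("DR%04d", seq_len(cfg$M)),
              diseaseIds = sprintf("DI%04d", seq_len(cfg$N)),
              proteinIds = sprintf("PR%04d", seq_len(cfg$P)))
  assoc <- generateAssociationMatrix(truth, cfg$seed + 10L, ids)
  views <- generateSimilarityViews(truth, cfg, ids$drugIds)
  diseaseK <- similarityKernel(truth$V)
  diseaseSim <- new("SimilarityView", ids = ids$diseaseIds, sim = diseaseK)
  if (!is.na(cfg$proteinLinkProb)) {
    prot <- generateProteinLayer(truth, cfg, ids)
    net <- assembleNetwork(views, diseaseSim, assoc,
                           prot$drugProtein, prot$diseaseProtein, prot$ppi)
  } else {
    net <- assembleNetwork(views, diseaseSim, assoc)
  }
  list(network = net, truth = truth)
}
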