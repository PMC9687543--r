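## Inter-domain propagation, plain-matrix implementations:
## - edge-aware bipartite graph convolution over known drug-disease
##   associations (node embeddings combined elementwise with degree-derived
##   edge embeddings, symmetric GCN normalization, cross-domain projection);
## - single-head graph attention projection between entity domains, used by
##   the protein-mediated message-passing round.

#' Degree-scaled edge features mapped onto nodes
#'
#' Maps the association edges into the node domain: drug i receives
#' `rowSum_i(A) * w`, disease j receives `colSum_j(A) * w`, with `w` a
#' learnable length-F vector per domain.
#'
#' @param A binary M x N association matrix (or \linkS4class{AssociationMatrix}).
#' @param w numeric length-F weight vector.
#' @param axis `"drug"` (rows) or `"disease"` (columns).
#' @return M x F (or N x F) matrix.
#' @export
edgeToNodeFeatures <- function(A, w, axis = c("drug", "disease")) {
  axis <- match.arg(axis)
  if (is(A, "AssociationMatrix")) A <- A@adj
  deg <- if (axis == "drug") rowSums(A) else colSums(A)
  outer(deg, as.numeric(w))
}

.bipartiteNorm <- function(A) {
  dr <- rowSums(A); dd <- colSums(A)
  sr <- ifelse(dr > 0, 1 / sqrt(dr), 0)
  sd_ <- ifelse(dd > 0, 1 / sqrt(dd), 0)
  (sr * A) * rep(sd_, each = nrow(A))
}

#' Edge-aware bipartite graph convolution over the association network
#'
#' One propagation layer:
#' `Xr_out[i] = act( sum_j A_ij / sqrt(|N_i||N_j|) * (Xd[j] * XedgeD[j]) %*% Wd2r )`
#' and symmetrically for diseases; `*` is the elementwise product and the
#' activation is the rectifier (disable with `activate = FALSE`). Nodes with
#' no inter-domain neighbours receive the zero vector.
#'
#' @param A binary M x N association matrix.
#' @param Xr,Xd drug (M x Fr) and disease (N x Fd) embeddings.
#' @param XedgeR,XedgeD edge features from [edgeToNodeFeatures()] (same widths
#'   as `Xr` / `Xd`).
#' @param Wd2r Fd x Fout projection (disease -> drug).
#' @param Wr2d Fr x Fout projection (drug -> disease).
#' @param activate apply the rectifier?
#' @return list with `drugs` (M x Fout) and `diseases` (N x Fout).
#' @export
neegcnPass <- function(A, Xr, Xd, XedgeR, XedgeD, Wd2r, Wr2d, activate = TRUE) {
  if (is(A, "AssociationMatrix")) A <- A@adj
  An <- .bipartiteNorm(A)
  out_r <- An %*% (Xd * XedgeD) %*% Wd2r
  out_d <- t(An) %*% (Xr * XedgeR) %*% Wr2d
  if (activate) { out_r[out_r < 0] <- 0; out_d[out_d < 0] <- 0 }
  list(drugs = out_r, diseases = out_d)
}

#' Single-head graph attention projection between two node sets
#'
#' For each destination node u with source neighbours `N_u`, attention
#' coefficients are a softmax over `leakyrelu(a' [Wu x_u || Wv x_v])` and the
#' output is `relu(sum_v alpha_uv Wv x_v)`. Destinations with no source
#' neighbour either keep their input row (`empty = "passthrough"`, requires
#' matching widths) or receive zeros (`empty = "zero"`).
#'
#' @param srcX source features (Ns x Fs).
#' @param dstX destination features (Nd x Fd).
#' @param edges integer matrix with columns (source index, destination index).
#' @param params list with `Wv` (Fs x k), `Wu` (Fd x k), `a1`, `a2` (k x 1
#'   halves of the length-2k attention vector), optional `slope` (leaky slope,
#'   default 0.2).
#' @param empty behaviour for destinations without neighbours.
#' @param activate apply the final rectifier?
#' @return Nd x k matrix; attention coefficients attached as attribute
#'   `"alpha"` (per edge, in input edge order).
#' @export
gatProject <- function(srcX, dstX, edges, params,
                       empty = c("zero", "passthrough"), activate = TRUE) {
  empty <- match.arg(empty)
  slope <- if (is.null(params$slope)) 0.2 else params$slope
  nDst <- nrow(dstX)
  k <- ncol(params$Wv)
  if (nrow(edges) == 0) {
    out <- matrix(0, nDst, k)
    if (empty == "passthrough") {
      if (ncol(dstX) != k) stop("passthrough needs matching widths")
      out <- dstX
    }
    attr(out, "alpha") <- numeric(0)
    return(out)
  }
  Hv <- srcX %*% params$Wv
  Hu <- dstX %*% params$Wu
  p <- drop(Hu %*% params$a1)
  q <- drop(Hv %*% params$a2)
  s <- p[edges[, 2]] + q[edges[, 1]]
  s <- ifelse(s >= 0, s, slope * s)
  ex <- exp(s - .segMax(s, edges[, 2]))
  denom <- .segSumVec(ex, edges[, 2], nDst)
  alpha <- ex / denom[edges[, 2]]
  out <- matrix(0, nDst, k)
  rs <- rowsum(alpha * Hv[edges[, 1], , drop = FALSE], edges[, 2])
  out[as.integer(rownames(rs)), ] <- rs
  if (activate) out[out < 0] <- 0
  if (empty == "passthrough") {
    lonely <- setdiff(seq_len(nDst), unique(edges[, 2]))
    if (length(lonely)) {
      if (ncol(dstX) != k) stop("passthrough needs matching widths")
      out[lonely, ] <- dstX[lonely, , drop = FALSE]
    }
  }
  attr(out, "alpha") <- alpha
  out
}

#' Resolve the directed edge index matrices of a network's protein layer
#'
#' @param net a \linkS4class{HeteroNetwork} with the protein layer.
#' @return list of integer edge matrices `drugToProtein`, `diseaseToProtein`,
#'   `ppi` (both directions), plus the reversed bipartite lists.
#' @export
proteinEdgeIndices <- function(net) {
  if (!hasProteinLayer(net)) stop("network has no protein layer")
  pid <- proteinIds(net)
  dp <- cbind(match(net@drugProtein@edges$source, drugIds(net)),
              match(net@drugProtein@edges$target, pid))
  ddp <- cbind(match(net@diseaseProtein@edges$source, diseaseIds(net)),
               match(net@diseaseProtein@edges$target, pid))
  pe <- cbind(match(net@ppi@edges$source, pid), match(net@ppi@edges$target, pid))
  ppi <- rbind(pe, pe[, 2:1, drop = FALSE])
  list(drugToProtein = dp, diseaseToProtein = ddp, ppi = ppi,
       proteinToDrug = dp[, 2:1, drop = FALSE],
       proteinToDisease = ddp[, 2:1, drop = FALSE])
}

#' One protein-mediated message-passing round
#'
#' Drug and disease embeddings are projected onto proteins by graph attention,
#' combined by feature concatenation plus a learnable 2k -> k projection,
#' smoothed over the PPI network by one further attention layer, and projected
#' back to the drug and disease domains. Proteins with links on only one side
#' contribute via that side alone; by default the PPI-smoothed embedding is
#' used for both back-projections (`unsmoothedDrugProjection = TRUE` uses the unsmoothed
#' protein embedding for the protein-to-drug projection).
#'
#' @param state list with `drugs` (M x Fr), `diseases` (N x Fd), `proteins`
#'   (P x Fp) current embeddings.
#' @param net a \linkS4class{HeteroNetwork} with the protein layer (or a
#'   precomputed [proteinEdgeIndices()] list).
#' @param params list with GAT parameter lists `rp`, `dp`, `pp`, `pr`, `pd`
#'   (each as in [gatProject()]) and `comb` (2k x k combination projection).
#' @param unsmoothedDrugProjection use the unsmoothed protein embedding for the
#'   protein-to-drug projection.
#' @return list with `drugContrib` (M x k), `diseaseContrib` (N x k),
#'   `proteins` (P x k, PPI-smoothed).
#' @export
proteinMessageRound <- function(state, net, params, unsmoothedDrugProjection = FALSE) {
  ei <- if (is(net, "HeteroNetwork")) proteinEdgeIndices(net) else net
  P <- nrow(state$proteins)
  Erp <- gatProject(state$drugs, state$proteins, ei$drugToProtein, params$rp,
                    empty = "zero")
  Edp <- gatProject(state$diseases, state$proteins, ei$diseaseToProtein,
                    params$dp, empty = "zero")
  Ep <- cbind(Erp, Edp) %*% params$comb
  EpT <- gatProject(Ep, Ep, ei$ppi, params$pp, empty = "passthrough")
  back <- if (unsmoothedDrugProjection) Ep else EpT
  Xpr <- gatProject(back, state$drugs, ei$proteinToDrug, params$pr, empty = "zero")
  Xpd <- gatProject(EpT, state$diseases, ei$proteinToDisease, params$pd,
                    empty = "zero")
  list(drugContrib = Xpr, diseaseContrib = Xpd, proteins = EpT)
}
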