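## KNN hypergraph construction and normalized hypergraph convolution.
## One hyperedge per vertex: hyperedge e_v contains v plus its K most similar
## other vertices, so the incidence matrix is square (Nv x Nv) and every
## hyperedge has degree K + 1.

#' Build the K-nearest-neighbour hypergraph of a similarity view
#'
#' Hyperedge `e_v` (column v of the incidence matrix) contains the central
#' vertex v and its K most-similar other vertices. Ties are broken
#' deterministically by (similarity descending, index ascending). K is clamped
#' to Nv - 1 with a warning for small graphs.
#'
#' @param sim a \linkS4class{SimilarityView} or square similarity matrix.
#' @param K number of neighbours per hyperedge (default 15).
#' @return a \linkS4class{Hypergraph} with the normalized operator cached.
#' @export
buildKnnHypergraph <- function(sim, K = 15) {
  m <- if (is(sim, "SimilarityView")) sim@sim else as.matrix(sim)
  nv <- nrow(m)
  if (K < 1) stop("K must be >= 1")
  if (K >= nv) {
    warning(sprintf("K = %d >= Nv = %d; clamping to %d", K, nv, nv - 1L))
    K <- nv - 1L
  }
  H <- matrix(0, nv, nv)
  for (v in seq_len(nv)) {
    cand <- setdiff(seq_len(nv), v)
    # order by similarity to v descending, index ascending on ties
    ord <- cand[order(-m[v, cand], cand)]
    H[c(v, ord[seq_len(K)]), v] <- 1
  }
  newHypergraph(H)
}

#' Construct a Hypergraph from an incidence matrix
#'
#' Computes vertex/hyperedge degrees and caches the normalized operator.
#'
#' @param H binary vertices x hyperedges incidence matrix.
#' @return a \linkS4class{Hypergraph}.
#' @export
newHypergraph <- function(H) {
  H <- as.matrix(H)
  dv <- rowSums(H)
  de <- colSums(H)
  if (any(dv < 1)) stop("isolated vertex (degree 0) in hypergraph")
  if (any(de < 1)) stop("empty hyperedge in hypergraph")
  sv <- 1 / sqrt(dv)
  C <- sv * H                       # D_v^{-1/2} H  (row scaling)
  op <- t(t(C) / de) %*% t(C)       # ... D_e^{-1} H^T D_v^{-1/2}
  op <- (op + t(op)) / 2            # enforce exact symmetry against fp drift
  new("Hypergraph", incidence = H, vertexDegrees = dv, edgeDegrees = de,
      operator = op)
}

#' Normalized hypergraph convolution operator
#'
#' Returns \eqn{D_v^{-1/2} H D_e^{-1} H^T D_v^{-1/2}}. The operator is
#' symmetric, its spectrum lies in \[-1, 1\], and \eqn{D_v^{1/2} 1} is an
#' exact eigenvector with eigenvalue 1.
#'
#' @param hg a \linkS4class{Hypergraph}.
#' @return Nv x Nv matrix.
#' @export
hypergraphOperator <- function(hg) hg@operator

#' One hypergraph convolution layer
#'
#' Computes `act(op %*% X %*% theta)` with no bias; `act` is the rectifier
#' when `activate = TRUE`, identity otherwise.
#'
#' @param op Nv x Nv operator matrix (from [hypergraphOperator()]).
#' @param X Nv x Fin feature matrix.
#' @param theta Fin x Fout weight matrix.
#' @param activate apply the rectifier?
#' @return Nv x Fout matrix.
#' @export
hgcnLayer <- function(op, X, theta, activate = TRUE) {
  if (ncol(op) != nrow(X)) stop("operator/feature shape mismatch")
  if (ncol(X) != nrow(theta)) stop("feature/weight shape mismatch")
  out <- op %*% X %*% theta
  if (activate) out[out < 0] <- 0
  out
}

#' Multi-view hypergraph convolution with a shared weight
#'
#' Applies [hgcnLayer()] per view with one shared weight matrix, stacking the
#' results channel-wise into an Nv x Fout x S array (the multi-channel drug
#' embedding consumed by the channel-attention fusion).
#'
#' @param hypergraphs list of \linkS4class{Hypergraph} objects with equal Nv.
#' @param X shared Nv x Fin input.
#' @param theta shared Fin x Fout weight.
#' @param activate apply the rectifier?
#' @return Nv x Fout x S array.
#' @export
multiviewHgcn <- function(hypergraphs, X, theta, activate = TRUE) {
  nv <- vapply(hypergraphs, function(h) nrow(h@incidence), integer(1))
  if (length(unique(nv)) != 1) stop("hypergraphs must share vertex count")
  S <- length(hypergraphs)
  out <- array(0, dim = c(nv[1], ncol(theta), S))
  for (s in seq_len(S))
    out[, , s] <- hgcnLayer(hypergraphs[[s]]@operator, X, theta, activate)
  out
}
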