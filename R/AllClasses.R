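#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' SimilarityView: one square similarity matrix over a set of entities
#'
#' Holds a single entity-entity similarity matrix (drugs or diseases) with
#' its identifier ordering. Valid objects are symmetric (within 1e-8), have
#' unit diagonal and values in \[0, 1\].
#'
#' @slot ids character vector of entity identifiers (row/column order).
#' @slot sim numeric square matrix of similarities.
#' @export
setClass("SimilarityView",
  representation(ids = "character", sim = "matrix"))

setValidity("SimilarityView", function(object) {
  m <- object@sim
  msgs <- character()
  if (nrow(m) != ncol(m)) msgs <- c(msgs, "similarity matrix must be square")
  if (length(object@ids) != nrow(m))
    msgs <- c(msgs, "id count must match matrix dimension")
  if (anyDuplicated(object@ids)) msgs <- c(msgs, "duplicate ids")
  if (!is.numeric(m) || anyNA(m)) msgs <- c(msgs, "non-numeric or NA entries")
  else {
    if (max(abs(m - t(m))) > 1e-8) msgs <- c(msgs, "matrix not symmetric (tol 1e-8)")
    if (any(abs(diag(m) - 1) > 1e-12)) msgs <- c(msgs, "diagonal must equal 1")
    if (min(m) < 0 || max(m) > 1) msgs <- c(msgs, "values must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' MultiViewSimilaritySet: S similarity views over one drug set
#'
#' An ordered list of \linkS4class{SimilarityView} objects that share the same
#' identifier ordering; the multi-view input of the drug intra-domain branch.
#'
#' @slot views list of SimilarityView objects (length S >= 1).
#' @export
setClass("MultiViewSimilaritySet", representation(views = "list"))

setValidity("MultiViewSimilaritySet", function(object) {
  v <- object@views
  if (length(v) < 1) return("need at least one view")
  if (!all(vapply(v, is, logical(1), "SimilarityView")))
    return("all views must be SimilarityView objects")
  ids <- v[[1]]@ids
  for (s in seq_along(v))
    if (!identical(v[[s]]@ids, ids)) return("all views must share ids and order")
  TRUE
})

#' AssociationMatrix: binary drug-disease association adjacency
#'
#' @slot drugIds,diseaseIds character identifier vectors.
#' @slot adj binary M x N matrix; \code{adj[i, j] == 1} iff drug i is known to
#'   be associated with disease j.
#' @export
setClass("AssociationMatrix",
  representation(drugIds = "character", diseaseIds = "character",
                 adj = "matrix"))

setValidity("AssociationMatrix", function(object) {
  msgs <- character()
  if (nrow(object@adj) != length(object@drugIds))
    msgs <- c(msgs, "row count must match drug ids")
  if (ncol(object@adj) != length(object@diseaseIds))
    msgs <- c(msgs, "column count must match disease ids")
  if (!all(object@adj %in% c(0, 1))) msgs <- c(msgs, "entries must be 0/1")
  if (length(msgs)) msgs else TRUE
})

#' BipartiteEdgeList: edges between two entity domains
#'
#' @slot sourceDomain,targetDomain domain labels (e.g. "drug", "protein").
#' @slot edges data.frame with character columns `source`, `target`;
#'   duplicate-free.
#' @export
setClass("BipartiteEdgeList",
  representation(sourceDomain = "character", targetDomain = "character",
                 edges = "data.frame"))

setValidity("BipartiteEdgeList", function(object) {
  e <- object@edges
  if (!all(c("source", "target") %in% names(e)))
    return("edges must have columns source, target")
  if (anyDuplicated(paste(e$source, e$target, sep = "\r")))
    return("duplicate edges")
  TRUE
})

#' PPINetwork: undirected unit-weight protein-protein interaction graph
#'
#' @slot proteinIds character protein identifiers.
#' @slot edges data.frame with columns `source`, `target` (undirected pairs,
#'   stored once with source <= target lexicographically after indexing).
#' @export
setClass("PPINetwork",
  representation(proteinIds = "character", edges = "data.frame"))

setValidity("PPINetwork", function(object) {
  e <- object@edges
  if (!all(c("source", "target") %in% names(e)))
    return("edges must have columns source, target")
  if (any(e$source == e$target)) return("self-loops not allowed")
  bad <- !(e$source %in% object@proteinIds) | !(e$target %in% object@proteinIds)
  if (any(bad)) return("edge endpoints must be protein ids")
  TRUE
})

setClassUnion("BipartiteEdgeListOrNULL", c("BipartiteEdgeList", "NULL"))
setClassUnion("PPINetworkOrNULL", c("PPINetwork", "NULL"))

#' HeteroNetwork: the assembled multi-association network
#'
#' Container for the drug multi-view similarity set, the disease similarity
#' view, the binary drug-disease association matrix, and (optionally) the
#' protein layer: drug-protein and disease-protein bipartite edge lists plus a
#' protein-protein interaction network. All members share consistent
#' identifier registries; use \code{\link{nDrugs}}, \code{\link{nDiseases}},
#' \code{\link{nProteins}} rather than reading slots.
#'
#' @slot drugViews MultiViewSimilaritySet.
#' @slot diseaseSim SimilarityView.
#' @slot assoc AssociationMatrix.
#' @slot drugProtein,diseaseProtein optional BipartiteEdgeList.
#' @slot ppi optional PPINetwork.
#' @export
setClass("HeteroNetwork",
  representation(drugViews = "MultiViewSimilaritySet",
                 diseaseSim = "SimilarityView",
                 assoc = "AssociationMatrix",
                 drugProtein = "BipartiteEdgeListOrNULL",
                 diseaseProtein = "BipartiteEdgeListOrNULL",
                 ppi = "PPINetworkOrNULL"))

setValidity("HeteroNetwork", function(object) {
  msgs <- character()
  drugIds <- object@drugViews@views[[1]]@ids
  if (!identical(object@assoc@drugIds, drugIds))
    msgs <- c(msgs, "association drug ids differ from similarity drug ids")
  if (!identical(object@assoc@diseaseIds, object@diseaseSim@ids))
    msgs <- c(msgs, "association disease ids differ from disease similarity ids")
  prot <- c(!is.null(object@drugProtein), !is.null(object@diseaseProtein),
            !is.null(object@ppi))
  if (any(prot) && !all(prot))
    msgs <- c(msgs, "protein components must be all present or all absent")
  if (all(prot)) {
    pid <- object@ppi@proteinIds
    if (!all(object@drugProtein@edges$target %in% pid))
      msgs <- c(msgs, "drug-protein targets not in protein registry")
    if (!all(object@drugProtein@edges$source %in% drugIds))
      msgs <- c(msgs, "drug-protein sources not in drug registry")
    if (!all(object@diseaseProtein@edges$target %in% pid))
      msgs <- c(msgs, "disease-protein targets not in protein registry")
    if (!all(object@diseaseProtein@edges$source %in% object@diseaseSim@ids))
      msgs <- c(msgs, "disease-protein sources not in disease registry")
  }
  if (length(msgs)) msgs else TRUE
})

#' Hypergraph: KNN hypergraph with cached normalized operator
#'
#' Incidence matrix H (vertices x hyperedges, binary), the vertex and
#' hyperedge degree vectors, and the cached normalized convolution operator
#' \eqn{D_v^{-1/2} H D_e^{-1} H^T D_v^{-1/2}}.
#'
#' @slot incidence binary Nv x Ne matrix.
#' @slot vertexDegrees,edgeDegrees numeric degree vectors.
#' @slot operator cached Nv x Nv normalized operator.
#' @export
setClass("Hypergraph",
  representation(incidence = "matrix", vertexDegrees = "numeric",
                 edgeDegrees = "numeric", operator = "matrix"))

setValidity("Hypergraph", function(object) {
  H <- object@incidence
  msgs <- character()
  if (!all(H %in% c(0, 1))) msgs <- c(msgs, "incidence entries must be 0/1")
  if (any(object@vertexDegrees < 1)) msgs <- c(msgs, "every vertex needs degree >= 1")
  if (any(object@edgeDegrees < 1)) msgs <- c(msgs, "every hyperedge needs degree >= 1")
  if (max(abs(object@operator - t(object@operator))) > 1e-10)
    msgs <- c(msgs, "operator must be symmetric within 1e-10")
  if (length(msgs)) msgs else TRUE
})

## ---- accessors ----

#' Entity counts of a HeteroNetwork
#'
#' @param x a \linkS4class{HeteroNetwork}.
#' @return integer count.
#' @export
nDrugs <- function(x) length(x@assoc@drugIds)

#' @rdname nDrugs
#' @export
nDiseases <- function(x) length(x@assoc@diseaseIds)

#' @rdname nDrugs
#' @export
nProteins <- function(x) if (is.null(x@ppi)) 0L else length(x@ppi@proteinIds)

#' @rdname nDrugs
#' @export
nViews <- function(x) length(x@drugViews@views)

#' Does the network carry the protein layer?
#'
#' @param x a \linkS4class{HeteroNetwork}.
#' @return logical.
#' @export
hasProteinLayer <- function(x) !is.null(x@ppi)

#' Identifier registries
#'
#' @param x a \linkS4class{HeteroNetwork}.
#' @return character vector of identifiers.
#' @export
drugIds <- function(x) x@assoc@drugIds

#' @rdname drugIds
#' @export
diseaseIds <- function(x) x@assoc@diseaseIds

#' @rdname drugIds
#' @export
proteinIds <- function(x) if (is.null(x@ppi)) character() else x@ppi@proteinIds

#' Association adjacency as a plain matrix
#'
#' @param x a \linkS4class{HeteroNetwork} or \linkS4class{AssociationMatrix}.
#' @return binary M x N matrix with id dimnames.
#' @export
associationMatrix <- function(x) {
  a <- if (is(x, "HeteroNetwork")) x@assoc else x
  m <- a@adj
  dimnames(m) <- list(a@drugIds, a@diseaseIds)
  m
}

#' Incidence matrix and normalized operator of a Hypergraph
#'
#' @param x a \linkS4class{Hypergraph}.
#' @return matrix.
#' @export
incidenceMatrix <- function(x) x@incidence

setMethod("show", "SimilarityView", function(object) {
  cat(sprintf("SimilarityView: %d entities, mean off-diagonal %.3f\n",
              length(object@ids),
              mean(object@sim[upper.tri(object@sim)])))
})

setMethod("show", "MultiViewSimilaritySet", function(object) {
  cat(sprintf("MultiViewSimilaritySet: %d view(s) over %d entities\n",
              length(object@views), length(object@views[[1]]@ids)))
})

setMethod("show", "AssociationMatrix", function(object) {
  cat(sprintf("AssociationMatrix: %d drugs x %d diseases, %d positives (sparsity %.4f)\n",
              nrow(object@adj), ncol(object@adj), sum(object@adj),
              computeSparsity(object)))
})

setMethod("show", "HeteroNetwork", function(object) {
  cat("HeteroNetwork\n")
  cat(sprintf("  drugs: %d (%d similarity view(s))\n", nDrugs(object), nViews(object)))
  cat(sprintf("  diseases: %d\n", nDiseases(object)))
  cat(sprintf("  known associations: %d (sparsity %.4f)\n",
              sum(object@assoc@adj), computeSparsity(object@assoc)))
  if (hasProteinLayer(object)) {
    cat(sprintf("  proteins: %d | drug-protein %d | disease-protein %d | PPI %d edges\n",
                nProteins(object), nrow(object@drugProtein@edges),
                nrow(object@diseaseProtein@edges), nrow(object@ppi@edges)))
  } else cat("  protein layer: absent\n")
})

setMethod("show", "Hypergraph", function(object) {
  cat(sprintf("Hypergraph: %d vertices, %d hyperedges, edge degree range [%d, %d]\n",
              nrow(object@incidence), ncol(object@incidence),
              min(object@edgeDegrees), max(object@edgeDegrees)))
})
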