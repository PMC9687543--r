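## Network input/output: readers for delimited similarity matrices, binary
## association matrices and edge lists; network assembly with id re-indexing;
## dataset statistics.

#' Construct a SimilarityView from ids and a matrix
#'
#' Applies the loading conventions: asymmetry up to `symTol` is repaired by
#' averaging with the transpose, the diagonal is forced to 1, and values are
#' clipped to \[0, 1\] (silently for excursions below 1e-6, with a warning up
#' to 0.01, an error beyond).
#'
#' @param ids character identifiers.
#' @param sim numeric square matrix.
#' @param symTol maximum asymmetry repaired by symmetrization (default 1e-6).
#' @return a \linkS4class{SimilarityView}.
#' @export
SimilarityView <- function(ids, sim, symTol = 1e-6) {
  sim <- as.matrix(sim)
  if (nrow(sim) != ncol(sim)) stop("similarity matrix must be square")
  if (!is.numeric(sim)) stop("non-numeric similarity entries")
  if (anyNA(sim)) stop("NA/NaN entries in similarity matrix")
  asym <- max(abs(sim - t(sim)))
  if (asym > symTol)
    stop(sprintf("similarity asymmetry %.3g exceeds tolerance %.1g; refusing to repair",
                 asym, symTol))
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  excess <- pmax(sim - 1, -sim, 0)
  mx <- max(excess)
  if (mx > 0.01)
    stop(sprintf("similarity value out of [0, 1] by %.3g; range violation", mx))
  if (mx > 1e-6)
    warning(sprintf("clipping similarity values to [0, 1] (max excursion %.3g)", mx))
  sim[sim < 0] <- 0
  sim[sim > 1] <- 1
  dimnames(sim) <- NULL
  new("SimilarityView", ids = as.character(ids), sim = sim)
}

#' @rdname SimilarityView
#' @param views list of SimilarityView objects sharing ids.
#' @export
MultiViewSimilaritySet <- function(views) {
  new("MultiViewSimilaritySet", views = views)
}

#' Construct an AssociationMatrix
#'
#' @param drugIds,diseaseIds character identifiers.
#' @param adj binary M x N matrix.
#' @return an \linkS4class{AssociationMatrix}.
#' @export
AssociationMatrix <- function(drugIds, diseaseIds, adj) {
  adj <- as.matrix(adj)
  storage.mode(adj) <- "double"
  dimnames(adj) <- NULL
  new("AssociationMatrix", drugIds = as.character(drugIds),
      diseaseIds = as.character(diseaseIds), adj = adj)
}

.readDelimMatrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  list(ids = rownames(df), m = m)
}

#' Read a similarity matrix from a delimited file
#'
#' Expects a header row of identifiers and a leading identifier column; TSV by
#' default, CSV if the file extension is `.csv`. The matrix is validated and
#' repaired per [SimilarityView()].
#'
#' @param path file path.
#' @return a \linkS4class{SimilarityView}.
#' @export
loadSimilarityMatrix <- function(path) {
  x <- .readDelimMatrix(path)
  if (nrow(x$m) != ncol(x$m)) stop("non-square similarity matrix in ", path)
  SimilarityView(x$ids, x$m)
}

#' Read a binary association matrix from a delimited file
#'
#' @param path file path (same dialect as [loadSimilarityMatrix()]).
#' @return an \linkS4class{AssociationMatrix}.
#' @export
loadAssociationMatrix <- function(path) {
  x <- .readDelimMatrix(path)
  if (!all(x$m %in% c(0, 1))) stop("association entries must be 0/1 in ", path)
  AssociationMatrix(x$ids, colnames(x$m), x$m)
}

#' Read a bipartite edge list
#'
#' Expects a TSV with header `source<TAB>target[<TAB>weight]`; any weight
#' column is ignored for bipartite lists. Duplicate edges are removed.
#'
#' @param path file path.
#' @param sourceDomain,targetDomain domain labels (e.g. "drug", "protein").
#' @return a \linkS4class{BipartiteEdgeList}.
#' @export
loadEdgeList <- function(path, sourceDomain, targetDomain) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty edge list: ", path)
  if (ncol(df) < 2) stop("malformed edge list (need >= 2 columns): ", path)
  e <- data.frame(source = as.character(df[[1]]), target = as.character(df[[2]]),
                  stringsAsFactors = FALSE)
  ndup <- nrow(e)
  e <- e[!duplicated(paste(e$source, e$target, sep = "\r")), , drop = FALSE]
  rownames(e) <- NULL
  message(sprintf("loaded %d edges (%d duplicates dropped) from %s",
                  nrow(e), ndup - nrow(e), basename(path)))
  new("BipartiteEdgeList", sourceDomain = sourceDomain,
      targetDomain = targetDomain, edges = e)
}

#' Construct a PPINetwork from an edge data frame
#'
#' Undirected unit-weight edges; self-loops are dropped with a warning and
#' reciprocal duplicates collapsed.
#'
#' @param proteinIds character protein identifiers.
#' @param edges data.frame with columns `source`, `target`.
#' @return a \linkS4class{PPINetwork}.
#' @export
PPINetwork <- function(proteinIds, edges) {
  proteinIds <- as.character(proteinIds)
  e <- data.frame(source = as.character(edges$source),
                  target = as.character(edges$target), stringsAsFactors = FALSE)
  loops <- e$source == e$target
  if (any(loops)) {
    warning(sprintf("dropping %d PPI self-loop(s)", sum(loops)))
    e <- e[!loops, , drop = FALSE]
  }
  lo <- pmin(e$source, e$target); hi <- pmax(e$source, e$target)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  e <- data.frame(source = lo[keep], target = hi[keep], stringsAsFactors = FALSE)
  rownames(e) <- NULL
  new("PPINetwork", proteinIds = proteinIds, edges = e)
}

#' Assemble the heterogeneous multi-association network
#'
#' Validates identifier consistency across all components and re-indexes every
#' later component to the identifier ordering of the first-loaded component of
#' its domain (drug order from the first similarity view, disease order from
#' the disease similarity, protein order from the PPI registry). Entities with
#' no edges are retained; a validation report counts them. Protein components
#' must be all present or all absent.
#'
#' @param drugViews a \linkS4class{MultiViewSimilaritySet} or list of views.
#' @param diseaseSim a \linkS4class{SimilarityView}.
#' @param assoc an \linkS4class{AssociationMatrix}.
#' @param drugProtein,diseaseProtein optional \linkS4class{BipartiteEdgeList}.
#' @param ppi optional \linkS4class{PPINetwork}.
#' @return a \linkS4class{HeteroNetwork}; its validation report is attached as
#'   attribute `"report"` (also retrievable with [validationReport()]).
#' @export
assembleNetwork <- function(drugViews, diseaseSim, assoc,
                            drugProtein = NULL, diseaseProtein = NULL,
                            ppi = NULL) {
  if (is.list(drugViews) && !is(drugViews, "MultiViewSimilaritySet"))
    drugViews <- MultiViewSimilaritySet(drugViews)
  prot <- c(!is.null(drugProtein), !is.null(diseaseProtein), !is.null(ppi))
  if (any(prot) && !all(prot))
    stop("protein components must be all present or all absent")

  drugOrder <- drugViews@views[[1]]@ids
  diseaseOrder <- diseaseSim@ids

  if (length(assoc@drugIds) != length(drugOrder))
    stop(sprintf("association matrix has %d drugs but similarity views have %d",
                 length(assoc@drugIds), length(drugOrder)))
  if (length(assoc@diseaseIds) != length(diseaseOrder))
    stop(sprintf("association matrix has %d diseases but disease similarity has %d",
                 length(assoc@diseaseIds), length(diseaseOrder)))
  ri <- match(drugOrder, assoc@drugIds)
  ci <- match(diseaseOrder, assoc@diseaseIds)
  if (anyNA(ri)) stop("drug ids in similarity views unresolvable in association matrix: ",
                      paste(utils::head(drugOrder[is.na(ri)], 5), collapse = ", "))
  if (anyNA(ci)) stop("disease ids in disease similarity unresolvable in association matrix: ",
                      paste(utils::head(diseaseOrder[is.na(ci)], 5), collapse = ", "))
  assoc <- AssociationMatrix(drugOrder, diseaseOrder, assoc@adj[ri, ci, drop = FALSE])
  if (sum(assoc@adj) < 1) stop("association matrix has no positive entries")

  report <- list(
    nDrugs = length(drugOrder), nDiseases = length(diseaseOrder),
    nViews = length(drugViews@views), nAssociations = sum(assoc@adj),
    sparsity = computeSparsity(assoc),
    drugsWithoutAssociation = sum(rowSums(assoc@adj) == 0),
    diseasesWithoutAssociation = sum(colSums(assoc@adj) == 0),
    warnings = character())

  if (all(prot)) {
    protOrder <- ppi@proteinIds
    checkIds <- function(el, srcIds, what) {
      bad <- setdiff(el@edges$source, srcIds)
      if (length(bad)) stop(sprintf("%s sources unresolvable: %s", what,
                                    paste(utils::head(bad, 5), collapse = ", ")))
      bad <- setdiff(el@edges$target, protOrder)
      if (length(bad)) stop(sprintf("%s targets unresolvable: %s", what,
                                    paste(utils::head(bad, 5), collapse = ", ")))
    }
    checkIds(drugProtein, drugOrder, "drug-protein")
    checkIds(diseaseProtein, diseaseOrder, "disease-protein")
    dpDeg <- table(factor(drugProtein@edges$source, levels = drugOrder))
    ddDeg <- table(factor(diseaseProtein@edges$source, levels = diseaseOrder))
    report$nProteins <- length(protOrder)
    report$drugsUnderTwoTargets <- sum(dpDeg < 2)
    report$diseasesWithoutProtein <- sum(ddDeg < 1)
    pDeg <- table(factor(c(ppi@edges$source, ppi@edges$target,
                           drugProtein@edges$target, diseaseProtein@edges$target),
                         levels = protOrder))
    report$proteinsWithoutEdge <- sum(pDeg == 0)
    if (report$drugsUnderTwoTargets > 0)
      report$warnings <- c(report$warnings,
        sprintf("%d drug(s) have fewer than 2 protein targets", report$drugsUnderTwoTargets))
    if (report$diseasesWithoutProtein > 0)
      report$warnings <- c(report$warnings,
        sprintf("%d disease(s) have no protein link", report$diseasesWithoutProtein))
  }

  net <- new("HeteroNetwork", drugViews = drugViews, diseaseSim = diseaseSim,
             assoc = assoc, drugProtein = drugProtein,
             diseaseProtein = diseaseProtein, ppi = ppi)
  attr(net, "report") <- report
  net
}

#' Validation report of an assembled network
#'
#' @param net a \linkS4class{HeteroNetwork} produced by [assembleNetwork()].
#' @return named list of counts and warnings (JSON-serializable).
#' @export
validationReport <- function(net) attr(net, "report")

#' Sparsity of an association matrix
#'
#' The ratio of known associations to all possible drug-disease pairs.
#' Returned at full precision; use `digits` for the conventional 4-decimal
#' display rounding (half-up).
#'
#' @param assoc an \linkS4class{AssociationMatrix}, a
#'   \linkS4class{HeteroNetwork}, or a plain binary matrix.
#' @param digits if non-NULL, round half-up to this many decimals.
#' @return numeric in \[0, 1\].
#' @export
computeSparsity <- function(assoc, digits = NULL) {
  m <- if (is(assoc, "HeteroNetwork")) assoc@assoc@adj
       else if (is(assoc, "AssociationMatrix")) assoc@adj
       else as.matrix(assoc)
  r <- sum(m != 0) / (nrow(m) * ncol(m))
  if (!is.null(digits)) r <- floor(r * 10^digits + 0.5) / 10^digits
  r
}

## ---- writers (simulate workflow, round-trip support) ----

.writeDelimMatrix <- function(m, rowIds, colIds, path) {
  # %.17g so doubles survive the text round trip bit-identically
  fm <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  df <- as.data.frame(fm, stringsAsFactors = FALSE)
  colnames(df) <- colIds
  df <- cbind(id = rowIds, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a HeteroNetwork to a directory of delimited files
#'
#' Writes `drug_sim_<s>.tsv` per view, `disease_sim.tsv`, `assoc.tsv`, and,
#' when the protein layer is present, `drug_protein.tsv`, `disease_protein.tsv`,
#' `ppi.tsv` and `proteins.txt`. Matrices already satisfying the invariants
#' round-trip exactly through [readNetworkDir()].
#'
#' @param net a \linkS4class{HeteroNetwork}.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeNetworkDir <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dids <- drugIds(net); sids <- diseaseIds(net)
  for (s in seq_len(nViews(net)))
    .writeDelimMatrix(net@drugViews@views[[s]]@sim, dids, dids,
                      file.path(dir, sprintf("drug_sim_%d.tsv", s)))
  .writeDelimMatrix(net@diseaseSim@sim, sids, sids, file.path(dir, "disease_sim.tsv"))
  .writeDelimMatrix(net@assoc@adj, dids, sids, file.path(dir, "assoc.tsv"))
  if (hasProteinLayer(net)) {
    writeEdges <- function(e, path) utils::write.table(
      data.frame(source = e$source, target = e$target), path,
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeEdges(net@drugProtein@edges, file.path(dir, "drug_protein.tsv"))
    writeEdges(net@diseaseProtein@edges, file.path(dir, "disease_protein.tsv"))
    writeEdges(net@ppi@edges, file.path(dir, "ppi.tsv"))
    writeLines(proteinIds(net), file.path(dir, "proteins.txt"))
  }
  invisible(dir)
}

#' Read a HeteroNetwork from a directory written by [writeNetworkDir()]
#'
#' @param dir directory path.
#' @return a \linkS4class{HeteroNetwork}.
#' @export
readNetworkDir <- function(dir) {
  simFiles <- sort(list.files(dir, "^drug_sim_[0-9]+\\.tsv$", full.names = TRUE))
  if (!length(simFiles)) stop("no drug similarity views found in ", dir)
  ord <- order(as.integer(sub("^drug_sim_([0-9]+)\\.tsv$", "\\1", basename(simFiles))))
  views <- lapply(simFiles[ord], loadSimilarityMatrix)
  diseaseSim <- loadSimilarityMatrix(file.path(dir, "disease_sim.tsv"))
  assoc <- loadAssociationMatrix(file.path(dir, "assoc.tsv"))
  dp <- file.path(dir, "drug_protein.tsv")
  if (file.exists(dp)) {
    drugProtein <- suppressMessages(loadEdgeList(dp, "drug", "protein"))
    diseaseProtein <- suppressMessages(
      loadEdgeList(file.path(dir, "disease_protein.tsv"), "disease", "protein"))
    ppiDf <- utils::read.table(file.path(dir, "ppi.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
    ppi <- PPINetwork(readLines(file.path(dir, "proteins.txt")), ppiDf)
    assembleNetwork(views, diseaseSim, assoc, drugProtein, diseaseProtein, ppi)
  } else assembleNetwork(views, diseaseSim, assoc)
}
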