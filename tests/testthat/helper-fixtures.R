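# Shared fixtures, all built in code.

# small deterministic symmetric similarity matrix with unit diagonal
toySim <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

toySimilarityView <- function(n, seed = 1, prefix = "E") {
  SimilarityView(sprintf("%s%02d", prefix, seq_len(n)), toySim(n, seed))
}

# consistent toy heterogeneous network: 3 drugs, 4 diseases, 5 proteins
toyNetwork <- function(withProteins = TRUE, S = 2) {
  drugs <- c("d1", "d2", "d3"); dis <- c("s1", "s2", "s3", "s4")
  prots <- paste0("p", 1:5)
  views <- lapply(seq_len(S), function(s) SimilarityView(drugs, toySim(3, s)))
  dSim <- SimilarityView(dis, toySim(4, 99))
  A <- matrix(c(1, 0, 1, 0,
                0, 1, 0, 0,
                1, 1, 0, 1), 3, 4, byrow = TRUE)
  assoc <- AssociationMatrix(drugs, dis, A)
  if (!withProteins) return(assembleNetwork(views, dSim, assoc))
  dp <- new("BipartiteEdgeList", sourceDomain = "drug", targetDomain = "protein",
            edges = data.frame(source = c("d1", "d1", "d2", "d3"),
                               target = c("p1", "p2", "p3", "p5")))
  ddp <- new("BipartiteEdgeList", sourceDomain = "disease", targetDomain = "protein",
             edges = data.frame(source = c("s1", "s2", "s4"),
                                target = c("p1", "p4", "p5")))
  ppi <- PPINetwork(prots, data.frame(source = c("p1", "p2", "p3", "p4"),
                                      target = c("p2", "p3", "p4", "p5")))
  assembleNetwork(views, dSim, assoc, dp, ddp, ppi)
}

# write a similarity matrix to a temp TSV in the package's file dialect
writeSimTsv <- function(m, ids = sprintf("x%d", seq_len(nrow(m)))) {
  path <- tempfile(fileext = ".tsv")
  df <- as.data.frame(m)
  colnames(df) <- ids
  df <- cbind(id = ids, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

writeEdgeTsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small random GAT parameter set
toyGatParams <- function(fsrc, fdst, k, seed = 1) {
  set.seed(seed)
  list(Wv = matrix(rnorm(fsrc * k), fsrc, k),
       Wu = matrix(rnorm(fdst * k), fdst, k),
       a1 = matrix(rnorm(k), k, 1), a2 = matrix(rnorm(k), k, 1),
       slope = 0.2)
}

# scalar-loop oracle for gatProject
gatOracle <- function(srcX, dstX, edges, params, activate = TRUE) {
  k <- ncol(params$Wv)
  out <- matrix(0, nrow(dstX), k)
  Hv <- srcX %*% params$Wv
  Hu <- dstX %*% params$Wu
  a <- c(params$a1, params$a2)
  for (u in unique(edges[, 2])) {
    nb <- edges[edges[, 2] == u, 1]
    sc <- sapply(nb, function(v) {
      z <- sum(a * c(Hu[u, ], Hv[v, ]))
      if (z >= 0) z else params$slope * z
    })
    al <- exp(sc - max(sc)); al <- al / sum(al)
    acc <- numeric(k)
    for (i in seq_along(nb)) acc <- acc + al[i] * Hv[nb[i], ]
    out[u, ] <- if (activate) pmax(acc, 0) else acc
  }
  out
}
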