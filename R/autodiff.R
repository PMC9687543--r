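## Minimal reverse-mode automatic differentiation over dense matrices.
## A tape records nodes in creation order; each op stores a backward closure
## returning gradients for its parents. Only the operations the model needs
## are implemented: matrix products, elementwise ops, activations, gather /
## segment-softmax / weighted aggregation over edge lists, same-padded 1D
## convolution, channel pooling and fusion, dropout masking, and the weighted
## binary cross-entropy on logits. Everything is deterministic; the engine is
## validated by finite-difference checks in the test suite.

adTape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

.adNew <- function(tape, val, parents = list(), back = NULL, param = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$parents <- parents
  n$back <- back
  n$param <- param
  n$tape <- tape
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  n$id <- tape$n
  tape$nodes[[tape$n]] <- n
  n
}

adConst <- function(tape, val) .adNew(tape, val)
adParam <- function(tape, val, name) .adNew(tape, val, param = name)

## a %*% b
adMM <- function(a, b) .adNew(a$tape, a$val %*% b$val, list(a, b),
  function(g) list(g %*% t(b$val), crossprod(a$val, g)))

## a %*% t(b)
adMMT <- function(a, b) .adNew(a$tape, tcrossprod(a$val, b$val), list(a, b),
  function(g) list(g %*% b$val, crossprod(g, a$val)))

adAdd <- function(a, b) .adNew(a$tape, a$val + b$val, list(a, b),
  function(g) list(g, g))

adAddList <- function(xs) {
  v <- xs[[1]]$val
  for (i in seq_along(xs)[-1]) v <- v + xs[[i]]$val
  .adNew(xs[[1]]$tape, v, xs,
         function(g) rep(list(g), length(xs)))
}

adEMul <- function(a, b) .adNew(a$tape, a$val * b$val, list(a, b),
  function(g) list(g * b$val, g * a$val))

## elementwise product with a constant matrix (dropout masks, loss weights)
adEMulConst <- function(a, m) .adNew(a$tape, a$val * m, list(a),
  function(g) list(g * m))

adRelu <- function(a) {
  v <- a$val; v[v < 0] <- 0
  .adNew(a$tape, v, list(a), function(g) list(g * (a$val > 0)))
}

adLeaky <- function(a, slope) {
  v <- ifelse(a$val >= 0, a$val, slope * a$val)
  .adNew(a$tape, v, list(a),
         function(g) list(g * ifelse(a$val >= 0, 1, slope)))
}

adSigmoid <- function(a) {
  s <- stats::plogis(a$val)
  .adNew(a$tape, s, list(a), function(g) list(g * s * (1 - s)))
}

## outer(deg, w) for a constant degree vector and a parameter vector w
adOuterDeg <- function(tape, deg, w) .adNew(tape, outer(deg, drop(w$val)),
  list(w), function(g) list(matrix(drop(crossprod(g, deg)), ncol = 1)))

## rows of X indexed by idx (with repetition)
adGatherRows <- function(X, idx) .adNew(X$tape, X$val[idx, , drop = FALSE],
  list(X), function(g) {
    out <- matrix(0, nrow(X$val), ncol(X$val))
    rs <- rowsum(g, idx)
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })

.segMax <- function(x, grp) {
  mx <- tapply(x, grp, max)
  as.numeric(mx[as.character(grp)])
}

.segSumVec <- function(x, grp, n) {
  out <- numeric(n)
  rs <- rowsum(x, grp)
  out[as.integer(rownames(rs))] <- rs
  out
}

## softmax of edge scores within destination segments; s is E x 1
adSegSoftmax <- function(s, dstIdx, nDst) {
  sv <- drop(s$val)
  ex <- exp(sv - .segMax(sv, dstIdx))
  denom <- .segSumVec(ex, dstIdx, nDst)
  al <- ex / denom[dstIdx]
  .adNew(s$tape, matrix(al, ncol = 1), list(s), function(g) {
    gv <- drop(g)
    dots <- .segSumVec(al * gv, dstIdx, nDst)
    list(matrix(al * (gv - dots[dstIdx]), ncol = 1))
  })
}

## out[u, ] = sum over edges e with dst(e)=u of alpha_e * M[src(e), ]
adEdgeAgg <- function(alpha, M, srcIdx, dstIdx, nDst) {
  av <- drop(alpha$val)
  contrib <- av * M$val[srcIdx, , drop = FALSE]
  out <- matrix(0, nDst, ncol(M$val))
  rs <- rowsum(contrib, dstIdx)
  out[as.integer(rownames(rs)), ] <- rs
  .adNew(alpha$tape, out, list(alpha, M), function(g) {
    gd <- g[dstIdx, , drop = FALSE]
    dalpha <- matrix(rowSums(gd * M$val[srcIdx, , drop = FALSE]), ncol = 1)
    dM <- matrix(0, nrow(M$val), ncol(M$val))
    rs2 <- rowsum(av * gd, srcIdx)
    dM[as.integer(rownames(rs2)), ] <- rs2
    list(dalpha, dM)
  })
}

adCbind <- function(a, b) {
  ka <- ncol(a$val)
  .adNew(a$tape, cbind(a$val, b$val), list(a, b),
         function(g) list(g[, seq_len(ka), drop = FALSE],
                          g[, -seq_len(ka), drop = FALSE]))
}

## global average pooling of a list of equally-shaped channels -> S x 1
adGap <- function(chans) {
  nel <- length(chans[[1]]$val)
  v <- matrix(vapply(chans, function(c) mean(c$val), numeric(1)), ncol = 1)
  .adNew(chans[[1]]$tape, v, chans, function(g) {
    gv <- drop(g)
    lapply(seq_along(chans), function(s)
      matrix(gv[s] / nel, nrow(chans[[s]]$val), ncol(chans[[s]]$val)))
  })
}

## fused = sum_s w_s * C_s ; w is S x 1
adChanFuse <- function(chans, w) {
  wv <- drop(w$val)
  v <- wv[1] * chans[[1]]$val
  for (s in seq_along(chans)[-1]) v <- v + wv[s] * chans[[s]]$val
  .adNew(w$tape, v, c(chans, list(w)), function(g) {
    gs <- lapply(seq_along(chans), function(s) wv[s] * g)
    dw <- matrix(vapply(chans, function(c) sum(g * c$val), numeric(1)), ncol = 1)
    c(gs, list(dw))
  })
}

## same-padded 1D convolution of z (S x 1) with kernel k (odd length x 1)
adConv1d <- function(z, k) {
  zv <- drop(z$val); kv <- drop(k$val)
  kl <- length(kv); half <- (kl - 1L) / 2L; S <- length(zv)
  zp <- c(rep(0, half), zv, rep(0, half))
  out <- vapply(seq_len(S), function(i) sum(kv * zp[i:(i + kl - 1L)]), numeric(1))
  .adNew(z$tape, matrix(out, ncol = 1), list(z, k), function(g) {
    gv <- drop(g)
    gp <- c(rep(0, half), gv, rep(0, half))
    dz <- vapply(seq_len(S), function(i)
      sum(rev(kv) * gp[i:(i + kl - 1L)]), numeric(1))
    dk <- vapply(seq_len(kl), function(m)
      sum(gv * zp[m:(m + S - 1L)]), numeric(1))
    list(matrix(dz, ncol = 1), matrix(dk, ncol = 1))
  })
}

## weighted binary cross-entropy on logits; w carries lambda on positives,
## 1 on usable negatives, 0 on excluded pairs; scale = 1 / (M * N)
adBceLogits <- function(S, target, w, scale) {
  p <- stats::plogis(S$val)
  ll <- target * stats::plogis(S$val, log.p = TRUE) +
        (1 - target) * stats::plogis(-S$val, log.p = TRUE)
  v <- -scale * sum(w * ll)
  .adNew(S$tape, v, list(S), function(g) list(g * scale * w * (p - target)))
}

## reverse pass: returns named list of gradients for every parameter node
adBackward <- function(loss) {
  tape <- loss$tape
  n <- tape$n
  grads <- vector("list", n)
  grads[[loss$id]] <- 1
  for (id in n:1) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (is.null(node$back)) next
    pg <- node$back(g)
    ps <- node$parents
    for (j in seq_along(ps)) {
      pid <- ps[[j]]$id
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]] else grads[[pid]] + pg[[j]]
    }
  }
  out <- list()
  for (id in seq_len(n)) {
    node <- tape$nodes[[id]]
    if (!is.null(node$param))
      out[[node$param]] <- if (is.null(grads[[id]])) node$val * 0 else grads[[id]]
  }
  out
}
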