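## Efficient channel attention over the S drug similarity channels:
## global average pooling -> shared small-kernel 1D convolution -> logistic
## weights -> weighted channel sum. The kernel is a learnable length-k vector
## shared across channels; same-padding with zeros keeps output length S.

#' Global average pooling over the spatial dimensions of a channel stack
#'
#' For each channel s, `Z_s = mean(stack[, , s])` — the average over all
#' entities and features.
#'
#' @param stack M x F x S array.
#' @return length-S numeric vector.
#' @export
globalAveragePool <- function(stack) {
  stopifnot(length(dim(stack)) == 3)
  apply(stack, 3, mean)
}

#' Same-padded 1D convolution of a channel descriptor
#'
#' Zero-padded convolution with an odd-length kernel shared across channels;
#' output length equals input length for any S >= 1.
#'
#' @param z length-S numeric vector.
#' @param kernel odd-length numeric kernel.
#' @return length-S numeric vector.
#' @export
conv1dSame <- function(z, kernel) {
  k <- length(kernel)
  if (k %% 2 == 0) stop("kernel length must be odd")
  S <- length(z)
  half <- (k - 1L) / 2L
  zp <- c(rep(0, half), z, rep(0, half))
  out <- numeric(S)
  for (i in seq_len(S)) out[i] <- sum(kernel * zp[i:(i + k - 1L)])
  out
}

#' Channel attention weights from a pooled descriptor
#'
#' `omega = logistic(conv1d_k(Z))` with a shared learnable kernel
#' (default length 3). Entries are strictly inside (0, 1).
#'
#' @param Z length-S pooled descriptor (from [globalAveragePool()]).
#' @param kernel numeric kernel weights of odd length.
#' @return length-S vector of weights in (0, 1).
#' @export
ecaWeights <- function(Z, kernel) {
  stats::plogis(conv1dSame(Z, kernel))
}

#' Fuse channels by attention-weighted summation
#'
#' `fused = sum_s omega_s * stack[, , s]`. Weights are used as-is (no
#' re-normalization to sum 1).
#'
#' @param stack M x F x S array.
#' @param omega length-S weight vector.
#' @return M x F matrix.
#' @export
fuseChannels <- function(stack, omega) {
  d <- dim(stack)
  if (length(omega) != d[3]) stop("weight length must equal channel count")
  out <- matrix(0, d[1], d[2])
  for (s in seq_len(d[3])) out <- out + omega[s] * stack[, , s]
  out
}

#' One-shot attention fusion of a channel stack
#'
#' Composition pool -> weights -> weighted sum. With a single channel the
#' attention block is bypassed and the channel passed through unscaled
#' (a logistic weight on the only view would merely rescale embeddings).
#'
#' @param stack M x F x S array.
#' @param kernel attention kernel weights.
#' @return list with `fused` (M x F) and `omega` (length S; 1 when bypassed).
#' @export
attentionFuse <- function(stack, kernel) {
  S <- dim(stack)[3]
  if (S == 1) return(list(fused = stack[, , 1, drop = TRUE], omega = 1))
  omega <- ecaWeights(globalAveragePool(stack), kernel)
  list(fused = fuseChannels(stack, omega), omega = omega)
}
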