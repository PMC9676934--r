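#' @include autograd.R
NULL

#' Causal (lower-triangular) attention mask
#'
#' @param nq,nk query/key sequence lengths.
#' @return logical matrix, TRUE where position i may attend to position j
#'   (j <= i).
#' @export
causalMask <- function(nq, nk = nq) {
  outer(seq_len(nq), seq_len(nk), ">=")
}

#' Block-diagonal window mask for inner-patch self-attention
#'
#' Partitions a sequence into consecutive windows of at most \code{window}
#' tokens; attention is confined within each window (the local stage of a
#' cross-attention block).
#'
#' @param n sequence length.
#' @param window window size in tokens.
#' @return logical n x n matrix.
#' @export
windowMask <- function(n, window) {
  grp <- (seq_len(n) - 1L) %/% window
  outer(grp, grp, "==")
}

#' Initialize multi-head attention projection weights
#'
#' @param dIn input width of queries/keys/values.
#' @param dModel projection width (default \code{dIn}); must be divisible
#'   by the head count.
#' @param dOut output width (default \code{dIn}).
#' @param sd init scale.
#' @return list of weight matrices/vectors \code{Wq, bq, Wk, bk, Wv, bv,
#'   Wo, bo}.
#' @export
initAttentionWeights <- function(dIn, dModel = dIn, dOut = dIn, sd = 0.02) {
  rn <- function(a, b) matrix(stats::rnorm(a * b, 0, sd), a, b)
  list(Wq = rn(dIn, dModel), bq = numeric(dModel),
       Wk = rn(dIn, dModel), bk = numeric(dModel),
       Wv = rn(dIn, dModel), bv = numeric(dModel),
       Wo = rn(dModel, dOut), bo = numeric(dOut))
}

#' Multi-head scaled dot-product attention
#'
#' The attention primitive: queries, keys and values are linearly
#' projected, split into \code{nHeads} heads, attended with
#' softmax(Q K^T * scale) per head, concatenated and projected by
#' \code{Wo}. Masked positions receive zero attention weight. The default
#' scaling is 1/sqrt(d_head) (the cited standard); \code{scale =
#' "linear"} divides by d_head instead.
#'
#' @param queries numeric nq x d matrix.
#' @param keys,values numeric nk x d matrices (equal lengths).
#' @param nHeads head count; the projection width must be divisible by it.
#' @param weights projection weights from [initAttentionWeights()]; when
#'   NULL, identity projections are used (queries/keys/values attended
#'   directly).
#' @param mask optional logical nq x nk matrix (TRUE = attend) or the
#'   string \code{"causal"}.
#' @param scale \code{"sqrt"} or \code{"linear"}.
#' @param returnWeights also return the per-head attention weight
#'   matrices.
#' @return the attended nq x d_out matrix, or a list \code{(output,
#'   weights)} when \code{returnWeights}.
#' @examples
#' x <- matrix(rnorm(12), 3, 4)
#' multiHeadAttention(x, x, x, nHeads = 2)
#' @export
multiHeadAttention <- function(queries, keys, values, nHeads, weights = NULL,
                               mask = NULL, scale = c("sqrt", "linear"),
                               returnWeights = FALSE) {
  scale <- match.arg(scale)
  if (nrow(keys) != nrow(values))
    stop("shape error: keys and values must have equal lengths")
  if (ncol(keys) != ncol(queries) && is.null(weights))
    stop("shape error: queries and keys widths differ; supply projection weights")
  if (is.character(mask) && identical(mask, "causal"))
    mask <- causalMask(nrow(queries), nrow(keys))
  if (!is.null(weights)) {
    Q <- sweep(queries %*% weights$Wq, 2L, weights$bq, "+")
    K <- sweep(keys %*% weights$Wk, 2L, weights$bk, "+")
    V <- sweep(values %*% weights$Wv, 2L, weights$bv, "+")
  } else {
    Q <- queries; K <- keys; V <- values
  }
  if (ncol(Q) %% nHeads != 0L)
    stop("shape error: width must be divisible by the head count")
  cc <- .sdpa_core(Q, K, V, nHeads, mask, scale)
  out <- cc$out
  if (!is.null(weights))
    out <- sweep(out %*% weights$Wo, 2L, weights$bo, "+")
  if (returnWeights) list(output = out, weights = cc$weights) else out
}
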