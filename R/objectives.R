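#' @include autograd.R
NULL

#' Loss weights of the combined objective
#'
#' The total training loss is \eqn{L = \alpha L_{con} + \beta L_{cap}}
#' with \eqn{\alpha + \beta = 1}; the reference setting is
#' \eqn{\alpha = 0.3}, \eqn{\beta = 0.7}, temperature \eqn{\tau = 0.07}.
#'
#' @param alpha weight of the constraint (contrastive) loss, in [0, 1].
#' @param beta weight of the captioning loss, in [0, 1].
#' @param tau contrastive temperature, > 0.
#' @return a validated list of class \code{LossWeights}.
#' @export
lossWeights <- function(alpha = 0.3, beta = 0.7, tau = 0.07) {
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("configuration error: alpha and beta must lie in [0, 1]")
  if (abs(alpha + beta - 1) > 1e-9)
    stop("configuration error: alpha + beta must equal 1")
  if (!is.finite(tau) || tau <= 0)
    stop("configuration error: tau must be positive")
  structure(list(alpha = alpha, beta = beta, tau = tau),
            class = "LossWeights")
}

.lse_rows <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Bidirectional contrastive constraint loss
#'
#' The alignment loss between the image class tokens and the text class
#' tokens of a batch: temperature-scaled InfoNCE in both directions,
#' \deqn{L_{I\to T} = -\frac1N \sum_i \log
#'   \frac{\exp(Img_i^\top Txt_i / \tau)}{\sum_j \exp(Img_i^\top Txt_j / \tau)},}
#' its transpose \eqn{L_{T\to I}}, and their sum \eqn{L_{con}}. Rows are
#' expected L2-normalized upstream so logits are cosines over temperature;
#' the log-sum-exp is computed stably.
#'
#' @param imgTokens numeric N x d matrix of image class embeddings.
#' @param txtTokens numeric N x d matrix of text class embeddings (row i
#'   pairs with row i of \code{imgTokens}).
#' @param tau temperature, > 0.
#' @return list with \code{con}, \code{i2t}, \code{t2i} (all >= 0).
#' @examples
#' z <- diag(4)
#' constraintLoss(z, z, tau = 0.07)$con
#' @export
constraintLoss <- function(imgTokens, txtTokens, tau = 0.07) {
  if (!is.matrix(imgTokens)) imgTokens <- rbind(imgTokens)
  if (!is.matrix(txtTokens)) txtTokens <- rbind(txtTokens)
  N <- nrow(imgTokens)
  if (N == 0L) stop("value error: empty batch")
  if (nrow(txtTokens) != N)
    stop("shape error: batch sizes differ")
  if (ncol(txtTokens) != ncol(imgTokens))
    stop("shape error: embedding dims differ")
  if (tau <= 0) stop("value error: tau must be positive")
  S <- tcrossprod(imgTokens, txtTokens) / tau
  di <- diag(S)
  i2t <- mean(.lse_rows(S) - di)
  t2i <- mean(.lse_rows(t(S)) - di)
  list(con = i2t + t2i, i2t = i2t, t2i = t2i)
}

#' Captioning (cross-entropy) loss
#'
#' Mean cross-entropy between the multimodal prediction and the
#' text-derived label. In the binary branch \code{probs} is the predicted
#' probability of the pathological class (label 1); probabilities are
#' clipped at 1e-7 so the loss stays finite at confident extremes. For
#' \code{nClasses > 2}, \code{probs} is an N x C matrix of class
#' probabilities and \code{labels} holds 0-based class indices.
#'
#' @param labels integer class labels (0/1 in the binary branch).
#' @param probs probability vector (binary) or matrix (multi-class).
#' @param nClasses number of classes.
#' @return mean cross-entropy, >= 0.
#' @examples
#' captioningLoss(c(0, 1), c(0.5, 0.5)) # log(2)
#' @export
captioningLoss <- function(labels, probs, nClasses = 2L) {
  eps <- 1e-7
  if (nClasses == 2L && !is.matrix(probs)) {
    if (any(probs < 0 | probs > 1))
      stop("value error: probabilities must lie in [0, 1]")
    if (length(labels) != length(probs))
      stop("shape error: labels and probs lengths differ")
    p <- pmin(pmax(probs, eps), 1 - eps)
    y <- as.numeric(labels)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    if (any(probs < 0 | probs > 1))
      stop("value error: probabilities must lie in [0, 1]")
    p <- pmin(pmax(probs, eps), 1 - eps)
    -mean(log(p[cbind(seq_len(nrow(p)), as.integer(labels) + 1L)]))
  }
}

#' Combined training loss
#'
#' \eqn{L = \alpha L_{con} + \beta L_{cap}}.
#'
#' @param lcon constraint loss value (or the list from
#'   [constraintLoss()]).
#' @param lcap captioning loss value.
#' @param weights a [lossWeights()] bundle.
#' @return a single number.
#' @examples
#' totalLoss(2, 1, lossWeights(0.3, 0.7)) # 1.3
#' @export
totalLoss <- function(lcon, lcap, weights = lossWeights()) {
  if (!inherits(weights, "LossWeights")) weights <- do.call(lossWeights, weights)
  if (is.list(lcon)) lcon <- lcon$con
  weights$alpha * lcon + weights$beta * lcap
}
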