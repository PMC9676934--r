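#' @include training.R
NULL

# encoder features of a list of patch matrices, computed outside any
# gradient tape: the backbone stays frozen by construction
.frozen_features <- function(model, patchList, batchSize = 32L) {
  cfg <- model@config
  n <- length(patchList)
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batchSize - 1L, n)
    B <- j - i + 1L
    tape <- ad_tape()
    Xp <- ad_const(tape, .stack_patches(patchList[i:j]))
    enc <- .fwd_image_encoder(tape, model@params, cfg, Xp, B,
                              training = FALSE)
    m <- enc$n
    for (b in seq_len(B))
      out[[i + b - 1L]] <- enc$node$val[seq.int((b - 1L) * m + 1L, b * m), ,
                                        drop = FALSE]
    i <- j + 1L
  }
  out
}

.head_spec <- function(di) {
  c(.cab_spec("fdd_cab", di), .ln_spec("fdd_ln", di),
    list(fdd_W = c(di, 2L), fdd_b = 2L))
}

# head forward on constant feature tokens: CAB -> LayerNorm -> linear on
# the image-query row -> class logits
.head_forward <- function(tape, head, cfg, featNode, B, nTok, training) {
  x <- .fwd_cab(tape, head, "fdd_cab", featNode, NULL, B, nTok,
                cfg@headsImage, cfg, training)
  x <- ad_layernorm(tape, x, head$fdd_ln_g, head$fdd_ln_b)
  q <- ad_rows(tape, x, seq_len(B) * nTok)
  ad_linear(tape, q, head$fdd_W, head$fdd_b)
}

#' Build the frozen-encoder diagnostic test model
#'
#' Loads the trained image encoder with frozen weights and fits a new head
#' (cross-attention block over the feature tokens and the image query
#' token, LayerNorm, linear softmax over the two classes) on the training
#' split with softmax cross-entropy. Only the head receives gradient
#' updates; encoder features are computed outside the tape, so frozen
#' tensors keep exactly zero gradients.
#'
#' @param model a trained [MMIFModel-class] (or a checkpoint path).
#' @param stacks named list of [GADFStack-class].
#' @param labels named record labels.
#' @param trainIds record ids of the head-fitting split (training records
#'   only; never validation or test).
#' @param hyper a [Hyperparams-class] (optimizer settings reused).
#' @param headEpochs epochs of head fitting (default 5).
#' @return an [FDDModel-class].
#' @export
buildTestModel <- function(model, stacks, labels, trainIds, hyper,
                           headEpochs = 5L) {
  if (is.character(model)) model <- loadCheckpoint(model)
  cfg <- model@config
  labels <- as.list(labels)
  set.seed(hyper@seed)
  head <- new.env(parent = emptyenv())
  hs <- .head_spec(cfg@embedDimImage)
  for (nm in names(hs)) head[[nm]] <- nnParam(hs[[nm]], init = .init_kind(nm))
  pairs <- .pair_data(stacks, labels, trainIds, cfg@patchSize)
  feats <- .frozen_features(model, pairs$patches, hyper@batchSize)
  nTok <- nrow(feats[[1]])
  n <- length(feats)
  for (ep in seq_len(headEpochs)) {
    ord <- sample.int(n)
    i <- 1L
    while (i <= n) {
      j <- min(i + hyper@batchSize - 1L, n)
      take <- ord[i:j]
      tape <- ad_tape()
      featNode <- ad_const(tape, do.call(rbind, feats[take]))
      logits <- .head_forward(tape, head, cfg, featNode, length(take), nTok,
                              training = TRUE)
      loss <- ad_softmaxce(tape, logits, pairs$label[take])
      ad_backward(tape, loss)
      .optim_step(head, hyper)
      i <- j + 1L
    }
  }
  new("FDDModel", backbone = model, head = head, config = cfg)
}

# vote rule: pathological when votes exceed half; exact tie -> pathological
.majority_label <- function(votes, n) {
  as.integer(votes >= n / 2)
}

# per-image pathological probabilities of a stack under the test model
.fdd_probs <- function(fdd, stack, batchSize = 32L) {
  patchList <- lapply(stackImages(stack), imagePatches,
                      fdd@config@patchSize)
  feats <- .frozen_features(fdd@backbone, patchList, batchSize)
  nTok <- nrow(feats[[1]])
  B <- length(feats)
  tape <- ad_tape()
  featNode <- ad_const(tape, do.call(rbind, feats))
  logits <- .head_forward(tape, fdd@head, fdd@config, featNode, B, nTok,
                          training = FALSE)
  .softmax_rows(logits$val)[, 2L]
}

#' Diagnose one record by majority vote over its image stack
#'
#' Each image of the stack is classified independently by the
#' frozen-encoder test model; the record is called pathological when the
#' pathological votes exceed half of the images (an exact tie also
#' resolves to pathological, as a clinical fail-safe).
#'
#' @param model an [FDDModel-class].
#' @param stack a [GADFStack-class].
#' @param labelTrue optional true label for evaluation.
#' @return a [DiagnosisResult-class].
#' @export
diagnoseRecord <- function(model, stack, labelTrue = NA_integer_) {
  probs <- .fdd_probs(model, stack)
  votes <- sum(probs > 0.5)
  pred <- .majority_label(votes, length(probs))
  new("DiagnosisResult", recordId = recordId(stack),
      perImageProbs = probs, votesPathological = as.integer(votes),
      labelPred = pred, labelTrue = as.integer(labelTrue))
}

#' Evaluate a set of record-level diagnoses
#'
#' ACC is the fraction of correct record labels; F1 is the harmonic mean
#' of precision and recall for the pathological class; AUC is the
#' rank-statistic (Mann-Whitney) area under the ROC curve of the
#' record-level score, defined as the mean per-image pathological
#' probability. When the truth set contains a single class, AUC is
#' undefined and returned as NA with a warning (ACC and F1 are still
#' returned).
#'
#' @param results list of [DiagnosisResult-class] with \code{labelTrue}
#'   set.
#' @return list with \code{acc}, \code{f1}, \code{auc}.
#' @export
evaluateDiagnoses <- function(results) {
  truth <- vapply(results, function(r) r@labelTrue, 1L)
  pred <- vapply(results, function(r) r@labelPred, 1L)
  score <- vapply(results, function(r) mean(r@perImageProbs), 1)
  if (anyNA(truth)) stop("value error: every result needs labelTrue")
  acc <- mean(pred == truth)
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  if (length(unique(truth)) < 2L) {
    warning("AUC undefined: truth set contains a single class")
    auc <- NA_real_
  } else {
    sp <- score[truth == 1L]
    sn <- score[truth == 0L]
    cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    auc <- mean(cmp)
  }
  list(acc = acc, f1 = f1, auc = auc)
}

#' Coefficient of determination of cross-modal label alignment
#'
#' \deqn{R^2 = 1 - \frac{\sum_i (\hat y^*_i - Txt_i)^2}
#'   {\sum_i (Txt_i - \bar{Txt})^2}}
#' where \eqn{\hat y^*} are the image-side (or multimodal) outcome labels
#' or scores and \eqn{Txt} the text-derived labels. May be negative.
#'
#' @param predLabels numeric predictions (hard labels or scores).
#' @param textLabels numeric text-derived labels; must not be constant.
#' @return a single number.
#' @examples
#' rSquare(c(1, 0, 1, 0), c(1, 0, 0, 0)) # -1/3
#' @export
rSquare <- function(predLabels, textLabels) {
  if (length(predLabels) != length(textLabels))
    stop("shape error: lengths differ")
  if (length(textLabels) < 2L)
    stop("value error: need at least 2 observations")
  ssTot <- sum((textLabels - mean(textLabels))^2)
  if (ssTot == 0)
    stop("undefined: text labels are all identical (zero total variance)")
  1 - sum((predLabels - textLabels)^2) / ssTot
}

#' Write a diagnosis report
#'
#' Per-record CSV (record id, votes, mean probability, prediction, truth)
#' plus a metrics JSON when truth labels are available.
#'
#' @param results list of [DiagnosisResult-class].
#' @param csvPath per-record report path.
#' @param jsonPath optional metrics JSON path.
#' @return the csv path, invisibly.
#' @export
writeDiagnosisReport <- function(results, csvPath, jsonPath = NULL) {
  df <- data.frame(
    record_id = vapply(results, function(r) r@recordId, ""),
    votes_pathological = vapply(results, function(r) r@votesPathological, 1L),
    mean_prob = vapply(results, function(r) mean(r@perImageProbs), 1),
    label_pred = vapply(results, function(r) r@labelPred, 1L),
    label_true = vapply(results, function(r) r@labelTrue, 1L)
  )
  utils::write.csv(df, csvPath, row.names = FALSE, quote = FALSE)
  if (!is.null(jsonPath) && !anyNA(df$label_true)) {
    m <- evaluateDiagnoses(results)
    jsonlite::write_json(m, jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(csvPath)
}
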