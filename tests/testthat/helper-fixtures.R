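# shared fixtures: everything is generated in code at test time

tinyConfig <- function(dropout = 0, ...) {
  modelConfig("custom", imageSize = 32, patchSize = 8, embedDimImage = 16,
              embedDimText = 16, encoderDepth = 2, unimodalDecoderDepth = 2,
              multimodalDecoderDepth = 2, headsImage = 2, headsText = 2,
              dropout = dropout, ...)
}

tinyModel <- function(seed = 1, ...) newMMIFModel(tinyConfig(...), seed = seed)

randImage <- function(s = 32, seed = 1) {
  set.seed(seed)
  array(stats::runif(s * s * 3), c(s, s, 3))
}

# short synthetic records + 2-image stacks at 32 px, for fast model tests
tinyStacks <- function(nPerClass = 10, seed = 1, nSamples = 720L,
                       schedule = c(360L, 180L), size = 32L) {
  recs <- generateDataset(nPerClass, nPerClass, seed = seed,
                          nSamples = nSamples)
  labels <- lapply(recs, recordLabel)
  names(labels) <- vapply(recs, recordId, "")
  stacks <- lapply(recs, function(r)
    recordToStack(fillMissing(r), schedule = schedule, size = size))
  names(stacks) <- names(labels)
  list(stacks = stacks, labels = labels, ids = names(labels))
}

# independent double-loop multi-head attention oracle
bruteForceMHA <- function(queries, keys, values, nHeads, w, mask = NULL,
                          scale = "sqrt") {
  Q <- sweep(queries %*% w$Wq, 2, w$bq, "+")
  K <- sweep(keys %*% w$Wk, 2, w$bk, "+")
  V <- sweep(values %*% w$Wv, 2, w$bv, "+")
  d <- ncol(Q)
  dh <- d / nHeads
  coef <- if (scale == "sqrt") 1 / sqrt(dh) else 1 / dh
  out <- matrix(0, nrow(Q), d)
  for (h in seq_len(nHeads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    for (i in seq_len(nrow(Q))) {
      s <- numeric(nrow(K))
      for (j in seq_len(nrow(K)))
        s[j] <- sum(Q[i, cols] * K[j, cols]) * coef
      if (!is.null(mask)) s[!mask[i, ]] <- -Inf
      a <- exp(s - max(s))
      a <- a / sum(a)
      for (j in seq_len(nrow(K)))
        out[i, cols] <- out[i, cols] + a[j] * V[j, cols]
    }
  }
  sweep(out %*% w$Wo, 2, w$bo, "+")
}

# fractional-weight PAA oracle: explicit per-segment overlap integration
bruteForcePAA <- function(x, d) {
  L <- length(x)
  w <- L / d
  out <- numeric(d)
  for (k in seq_len(d)) {
    a <- (k - 1) * w
    b <- k * w
    acc <- 0
    for (t in seq_len(L)) {
      lo <- max(a, t - 1)
      hi <- min(b, t)
      if (hi > lo) acc <- acc + (hi - lo) * x[t]
    }
    out[k] <- acc / w
  }
  out
}
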