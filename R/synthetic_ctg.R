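#' @include fhr_io.R
NULL

#' Synthetic CTG generator parameters
#'
#' Bundle of generator parameters for one synthetic 30-minute FHR trace.
#' The class presets encode the physiology the classifier is meant to
#' separate: a normal fetus shows a baseline within 110-160 bpm with
#' moderate beat-to-beat variability and at most shallow decelerations; a
#' compromised fetus shows reduced variability and deep, repetitive
#' decelerations.
#'
#' @param baselineBpm mean FHR level in bpm, within [60, 220].
#' @param variabilityBpm short-term variability band amplitude in bpm
#'   (approximate peak-to-peak of the band-limited noise); >= 0.
#' @param nDecel expected deceleration count per 30 minutes.
#' @param decelDepthBpm deceleration depth in bpm.
#' @param decelWidthS deceleration duration in seconds.
#' @param missingFrac fraction of missing samples in [0, 0.10].
#' @param seed integer RNG seed; the trace is fully determined by it.
#' @return a validated parameter list of class \code{SynthParams}.
#' @seealso [synthPreset()], [generateRecord()]
#' @export
synthParams <- function(baselineBpm = 140, variabilityBpm = 15, nDecel = 1,
                        decelDepthBpm = 20, decelWidthS = 30,
                        missingFrac = 0.05, seed = 1L) {
  if (baselineBpm < 60 || baselineBpm > 220)
    stop("baselineBpm must lie in [60, 220]")
  if (variabilityBpm < 0) stop("variabilityBpm must be >= 0")
  if (missingFrac < 0 || missingFrac > 0.10)
    stop("missingFrac must lie in [0, 0.10]")
  structure(list(baselineBpm = baselineBpm, variabilityBpm = variabilityBpm,
                 nDecel = nDecel, decelDepthBpm = decelDepthBpm,
                 decelWidthS = decelWidthS, missingFrac = missingFrac,
                 seed = as.integer(seed)),
            class = "SynthParams")
}

#' Class presets for the synthetic generator
#'
#' @param label 0 (normal) or 1 (pathological).
#' @param seed integer seed passed through to [synthParams()].
#' @return a \code{SynthParams} list.
#' @export
synthPreset <- function(label, seed = 1L) {
  if (!label %in% c(0, 1)) stop("value error: label must be 0 or 1")
  if (label == 0) {
    synthParams(baselineBpm = 140, variabilityBpm = 15, nDecel = 1,
                decelDepthBpm = 20, decelWidthS = 30, missingFrac = 0.05,
                seed = seed)
  } else {
    synthParams(baselineBpm = 135, variabilityBpm = 4, nDecel = 6,
                decelDepthBpm = 45, decelWidthS = 60, missingFrac = 0.05,
                seed = seed)
  }
}

# ideal FFT low-pass at cutoffHz (band-limits the variability noise)
.lowpass_fft <- function(x, rateHz = 4, cutoffHz = 0.5) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * rateHz
  f <- pmin(f, rateHz - f) # two-sided frequency axis
  X <- stats::fft(x)
  X[f > cutoffHz] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Generate one synthetic FHR record
#'
#' Builds a 30-minute, 4 Hz trace as baseline + band-limited (0.5 Hz)
#' Gaussian variability + negative-Gaussian deceleration bumps at random
#' onsets, masks a Bernoulli fraction of samples as missing, and attaches
#' clinical metadata consistent with the class (label 0: pH around 7.25
#' with Apgar 9/10; label 1: pH around 6.95). The record is fully
#' determined by \code{params$seed}.
#'
#' @param label 0 (normal) or 1 (pathological).
#' @param params a [synthParams()] bundle; defaults to the class preset.
#' @param recordId identifier; default derived from label and seed.
#' @param nSamples trace length (default 7200 = 30 min at 4 Hz).
#' @return an [FHRRecord-class] with label and metadata set.
#' @examples
#' rec <- generateRecord(0, synthPreset(0, seed = 7))
#' rec
#' @export
generateRecord <- function(label, params = synthPreset(label),
                           recordId = NULL, nSamples = 7200L) {
  if (!label %in% c(0, 1)) stop("value error: label must be 0 or 1")
  stopifnot(inherits(params, "SynthParams"))
  if (is.null(recordId))
    recordId <- sprintf("syn%s%06d", c("N", "P")[label + 1L], params$seed)
  set.seed(params$seed)
  n <- as.integer(nSamples)
  rateHz <- 4
  # band-limited variability, scaled so its peak-to-peak spread tracks
  # variabilityBpm (sd = amplitude / 4)
  noise <- .lowpass_fft(stats::rnorm(n), rateHz = rateHz, cutoffHz = 0.5)
  s <- stats::sd(noise)
  if (s > 0 && params$variabilityBpm > 0) {
    noise <- noise / s * (params$variabilityBpm / 4)
  } else {
    noise <- numeric(n)
  }
  v <- params$baselineBpm + noise
  nd <- stats::rpois(1, params$nDecel)
  if (nd > 0) {
    t <- seq_len(n)
    widthSamp <- params$decelWidthS * rateHz
    sigma <- widthSamp / 4
    onsets <- sort(stats::runif(nd, 1, n))
    depths <- params$decelDepthBpm * stats::runif(nd, 0.7, 1.3)
    for (k in seq_len(nd))
      v <- v - depths[k] * exp(-(t - onsets[k])^2 / (2 * sigma^2))
  }
  v <- pmin(pmax(v, 50), 220)
  mask <- stats::runif(n) < params$missingFrac
  if (label == 0) {
    ph <- round(stats::runif(1, 7.18, 7.38), 2)
    a5 <- sample(9:10, 1)
    a10 <- sample(9:10, 1)
  } else {
    ph <- round(stats::runif(1, 6.85, 7.04), 2)
    a5 <- sample(3:7, 1)
    a10 <- sample(4:8, 1)
  }
  FHRRecord(v, missingMask = mask, recordId = recordId, ph = ph,
            apgar5 = a5, apgar10 = a10, label = as.integer(label),
            rateHz = rateHz)
}

#' Generate a labelled synthetic dataset
#'
#' Generates \code{nNormal + nPathological} records with unique ids. Each
#' record uses the class preset with a small per-record jitter of baseline
#' and variability, all driven deterministically by \code{seed}.
#'
#' @param nNormal,nPathological record counts per class.
#' @param seed integer master seed.
#' @param nSamples per-record trace length.
#' @return a list of [FHRRecord-class] objects.
#' @examples
#' recs <- generateDataset(3, 3, seed = 42, nSamples = 1200)
#' table(vapply(recs, recordLabel, 1L))
#' @export
generateDataset <- function(nNormal, nPathological, seed = 1L,
                            nSamples = 7200L) {
  stopifnot(nNormal >= 0, nPathological >= 0)
  nTot <- nNormal + nPathological
  if (nTot == 0) return(list())
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nTot)
  jitBase <- stats::runif(nTot, 0.96, 1.04)
  jitVar <- stats::runif(nTot, 0.85, 1.15)
  labels <- rep(c(0L, 1L), c(nNormal, nPathological))
  out <- vector("list", nTot)
  for (i in seq_len(nTot)) {
    p <- synthPreset(labels[i], seed = seeds[i])
    p$baselineBpm <- min(max(p$baselineBpm * jitBase[i], 60), 220)
    p$variabilityBpm <- p$variabilityBpm * jitVar[i]
    id <- sprintf("syn%s%04d", c("N", "P")[labels[i] + 1L],
                  if (labels[i] == 0) i else i - nNormal)
    out[[i]] <- generateRecord(labels[i], p, recordId = id,
                               nSamples = nSamples)
  }
  out
}

#' Write a synthetic dataset in the package CSV dialect
#'
#' One CSV per record plus a \code{metadata.csv} table, so synthetic data
#' round-trip through [readFHRRecord()] and [readClinicalMetadata()].
#'
#' @param records list of [FHRRecord-class].
#' @param dir output directory (created if needed).
#' @return the metadata file path, invisibly.
#' @export
writeDataset <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in records) writeFHRCsv(r, file.path(dir, paste0(r@recordId, ".csv")))
  md <- data.frame(
    record_id = vapply(records, function(r) r@recordId, ""),
    ph = vapply(records, function(r) r@ph, 1),
    apgar5 = vapply(records, function(r) r@apgar5, 1L),
    apgar10 = vapply(records, function(r) r@apgar10, 1L),
    label = vapply(records, function(r) r@label, 1L)
  )
  if (nrow(md) == 0L)
    md <- data.frame(record_id = character(), ph = numeric(),
                     apgar5 = integer(), apgar10 = integer(),
                     label = integer())
  writeClinicalMetadata(md, file.path(dir, "metadata.csv"))
  invisible(file.path(dir, "metadata.csv"))
}

#' Short-term variability summary of a record
#'
#' Median over one-minute windows of the within-window standard deviation
#' of the gap-filled trace. This single statistic separates the two
#' synthetic class presets and is used as a sanity probe of class
#' separability.
#'
#' @param record an [FHRRecord-class].
#' @param windowS window length in seconds.
#' @return a single number (bpm).
#' @export
shortTermVariability <- function(record, windowS = 60) {
  rec <- fillMissing(record)
  v <- rec@samples
  w <- as.integer(windowS * rec@rateHz)
  nw <- length(v) %/% w
  if (nw < 1) return(stats::sd(v))
  sds <- vapply(seq_len(nw), function(k)
    stats::sd(v[seq.int((k - 1L) * w + 1L, k * w)]), 1)
  stats::median(sds)
}
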