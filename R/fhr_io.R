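#' @include AllClasses.R
NULL

# Cohort thresholds: pH >= 7.15 with Apgar 5/10 in [9,10] defines normal,
# pH < 7.05 defines pathological, the band between is excluded; records with
# more than 10% missing samples over the analysis window are rejected.
.PH_NORMAL <- 7.15
.PH_PATH <- 7.05
.APGAR_BAND <- c(9L, 10L)
.MAX_MISSING <- 0.10
.WINDOW_SAMPLES <- 30 * 60 * 4

#' Read one FHR record from disk
#'
#' Reads a 4 Hz fetal heart-rate trace either from a plain CSV (one numeric
#' value per line, optional header; 0 or NaN encode a missing sample, the
#' cardiotocography export convention) or from a WFDB record (CTU-UHB
#' layout: format-16 signals, FHR in the first channel, clinical metadata in
#' \verb{#}-comment lines of the header). Samples outside the plausible
#' [30, 300] bpm range are flagged as missing.
#'
#' @param path file path; for WFDB either the \code{.hea} file or the record
#'   base name.
#' @param format \code{"csv"} or \code{"wfdb"}.
#' @param recordId identifier; defaults to the file base name.
#' @param metadata optional data frame from [readClinicalMetadata()]; when
#'   given, pH/Apgar/label for this record id are attached.
#' @return an [FHRRecord-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("fhr", rep("140", 100)), f)
#' readFHRRecord(f)
#' @export
readFHRRecord <- function(path, format = c("csv", "wfdb"), recordId = NULL,
                          metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path) && format == "csv")
    stop("cannot read FHR record: file not found: ", path)
  if (is.null(recordId))
    recordId <- sub("\\.(csv|hea|dat)$", "", basename(path))
  if (format == "csv") {
    rec <- .read_fhr_csv(path, recordId)
  } else {
    rec <- .read_wfdb_record(path, recordId)
  }
  if (!is.null(metadata)) rec <- .attach_metadata(rec, metadata)
  rec
}

.read_fhr_csv <- function(path, recordId) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("format error: empty FHR CSV file: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  # tolerate a single header line
  if (is.na(vals[1]) && !is.nan(vals[1])) {
    lines <- lines[-1]
    vals <- suppressWarnings(as.numeric(lines))
  }
  if (length(vals) == 0L)
    stop("format error: no samples in FHR CSV file: ", path)
  bad <- is.na(vals) & !is.nan(vals)
  if (any(bad))
    stop("format error: non-numeric content in FHR CSV file: ", path,
         " (first offending line: '", lines[which(bad)[1]], "')")
  .record_from_raw(vals, recordId)
}

# raw values -> record; 0, non-finite and out-of-range values become missing
.record_from_raw <- function(vals, recordId, ph = NA_real_,
                             apgar5 = NA_integer_, apgar10 = NA_integer_,
                             label = NA_integer_) {
  miss <- !is.finite(vals) | vals == 0 |
    vals < .FHR_RANGE[1] | vals > .FHR_RANGE[2]
  FHRRecord(vals, missingMask = miss, recordId = recordId, ph = ph,
            apgar5 = apgar5, apgar10 = apgar10, label = label)
}

.attach_metadata <- function(rec, metadata) {
  i <- match(rec@recordId, as.character(metadata$record_id))
  if (is.na(i)) return(rec)
  rec@ph <- as.numeric(metadata$ph[i])
  if ("apgar5" %in% names(metadata)) rec@apgar5 <- as.integer(metadata$apgar5[i])
  if ("apgar10" %in% names(metadata)) rec@apgar10 <- as.integer(metadata$apgar10[i])
  if ("label" %in% names(metadata)) rec@label <- as.integer(metadata$label[i])
  validObject(rec)
  rec
}

#' Read a clinical metadata table
#'
#' CSV with columns \code{record_id}, \code{ph}, \code{apgar5},
#' \code{apgar10} and optionally \code{label}.
#'
#' @param path CSV file path.
#' @return a data frame.
#' @export
readClinicalMetadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "ph")
  if (!all(need %in% names(df)))
    stop("metadata error: columns record_id and ph are required in ", path)
  df
}

#' Write an FHR record as CSV
#'
#' Writes the package CSV dialect: a \code{fhr} header then one value per
#' line, with missing samples encoded as 0.
#'
#' @param record an [FHRRecord-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeFHRCsv <- function(record, path) {
  v <- record@samples
  v[record@missingMask] <- 0
  writeLines(c("fhr", format(v, digits = 12, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Write a clinical metadata table
#'
#' @param metadata data frame with \code{record_id}, \code{ph},
#'   \code{apgar5}, \code{apgar10}, \code{label}.
#' @param path output CSV file.
#' @return the path, invisibly.
#' @export
writeClinicalMetadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the cohort inclusion and labelling rules
#'
#' A record is rejected when more than 10\% of samples in the 30-minute
#' analysis window are missing, or when it is shorter than the window.
#' Otherwise it is labelled normal (0) when pH >= 7.15 and both Apgar
#' scores lie in [9, 10], pathological (1) when pH < 7.05, and excluded
#' when it falls in the intermediate pH band [7.05, 7.15) or fails the
#' Apgar condition of the normal branch.
#'
#' Missingness is evaluated on the trailing analysis window because that is
#' the segment actually analysed.
#'
#' @param record an [FHRRecord-class]; \code{ph} must be set.
#' @param maxMissing maximum tolerated missing fraction (default 0.10).
#' @param windowSamples analysis window length in samples (default 7200 =
#'   30 min at 4 Hz).
#' @return an [InclusionDecision-class].
#' @examples
#' rec <- FHRRecord(rep(140, 7200), ph = 7.2, apgar5 = 9L, apgar10 = 10L)
#' applyInclusionCriteria(rec)
#' @export
applyInclusionCriteria <- function(record, maxMissing = .MAX_MISSING,
                                   windowSamples = .WINDOW_SAMPLES) {
  if (is.na(record@ph))
    stop("metadata error: record '", record@recordId, "' has no pH value")
  reasons <- character()
  n <- length(record@samples)
  if (n < windowSamples) reasons <- c(reasons, "length")
  idx <- seq.int(max(1L, n - windowSamples + 1L), n)
  if (mean(record@missingMask[idx]) > maxMissing)
    reasons <- c(reasons, "missingness")
  label <- NA_integer_
  if (length(reasons) == 0L) {
    ph <- record@ph
    if (ph < .PH_PATH) {
      label <- 1L
    } else if (ph >= .PH_NORMAL) {
      a5 <- record@apgar5
      a10 <- record@apgar10
      ok <- !is.na(a5) && !is.na(a10) &&
        a5 >= .APGAR_BAND[1] && a5 <= .APGAR_BAND[2] &&
        a10 >= .APGAR_BAND[1] && a10 <= .APGAR_BAND[2]
      if (ok) label <- 0L else reasons <- c(reasons, "apgar_band")
    } else {
      reasons <- c(reasons, "ph_band")
    }
  }
  new("InclusionDecision", eligible = length(reasons) == 0L,
      assignedLabel = label, reasons = reasons)
}

#' Extract the final analysis window of a record
#'
#' Returns the trailing \code{minutes x 60 x rateHz} samples (7200 with the
#' defaults: the last 30 minutes at 4 Hz, where intrapartum distress is
#' expressed).
#'
#' @param record an [FHRRecord-class].
#' @param minutes window length in minutes.
#' @param rateHz sampling rate in Hz.
#' @return an [FHRRecord-class] of exactly the window length.
#' @export
extractFinalWindow <- function(record, minutes = 30, rateHz = 4) {
  n <- as.integer(round(minutes * 60 * rateHz))
  if (n < 1L) stop("window must contain at least one sample")
  len <- length(record@samples)
  if (len < n)
    stop("length error: record '", record@recordId, "' has ", len,
         " samples, need ", n)
  idx <- seq.int(len - n + 1L, len)
  initialize(record, samples = record@samples[idx],
             missingMask = record@missingMask[idx])
}

#' Fill missing samples by linear interpolation
#'
#' Interior gaps are linearly interpolated between the flanking valid
#' samples; leading/trailing gaps take the nearest valid value. This is a
#' deterministic, parameter-free stand-in for dictionary-learning signal
#' reconstruction; with at most 10\% missingness (the inclusion rule) the
#' difference is limited to short gap interiors. The missingness mask is
#' preserved for audit, so the operation is idempotent.
#'
#' @param record an [FHRRecord-class].
#' @return an [FHRRecord-class] with all samples finite.
#' @examples
#' r <- FHRRecord(c(130, NA, 150))
#' fhrSamples(fillMissing(r))
#' @export
fillMissing <- function(record) {
  v <- record@samples
  obs <- which(!record@missingMask)
  if (length(obs) == 0L)
    stop("unrecoverable record '", record@recordId, "': all samples missing")
  if (length(obs) < length(v)) {
    v <- stats::approx(obs, v[obs], xout = seq_along(v), method = "linear",
                       rule = 2)$y
  }
  initialize(record, samples = v)
}
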