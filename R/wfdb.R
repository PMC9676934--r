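#' @include fhr_io.R
NULL

# Minimal WFDB support (no wfdb library exists for R): header parsing plus
# format-16 signal files, which covers the CTU-UHB cardiotocography layout
# (FHR is the first signal channel; pH/Apgar live in '#' header comments).

.parse_wfdb_header <- function(heaPath) {
  lines <- readLines(heaPath, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  comments <- grep("^#", lines, value = TRUE)
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  if (length(lines) < 2L)
    stop("format error: WFDB header needs a record line and signal lines: ",
         heaPath)
  rl <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rl[2])
  fs <- if (length(rl) >= 3) as.numeric(rl[3]) else 250
  nsamp <- if (length(rl) >= 4) as.integer(rl[4]) else NA_integer_
  sig <- lapply(lines[1 + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- as.integer(sub("x.*$", "", f[2]))
    gainfield <- if (length(f) >= 3) f[3] else "200"
    gain <- suppressWarnings(as.numeric(sub("[(/].*$", "", gainfield)))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- NA_real_
    if (grepl("\\(", gainfield))
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainfield))
    adczero <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0
    if (is.na(baseline)) baseline <- if (is.na(adczero)) 0 else adczero
    list(file = f[1], fmt = fmt, gain = gain, baseline = baseline,
         desc = if (length(f) >= 9) paste(f[-(1:8)], collapse = " ") else "")
  })
  meta <- list(ph = NA_real_, apgar5 = NA_integer_, apgar10 = NA_integer_)
  for (cm in comments) {
    kv <- strsplit(trimws(sub("^#", "", cm)), "\\s+")[[1]]
    if (length(kv) < 2) next
    key <- tolower(kv[1])
    if (key == "ph") meta$ph <- as.numeric(kv[2])
    if (key == "apgar5") meta$apgar5 <- as.integer(kv[2])
    if (key == "apgar10") meta$apgar10 <- as.integer(kv[2])
  }
  list(record = rl[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig,
       meta = meta)
}

.read_wfdb_record <- function(path, recordId = NULL) {
  heaPath <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(heaPath))
    stop("cannot read WFDB record: header not found: ", heaPath)
  hdr <- .parse_wfdb_header(heaPath)
  if (is.null(recordId)) recordId <- hdr$record
  sig1 <- hdr$signals[[1]]
  if (sig1$fmt != 16L)
    stop("format error: only WFDB format 16 is supported (got ", sig1$fmt, ")")
  datPath <- file.path(dirname(heaPath), sig1$file)
  if (!file.exists(datPath))
    stop("cannot read WFDB record: signal file not found: ", datPath)
  nTot <- file.info(datPath)$size %/% 2L
  raw <- readBin(datPath, what = "integer", n = nTot, size = 2L,
                 signed = TRUE, endian = "little")
  # format 16 interleaves samples across signals
  adc <- raw[seq.int(1L, length(raw), by = hdr$nsig)]
  if (!is.na(hdr$nsamp)) adc <- adc[seq_len(min(hdr$nsamp, length(adc)))]
  vals <- (adc - sig1$baseline) / sig1$gain
  .record_from_raw(vals, recordId, ph = hdr$meta$ph,
                   apgar5 = hdr$meta$apgar5, apgar10 = hdr$meta$apgar10)
}

# Write a record in WFDB format 16 (single FHR channel). Used for fixtures
# and round-trip tests; missing samples are written as physical 0.
.write_wfdb_record <- function(record, dir, gain = 4, baseline = 0) {
  id <- record@recordId
  v <- record@samples
  v[record@missingMask] <- 0
  adc <- as.integer(round(v * gain + baseline))
  heaPath <- file.path(dir, paste0(id, ".hea"))
  datPath <- file.path(dir, paste0(id, ".dat"))
  hea <- c(
    sprintf("%s 1 %g %d", id, record@rateHz, length(adc)),
    sprintf("%s.dat 16 %g(%g)/bpm 16 0 %d 0 0 FHR", id, gain, baseline,
            adc[1]),
    if (!is.na(record@ph)) sprintf("#pH %.2f", record@ph),
    if (!is.na(record@apgar5)) sprintf("#Apgar5 %d", record@apgar5),
    if (!is.na(record@apgar10)) sprintf("#Apgar10 %d", record@apgar10)
  )
  writeLines(hea, heaPath)
  writeBin(adc, datPath, size = 2L, endian = "little")
  invisible(file.path(dir, id))
}
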