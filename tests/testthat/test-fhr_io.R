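test_that("CSV reader handles clean, missing and malformed traces", {
  d <- withr::local_tempdir()
  f <- file.path(d, "r1.csv")

  writeLines(c("fhr", format(rep(140, 7200))), f)
  rec <- readFHRRecord(f)
  expect_s4_class(rec, "FHRRecord")
  expect_identical(length(fhrSamples(rec)), 7200L)
  expect_identical(missingFraction(rec), 0)
  expect_identical(samplingRate(rec), 4)

  v <- rep(140, 7200)
  v[sample.int(7200, 720)] <- 0 # the missing-sample encoding
  writeLines(format(v), f)      # headerless dialect is also accepted
  rec <- readFHRRecord(f)
  expect_equal(missingFraction(rec), 0.10)

  writeLines(c("fhr", "140", "NaN", "150"), f)
  expect_equal(missingMask(readFHRRecord(f)), c(FALSE, TRUE, FALSE))

  writeLines(character(), f)
  expect_error(readFHRRecord(f), "empty")
  writeLines(c("140", "oops", "150"), f)
  expect_error(readFHRRecord(f), "format error")
  expect_error(readFHRRecord(file.path(d, "absent.csv")), "not found")
})

test_that("implausible sample values are flagged as signal loss", {
  d <- withr::local_tempdir()
  f <- file.path(d, "r2.csv")
  writeLines(c("fhr", "140", "10", "320", "150"), f)
  rec <- readFHRRecord(f)
  expect_equal(missingMask(rec), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("inclusion criteria implement the pH/Apgar/missingness rules", {
  mk <- function(ph = NA, a5 = NA, a10 = NA, missFrac = 0, n = 7200) {
    v <- rep(140, n)
    mask <- rep(FALSE, n)
    if (missFrac > 0) mask[seq_len(round(missFrac * n))] <- TRUE
    FHRRecord(v, missingMask = mask, ph = ph, apgar5 = a5, apgar10 = a10)
  }
  dec <- applyInclusionCriteria(mk(7.20, 9, 10, 0.05))
  expect_true(dec@eligible)
  expect_identical(dec@assignedLabel, 0L)

  dec <- applyInclusionCriteria(mk(7.00, missFrac = 0.05))
  expect_true(dec@eligible)
  expect_identical(dec@assignedLabel, 1L)

  dec <- applyInclusionCriteria(mk(7.10, 9, 10))
  expect_false(dec@eligible)
  expect_identical(dec@reasons, "ph_band")

  dec <- applyInclusionCriteria(mk(7.20, 8, 10))
  expect_false(dec@eligible)
  expect_identical(dec@reasons, "apgar_band")

  dec <- applyInclusionCriteria(mk(7.20, 9, 10, missFrac = 0.11))
  expect_false(dec@eligible)
  expect_true("missingness" %in% dec@reasons)

  dec <- applyInclusionCriteria(mk(7.20, 9, 10, n = 7000))
  expect_false(dec@eligible)
  expect_true("length" %in% dec@reasons)

  expect_error(applyInclusionCriteria(mk(NA, 9, 10)), "metadata error")
})

test_that("inclusion decisions partition the metadata grid into three outcomes", {
  for (ph in c(6.9, 7.0, 7.049, 7.05, 7.10, 7.149, 7.15, 7.2, 7.35)) {
    for (a5 in c(5L, 8L, 9L, 10L)) {
      for (a10 in c(5L, 9L, 10L)) {
        rec <- FHRRecord(rep(140, 7200), ph = ph, apgar5 = a5, apgar10 = a10)
        dec <- applyInclusionCriteria(rec)
        if (dec@eligible) {
          expect_true(dec@assignedLabel %in% c(0L, 1L))
          expect_length(dec@reasons, 0L)
          if (dec@assignedLabel == 1L) expect_lt(ph, 7.05)
          if (dec@assignedLabel == 0L) {
            expect_gte(ph, 7.15)
            expect_true(all(c(a5, a10) %in% 9:10))
          }
        } else {
          expect_true(is.na(dec@assignedLabel))
          expect_gt(length(dec@reasons), 0L)
        }
      }
    }
  }
})

test_that("final-window extraction returns the trailing 30 minutes", {
  v <- seq_len(14400) %% 100 + 120
  rec <- FHRRecord(v, recordId = "w")
  win <- extractFinalWindow(rec)
  expect_identical(length(fhrSamples(win)), 7200L)
  expect_identical(fhrSamples(win), v[7201:14400])

  same <- FHRRecord(v[1:7200])
  expect_identical(fhrSamples(extractFinalWindow(same)), v[1:7200])
  # idempotence
  expect_identical(fhrSamples(extractFinalWindow(win)), fhrSamples(win))

  expect_error(extractFinalWindow(FHRRecord(rep(140, 7199))), "length error")
})

test_that("gap filling interpolates interior gaps and pads edges", {
  r <- FHRRecord(c(130, NA, 150))
  expect_equal(fhrSamples(fillMissing(r)), c(130, 140, 150))

  r <- FHRRecord(c(NA, NA, 140, 150))
  expect_equal(fhrSamples(fillMissing(r)), c(140, 140, 140, 150))

  r <- FHRRecord(c(130, 135, NA, NA))
  expect_equal(fhrSamples(fillMissing(r)), c(130, 135, 135, 135))

  clean <- FHRRecord(c(130, 140, 150))
  expect_identical(fhrSamples(fillMissing(clean)), fhrSamples(clean))

  # mask preserved, operation idempotent
  r <- FHRRecord(c(130, NA, 150, NA, 140))
  f1 <- fillMissing(r)
  expect_identical(missingMask(f1), missingMask(r))
  expect_identical(fhrSamples(fillMissing(f1)), fhrSamples(f1))

  expect_error(fillMissing(FHRRecord(rep(NA_real_, 5))), "unrecoverable")
})

test_that("WFDB format-16 records round-trip with metadata", {
  d <- withr::local_tempdir()
  set.seed(7)
  v <- round(runif(1200, 110, 170), 2)
  mask <- runif(1200) < 0.05
  rec <- FHRRecord(v, missingMask = mask, recordId = "wf01", ph = 7.21,
                   apgar5 = 9L, apgar10 = 10L)
  ctgfusion:::.write_wfdb_record(rec, d, gain = 100)
  back <- readFHRRecord(file.path(d, "wf01"), format = "wfdb")
  expect_identical(recordId(back), "wf01")
  expect_identical(missingMask(back), mask)
  expect_equal(fhrSamples(back)[!mask], v[!mask], tolerance = 1 / 100)
  expect_equal(phValue(back), 7.21)
  expect_identical(apgarScores(back), c(apgar5 = 9L, apgar10 = 10L))
  expect_error(readFHRRecord(file.path(d, "nope"), format = "wfdb"),
               "not found")
})

test_that("clinical metadata attaches to records by id", {
  d <- withr::local_tempdir()
  md <- data.frame(record_id = "r9", ph = 7.3, apgar5 = 9L, apgar10 = 9L,
                   label = 0L)
  writeClinicalMetadata(md, file.path(d, "metadata.csv"))
  back <- readClinicalMetadata(file.path(d, "metadata.csv"))
  f <- file.path(d, "r9.csv")
  writeFHRCsv(FHRRecord(rep(140, 100), recordId = "r9"), f)
  rec <- readFHRRecord(f, metadata = back)
  expect_equal(phValue(rec), 7.3)
  expect_identical(recordLabel(rec), 0L)
})
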