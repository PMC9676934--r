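test_that("unit rescaling maps extremes to -1/+1 and constants to zero", {
  expect_equal(rescaleToUnit(c(0, 5, 10)), c(-1, 0, 1))
  expect_equal(rescaleToUnit(c(140, 140, 140)), c(0, 0, 0))
  expect_equal(rescaleToUnit(c(120, 160)), c(-1, 1))
  expect_error(rescaleToUnit(numeric()), "empty")
  expect_error(rescaleToUnit(c(1, NA)), "finite")
})

test_that("PAA reduces to segment means, with fractional boundary weights", {
  expect_equal(paa(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  x <- rnorm(10)
  expect_identical(paa(x, 10), x)       # identity
  expect_equal(paa(x, 1), mean(x))      # single segment

  set.seed(42)
  for (L in c(7L, 10L, 13L, 24L)) {
    x <- runif(L, -1, 1)
    for (d in c(2L, 3L, 5L, L - 1L)) {
      expect_equal(paa(x, d), bruteForcePAA(x, d), tolerance = 1e-12,
                   label = sprintf("paa L=%d d=%d", L, d))
    }
    expect_true(all(abs(paa(x, 3)) <= 1))  # stays in range
  }
  expect_error(paa(x, 0), "value error")
  expect_error(paa(x, length(x) + 1), "value error")
})

test_that("the PAA schedule spans start..stop inclusive by a fixed step", {
  s <- paaSchedule()
  expect_length(s, 40L)
  expect_identical(s[1], 7200L)
  expect_identical(s[40], 180L)
  expect_true(all(diff(s) == -180L))
  expect_identical(paaSchedule(360, 360, 180, 180), c(360L, 180L))
  expect_identical(paaSchedule(180, 180, 180, 180), 180L)
  expect_error(paaSchedule(7200, 7200, 170, 180), "divisible")
  expect_error(paaSchedule(100, 360, 180, 180), "signal length")
})

test_that("GADF matches the angular-difference oracle and its algebra", {
  expect_equal(gadf(c(1, 0)), matrix(c(0, 1, -1, 0), 2))
  set.seed(11)
  for (k in 1:20) {
    x <- runif(sample(3:64, 1), -1, 1)
    M <- gadf(x)
    phi <- acos(x)
    expect_lt(max(abs(M - outer(phi, phi, function(a, b) sin(a - b)))), 1e-9)
    expect_lt(max(abs(M + t(M))), 1e-9)   # antisymmetry
    expect_lt(max(abs(diag(M))), 1e-9)    # zero diagonal
    expect_true(all(M >= -1 & M <= 1))
  }
  expect_error(gadf(c(0.5, 1.1)), "domain error")
  expect_silent(gadf(c(1 + 1e-10, -1)))   # rounding clamp
})

test_that("rendering maps to [0,1], replicates channels and resizes bilinearly", {
  set.seed(3)
  m <- gadf(runif(30, -1, 1))
  img <- renderImage(m, 224)
  expect_identical(dim(img), c(224L, 224L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(img[, , 1], img[, , 2])
  expect_identical(img[, , 1], img[, , 3])

  # identity resize: a 224x224 input is an exact affine map of the entries
  m224 <- gadf(runif(224, -1, 1))
  out <- renderImage(m224, 224)
  expect_equal(out[, , 1], (m224 + 1) / 2, tolerance = 1e-12)

  expect_error(renderImage(m, 0), "value error")
})

test_that("a record becomes one image per schedule dimension, deterministically", {
  rec <- fillMissing(generateRecord(0, synthPreset(0, seed = 5),
                                    nSamples = 360L))
  st <- recordToStack(rec, schedule = c(360L, 180L), size = 32)
  expect_s4_class(st, "GADFStack")
  expect_identical(nImages(st), 2L)
  expect_identical(stackDims(st), c(360L, 180L))
  expect_identical(recordId(st), recordId(rec))

  st2 <- recordToStack(rec, schedule = c(360L, 180L), size = 32)
  expect_identical(stackImages(st), stackImages(st2))

  raw <- FHRRecord(rep(c(120, 160), 50))
  expect_error(recordToStack(raw, schedule = c(200L)), "length error")
  gap <- FHRRecord(c(130, NA, 150))
  expect_error(recordToStack(gap, schedule = c(3L)), "missing samples")
})

test_that("the imaging pipeline is invariant to positive affine rescaling", {
  rec <- fillMissing(generateRecord(0, synthPreset(0, seed = 9),
                                    nSamples = 360L))
  v <- fhrSamples(rec)
  shifted <- FHRRecord(0.5 * v + 60, recordId = recordId(rec))
  s1 <- recordToStack(rec, schedule = c(180L), size = 32)
  s2 <- recordToStack(shifted, schedule = c(180L), size = 32)
  expect_equal(stackImages(s1), stackImages(s2), tolerance = 1e-9)
})

test_that("time reversal rotates the GADF when the dimension divides the length", {
  set.seed(13)
  x <- runif(12)
  d <- 4L
  p1 <- paa(rescaleToUnit(x), d)
  p2 <- paa(rescaleToUnit(rev(x)), d)
  expect_equal(p2, rev(p1), tolerance = 1e-12)
  J <- diag(d)[d:1, ]
  expect_equal(gadf(p2), J %*% gadf(p1) %*% J, tolerance = 1e-12)
})

test_that("stacks round-trip through the array container and PPM writer", {
  d <- withr::local_tempdir()
  rec <- fillMissing(generateRecord(1, synthPreset(1, seed = 2),
                                    nSamples = 360L))
  st <- recordToStack(rec, schedule = c(360L, 180L), size = 16)
  p <- writeStack(st, d, format = "rds")
  back <- readStack(p)
  expect_identical(stackImages(back), stackImages(st))
  expect_identical(stackDims(back), stackDims(st))

  paths <- writeStack(st, d, format = "ppm")
  expect_true(all(file.exists(file.path(d, sprintf("%s_dim%d.ppm",
                                                   recordId(st),
                                                   stackDims(st))))))
  hdr <- readBin(file.path(d, sprintf("%s_dim360.ppm", recordId(st))),
                 "raw", 20)
  expect_identical(rawToChar(hdr[1:2]), "P6")
})
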