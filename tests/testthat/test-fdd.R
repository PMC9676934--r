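# small trained-enough fixture shared by the diagnosis tests
fddFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fx <- tinyStacks(10, seed = 4)
    plan <- makeFoldPlan(data.frame(record_id = fx$ids,
                                    label = unlist(fx$labels)), seed = 4)
    f <- foldSplits(plan)[[1]]
    hy <- hyperparams(batchSize = 8L, epochs = 1L, seed = 2L)
    backbone <- trainFold(fx$stacks, fx$labels, f$train, f$val,
                          tinyConfig(0.1), hy)$model
    fdd <- buildTestModel(backbone, fx$stacks, fx$labels, f$train, hy,
                          headEpochs = 2L)
    cache <<- list(fx = fx, plan = plan, fold = f, hy = hy,
                   backbone = backbone, fdd = fdd)
    cache
  }
})

test_that("the majority-vote rule is exceed-half with a fail-safe tie", {
  vote <- ctgfusion:::.majority_label
  expect_identical(vote(21L, 40L), 1L) # > 50%
  expect_identical(vote(20L, 40L), 1L) # exact tie -> pathological
  expect_identical(vote(19L, 40L), 0L)
  expect_identical(vote(0L, 40L), 0L)  # unanimous normal
  expect_identical(vote(40L, 40L), 1L)
})

test_that("the frozen encoder receives exactly zero gradient", {
  fixt <- fddFixture()
  P <- fixt$fdd@backbone@params
  for (nm in ls(P))
    expect_identical(sum(abs(P[[nm]]$grad)), 0,
                     label = paste("frozen grad of", nm))
  # the head, by contrast, was actually trained away from its init
  set.seed(fixt$hy@seed)
  init <- new.env(parent = emptyenv())
  hs <- ctgfusion:::.head_spec(fixt$fdd@config@embedDimImage)
  for (nm in names(hs))
    init[[nm]] <- ctgfusion:::nnParam(hs[[nm]], ctgfusion:::.init_kind(nm))
  expect_gt(max(abs(fixt$fdd@head$fdd_W$val - init$fdd_W$val)), 0)
})

test_that("head fitting is deterministic given the checkpoint and seed", {
  fixt <- fddFixture()
  fdd2 <- buildTestModel(fixt$backbone, fixt$fx$stacks, fixt$fx$labels,
                         fixt$fold$train, fixt$hy, headEpochs = 2L)
  for (nm in ls(fixt$fdd@head))
    expect_identical(fdd2@head[[nm]]$val, fixt$fdd@head[[nm]]$val)
})

test_that("record diagnosis aggregates consistent per-image votes", {
  fixt <- fddFixture()
  id <- testIds(fixt$plan)[1]
  res <- diagnoseRecord(fixt$fdd, fixt$fx$stacks[[id]],
                        labelTrue = fixt$fx$labels[[id]])
  expect_s4_class(res, "DiagnosisResult")
  expect_length(res@perImageProbs, nImages(fixt$fx$stacks[[id]]))
  expect_true(all(res@perImageProbs >= 0 & res@perImageProbs <= 1))
  expect_identical(res@votesPathological, sum(res@perImageProbs > 0.5))
  expect_identical(res@labelPred,
                   ctgfusion:::.majority_label(res@votesPathological,
                                               length(res@perImageProbs)))
})

test_that("diagnosis is invariant to the image order within a stack", {
  fixt <- fddFixture()
  id <- testIds(fixt$plan)[2]
  st <- fixt$fx$stacks[[id]]
  perm <- rev(seq_len(nImages(st)))
  stPerm <- new("GADFStack", images = stackImages(st)[perm],
                dims = stackDims(st)[perm], recordId = recordId(st))
  a <- diagnoseRecord(fixt$fdd, st)
  b <- diagnoseRecord(fixt$fdd, stPerm)
  # row position inside the batched matrix products may shift the last
  # few floating-point bits, so compare probabilities with a tolerance
  expect_equal(sort(a@perImageProbs), sort(b@perImageProbs),
               tolerance = 1e-10)
  expect_identical(a@votesPathological, b@votesPathological)
  expect_identical(a@labelPred, b@labelPred)
})

# hand-constructable results for the metric tests
mkResult <- function(id, probs, truth) {
  new("DiagnosisResult", recordId = id, perImageProbs = probs,
      votesPathological = sum(probs > 0.5),
      labelPred = ctgfusion:::.majority_label(sum(probs > 0.5),
                                              length(probs)),
      labelTrue = as.integer(truth))
}

test_that("evaluation reproduces the hand-computed confusion metrics", {
  # truth [1,1,0,0], predictions [1,0,0,0]
  res <- list(mkResult("a", c(0.9, 0.8), 1), mkResult("b", c(0.4, 0.3), 1),
              mkResult("c", c(0.2, 0.1), 0), mkResult("d", c(0.35, 0.1), 0))
  m <- evaluateDiagnoses(res)
  expect_equal(m$acc, 0.75)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-12)

  # perfect classifier
  res <- list(mkResult("a", c(0.9, 0.9), 1), mkResult("b", c(0.1, 0.1), 0))
  m <- evaluateDiagnoses(res)
  expect_equal(unlist(m), c(acc = 1, f1 = 1, auc = 1))

  # constant scores: chance-level AUC
  res <- list(mkResult("a", 0.4, 1), mkResult("b", 0.4, 0),
              mkResult("c", 0.4, 1), mkResult("d", 0.4, 0))
  expect_equal(evaluateDiagnoses(res)$auc, 0.5)

  # single-class truth: AUC undefined, ACC/F1 still returned
  res <- list(mkResult("a", 0.9, 1), mkResult("b", 0.8, 1))
  expect_warning(m <- evaluateDiagnoses(res), "AUC undefined")
  expect_true(is.na(m$auc))
  expect_equal(m$acc, 1)
})

test_that("accuracy equals one minus the normalized Hamming distance", {
  set.seed(6)
  for (k in 1:5) {
    truth <- rbinom(12, 1, 0.5)
    probs <- runif(12)
    res <- lapply(seq_len(12), function(i)
      mkResult(paste0("r", i), probs[i], truth[i]))
    preds <- vapply(res, function(r) r@labelPred, 1L)
    if (length(unique(truth)) < 2) next
    m <- evaluateDiagnoses(res)
    expect_equal(m$acc, 1 - sum(preds != truth) / 12)
  }
})

test_that("the alignment R-square matches its definition", {
  expect_equal(rSquare(c(1, 0, 1, 1), c(1, 0, 1, 1)), 1)
  txt <- c(1, 0, 0, 1)
  expect_equal(rSquare(rep(mean(txt), 4), txt), 0)
  expect_equal(rSquare(c(1, 0, 1, 0), c(1, 0, 0, 0)), 1 - 1 / 0.75,
               tolerance = 1e-9)
  # continuous scores are accepted too: SS_res = 0.1, SS_tot = 1
  expect_equal(rSquare(c(0.9, 0.1, 0.2, 0.8), c(1, 0, 0, 1)), 0.9,
               tolerance = 1e-12)
  expect_error(rSquare(c(1, 0), c(1, 1)), "undefined")
  expect_error(rSquare(1, 1), "at least 2")
})

test_that("diagnosis reports round-trip through the CSV/JSON writers", {
  d <- withr::local_tempdir()
  res <- list(mkResult("a", c(0.9, 0.8), 1), mkResult("b", c(0.1, 0.2), 0))
  csv <- file.path(d, "report.csv")
  js <- file.path(d, "metrics.json")
  writeDiagnosisReport(res, csv, js)
  df <- read.csv(csv)
  expect_identical(nrow(df), 2L)
  expect_identical(df$label_pred, c(1L, 0L))
  m <- jsonlite::read_json(js)
  expect_equal(m$acc, 1)
  m2 <- cmdEvaluate(csv)
  expect_equal(m2$acc, 1)
})
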