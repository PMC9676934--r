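test_that("patchification yields the expected token grid", {
  img <- randImage(32, 1)
  Xp <- imagePatches(img, 8L)
  expect_identical(dim(Xp), c(16L, 192L))
  # first patch is the top-left 8x8 block, channels stacked
  expect_equal(Xp[1, ], as.vector(img[1:8, 1:8, ]))
  expect_error(imagePatches(img, 5L), "shape error")
  expect_identical(nPatches(modelConfig("B/16")), 196L) # (224/16)^2
  expect_identical(nPatches(modelConfig("B/32")), 49L)
})

test_that("the image encoder emits patch features and the query token", {
  m <- tinyModel()
  img <- randImage(32, 2)
  enc <- imageEncode(m, img)
  expect_identical(dim(enc$imgEmbeds), c(16L, 16L))
  expect_identical(dim(enc$imgQuery), c(1L, 16L))
  expect_true(all(is.finite(enc$imgEmbeds)))
  # eval-mode determinism
  enc2 <- imageEncode(m, img)
  expect_identical(enc$imgEmbeds, enc2$imgEmbeds)
  expect_identical(enc$imgQuery, enc2$imgQuery)
  expect_error(imageEncode(m, randImage(16, 1)), "shape error")
})

test_that("the unimodal text decoder is causal and label-sensitive", {
  m <- tinyModel()
  td0 <- textDecodeUnimodal(m, tokenizeCaption(makeCaption(0)))
  td1 <- textDecodeUnimodal(m, tokenizeCaption(makeCaption(1)))
  expect_identical(dim(td0$textEmbeds), c(4L, 16L))
  expect_identical(dim(td0$classText), c(1L, 16L))
  # the two templates produce different class-text tokens after random init
  expect_gt(max(abs(td0$classText - td1$classText)), 1e-6)
  expect_error(textDecodeUnimodal(m, 1:3), "shape error")
})

test_that("the multimodal decoder honours the class-token contracts", {
  m <- tinyModel()
  b <- encodeBundle(m, randImage(32, 3), 1)
  expect_s4_class(b, "EmbeddingBundle")
  fo <- mranForward(m, b)
  expect_s4_class(fo, "FusionOutput")
  expect_identical(dim(fo@classImg), c(1L, 16L))
  expect_identical(dim(fo@classMul), c(1L, 16L))
  # joint sequence length equals the text-stream length (class + 4 tokens)
  expect_identical(nrow(fo@mulEmbeds), 5L)
  # eval-mode determinism
  fo2 <- mranForward(m, b)
  expect_identical(fo@mulEmbeds, fo2@mulEmbeds)
})

test_that("cross-attention blocks preserve the query-sequence shape", {
  m <- tinyModel()
  set.seed(5)
  x <- matrix(rnorm(10 * 16), 10, 16)
  # degenerate window spanning the whole sequence, self-context
  out <- cabForward(m, x, context = NULL, which = "stage1", window = 10L)
  expect_identical(dim(out), dim(x))
  # output length equals input length for any context length
  for (nc in c(1L, 4L, 23L)) {
    ctx <- matrix(rnorm(nc * 16), nc, 16)
    expect_identical(dim(cabForward(m, x, ctx, which = "stage1")), dim(x))
  }
  expect_error(cabForward(m, x, matrix(0, 3, 8), which = "stage1"),
               "shape error")
})

test_that("with zeroed value projections the CPSA stage is context-blind", {
  m <- tinyModel(seed = 7)
  m@params$mran_s1_cab_cpsa_Wv$val[] <- 0
  m@params$mran_s1_cab_cpsa_bv$val[] <- 0
  set.seed(8)
  x <- matrix(rnorm(6 * 16), 6, 16)
  o0 <- cabForward(m, x, context = matrix(0, 4, 16), which = "stage1")
  o1 <- cabForward(m, x, context = matrix(rnorm(4 * 16), 4, 16),
                   which = "stage1")
  expect_equal(o0, o1, tolerance = 1e-12) # only the residual survives
})

test_that("forward passes stay finite over many random inputs", {
  cfg <- modelConfig("custom", imageSize = 16, patchSize = 8,
                     embedDimImage = 8, embedDimText = 8, encoderDepth = 1,
                     unimodalDecoderDepth = 1, multimodalDecoderDepth = 1,
                     headsImage = 2, headsText = 2, dropout = 0)
  hy <- hyperparams(seed = 1)
  for (s in 1:100) {
    set.seed(s)
    m <- if (s %% 10 == 1) newMMIFModel(cfg, seed = s) else m
    img <- array(runif(16 * 16 * 3), c(16, 16, 3))
    tape <- ctgfusion:::ad_tape()
    Xp <- ctgfusion:::ad_const(tape, imagePatches(img, 8L))
    ids <- matrix(tokenizeCaption(makeCaption(s %% 2)), 1)
    fw <- ctgfusion:::.fwd_mmif(tape, m, Xp, ids, s %% 2, hy, training = FALSE)
    expect_true(is.finite(fw$loss$val))
    expect_true(all(is.finite(fw$mran$stream$val)))
  }
})

test_that("gradient reaches every learnable tensor", {
  m <- tinyModel(seed = 3)
  hy <- hyperparams(seed = 1)
  imgs <- list(imagePatches(randImage(32, 1), 8L),
               imagePatches(randImage(32, 2), 8L))
  ids <- rbind(tokenizeCaption(makeCaption(0)), tokenizeCaption(makeCaption(1)))
  tape <- ctgfusion:::ad_tape()
  Xp <- ctgfusion:::ad_const(tape, do.call(rbind, imgs))
  fw <- ctgfusion:::.fwd_mmif(tape, m, Xp, ids, c(0L, 1L), hy,
                              training = FALSE)
  ctgfusion:::ad_backward(tape, fw$loss)
  P <- m@params
  for (nm in ls(P))
    expect_gt(sum(abs(P[[nm]]$grad)), 0, label = paste("grad of", nm))
})

test_that("backpropagation matches finite differences", {
  m <- tinyModel(seed = 4)
  hy <- hyperparams(seed = 1)
  imgs <- list(imagePatches(randImage(32, 4), 8L),
               imagePatches(randImage(32, 5), 8L))
  ids <- rbind(tokenizeCaption(makeCaption(0)), tokenizeCaption(makeCaption(1)))
  lossAt <- function(backward = FALSE) {
    tape <- ctgfusion:::ad_tape()
    Xp <- ctgfusion:::ad_const(tape, do.call(rbind, imgs))
    fw <- ctgfusion:::.fwd_mmif(tape, m, Xp, ids, c(0L, 1L), hy,
                                training = FALSE)
    if (backward) ctgfusion:::ad_backward(tape, fw$loss)
    fw$loss$val
  }
  lossAt(backward = TRUE)
  eps <- 1e-5
  for (nm in c("img_query", "txt_cls", "enc1_attn_Wq", "tdec1_mlp_W1",
               "mran_s1_cab_cpsa_Wv", "mran1_cab_ipsa1_Wo", "con_proj_W",
               "cap_W", "txt_embed", "enc_head_ln_g")) {
    p <- m@params[[nm]]
    i <- which.max(abs(p$grad))
    g <- p$grad[i]
    v0 <- p$val[i]
    p$val[i] <- v0 + eps
    l1 <- lossAt()
    p$val[i] <- v0 - eps
    l2 <- lossAt()
    p$val[i] <- v0
    fd <- (l1 - l2) / (2 * eps)
    expect_lt(abs(g - fd) / max(abs(fd), 1e-6), 1e-4,
              label = paste("finite-difference check of", nm))
  }
})

test_that("parameter counts order the architecture variants", {
  b16 <- modelConfig("B/16")
  l16 <- modelConfig("L/16")
  expect_lt(nParameters(b16), nParameters(l16))
  expect_identical(nPatches(modelConfig("B/32")) * 4L,
                   nPatches(modelConfig("B/16")))
  expect_identical(nPatches(modelConfig("L/32")) * 4L,
                   nPatches(modelConfig("L/16")))
  # the analytic count agrees with an allocated model
  cfg <- tinyConfig()
  expect_identical(nParameters(newMMIFModel(cfg, 1)), nParameters(cfg))
})

test_that("checkpoints round-trip weights, config and vocabulary", {
  d <- withr::local_tempdir()
  m <- tinyModel(seed = 9)
  p <- file.path(d, "ck.rds")
  saveCheckpoint(m, p)
  back <- loadCheckpoint(p)
  expect_identical(back@config, m@config)
  expect_identical(back@vocab, m@vocab)
  for (nm in ls(m@params))
    expect_identical(back@params[[nm]]$val, m@params[[nm]]$val)
  # schema guard
  bad <- readRDS(p)
  bad$schema <- "other-schema"
  saveRDS(bad, p)
  expect_error(loadCheckpoint(p), "compatibility error")
})

test_that("the full-size encoder obeys the 196-token geometry", {
  cfg <- modelConfig("B/16", encoderDepth = 1L, unimodalDecoderDepth = 1L,
                     multimodalDecoderDepth = 1L)
  m <- newMMIFModel(cfg, seed = 1)
  set.seed(6)
  img <- array(runif(224 * 224 * 3), c(224, 224, 3))
  enc <- imageEncode(m, img)
  expect_identical(dim(enc$imgEmbeds), c(196L, 768L))
  expect_identical(dim(enc$imgQuery), c(1L, 768L))
})
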