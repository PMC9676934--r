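#' @include attention.R captions.R
NULL

.CKPT_SCHEMA <- "ctgfusion-checkpoint-1"

# ---------------------------------------------------------------------------
# Parameter specification. A single source of truth: newMMIFModel() allocates
# from it and nParameters(ModelConfig) sums it, so the analytic count can
# never drift from the allocated model.
# ---------------------------------------------------------------------------

.attn_spec <- function(prefix, dq, dkv = dq) {
  out <- list(c(dq, dq), dq, c(dkv, dq), dq, c(dkv, dq), dq, c(dq, dq), dq)
  names(out) <- paste0(prefix, c("_Wq", "_bq", "_Wk", "_bk", "_Wv", "_bv",
                                 "_Wo", "_bo"))
  out
}

.ln_spec <- function(prefix, d) {
  out <- list(d, d)
  names(out) <- paste0(prefix, c("_g", "_b"))
  out
}

.mlp_spec <- function(prefix, d, r) {
  dh <- as.integer(round(r * d))
  out <- list(c(d, dh), dh, c(dh, d), d)
  names(out) <- paste0(prefix, c("_W1", "_b1", "_W2", "_b2"))
  out
}

.cab_spec <- function(prefix, dx, dctx = dx) {
  c(.ln_spec(paste0(prefix, "_ipsa1_ln"), dx),
    .attn_spec(paste0(prefix, "_ipsa1"), dx),
    .ln_spec(paste0(prefix, "_cpsa_ln"), dx),
    .attn_spec(paste0(prefix, "_cpsa"), dx, dctx),
    .ln_spec(paste0(prefix, "_ipsa2_ln"), dx),
    .attn_spec(paste0(prefix, "_ipsa2"), dx))
}

.decoder_spec <- function(prefix, d, r) {
  c(.ln_spec(paste0(prefix, "_ln1"), d), .attn_spec(paste0(prefix, "_attn1"), d),
    .ln_spec(paste0(prefix, "_ln2"), d), .attn_spec(paste0(prefix, "_attn2"), d),
    .ln_spec(paste0(prefix, "_ln3"), d), .mlp_spec(paste0(prefix, "_mlp"), d, r))
}

.param_spec <- function(cfg) {
  di <- cfg@embedDimImage
  dt <- cfg@embedDimText
  np <- nPatches(cfg)
  pin <- as.integer(cfg@patchSize^2 * 3L)
  r <- cfg@mlpRatio
  sp <- list(txt_embed = c(5L, dt), txt_pos = c(4L, dt), txt_cls = c(1L, dt),
             enc_patch_W = c(pin, di), enc_patch_b = di,
             enc_pos = c(np, di), img_query = c(1L, di))
  for (l in seq_len(cfg@encoderDepth)) {
    pfx <- paste0("enc", l)
    sp <- c(sp, .ln_spec(paste0(pfx, "_ln1"), di),
            .attn_spec(paste0(pfx, "_attn"), di),
            .ln_spec(paste0(pfx, "_ln2"), di),
            .mlp_spec(paste0(pfx, "_mlp"), di, r))
  }
  sp <- c(sp, .ln_spec("enc_head_ln", di),
          list(enc_head_W = c(di, di), enc_head_b = di))
  for (l in seq_len(cfg@unimodalDecoderDepth))
    sp <- c(sp, .decoder_spec(paste0("tdec", l), dt, r))
  sp <- c(sp, list(tdec_out_W = c(dt, dt), tdec_out_b = dt))
  sp <- c(sp, .cab_spec("mran_s1_cab", di), .ln_spec("mran_s1_ln", di),
          list(mran_proj_W = c(di, dt), mran_proj_b = dt))
  for (l in seq_len(cfg@multimodalDecoderDepth))
    sp <- c(sp, .decoder_spec(paste0("mran", l, "_dec"), dt, r),
            .cab_spec(paste0("mran", l, "_cab"), dt))
  sp <- c(sp, .ln_spec("mran_out_ln", dt),
          list(con_proj_W = c(di, dt), con_proj_b = dt,
               cap_W = c(dt, 2L), cap_b = 2L))
  sp
}

.init_kind <- function(name) {
  if (grepl("_g$", name)) return("ones")
  if (grepl("(_b|_b1|_b2|_bq|_bk|_bv|_bo)$", name)) return("zeros")
  # token/position/vocabulary embeddings: truncated normal (ViT convention);
  # weight matrices: Glorot, which keeps activation scale stable at small d
  if (grepl("^(txt_embed|txt_pos|txt_cls|enc_pos|img_query)$", name))
    return("trunc_normal")
  "xavier"
}

#' @describeIn ModelConfig total learnable parameter count of the
#'   architecture (computed from the layer specification without
#'   allocating a model).
#' @export
setMethod("nParameters", "ModelConfig", function(x) {
  sum(vapply(.param_spec(x), prod, 1))
})

#' Create a fresh multimodal model
#'
#' Allocates all learnable tensors of the parallel image-encoder /
#' text-decoder backbone and the multimodal alignment decoder, initialized
#' with truncated-normal weights (sd 0.02), unit LayerNorm gains and zero
#' biases. Initialization is fully determined by \code{seed}.
#'
#' @param config a [ModelConfig-class].
#' @param seed integer RNG seed.
#' @return an [MMIFModel-class].
#' @examples
#' m <- newMMIFModel(modelConfig("custom", imageSize = 32, patchSize = 8,
#'   embedDimImage = 16, embedDimText = 16, encoderDepth = 1,
#'   unimodalDecoderDepth = 1, multimodalDecoderDepth = 1,
#'   headsImage = 2, headsText = 2), seed = 1)
#' nParameters(m)
#' @export
newMMIFModel <- function(config, seed = 1L) {
  set.seed(seed)
  sp <- .param_spec(config)
  P <- new.env(parent = emptyenv())
  for (nm in names(sp))
    P[[nm]] <- nnParam(sp[[nm]], init = .init_kind(nm))
  new("MMIFModel", config = config, params = P, vocab = ctgVocabulary(),
      schema = .CKPT_SCHEMA)
}

# ---------------------------------------------------------------------------
# Forward builders (tape-based)
# ---------------------------------------------------------------------------

.fwd_mha <- function(tape, P, prefix, xq, xkv, B, h, mask, scale, dropout,
                     training) {
  q <- ad_linear(tape, xq, P[[paste0(prefix, "_Wq")]], P[[paste0(prefix, "_bq")]])
  k <- ad_linear(tape, xkv, P[[paste0(prefix, "_Wk")]], P[[paste0(prefix, "_bk")]])
  v <- ad_linear(tape, xkv, P[[paste0(prefix, "_Wv")]], P[[paste0(prefix, "_bv")]])
  o <- ad_sdpa(tape, q, k, v, B, h, mask, scale)
  o <- ad_linear(tape, o, P[[paste0(prefix, "_Wo")]], P[[paste0(prefix, "_bo")]])
  ad_dropout(tape, o, dropout, training)
}

.fwd_mlp <- function(tape, P, prefix, x, dropout, training) {
  h <- ad_linear(tape, x, P[[paste0(prefix, "_W1")]], P[[paste0(prefix, "_b1")]])
  h <- ad_gelu(tape, h)
  h <- ad_linear(tape, h, P[[paste0(prefix, "_W2")]], P[[paste0(prefix, "_b2")]])
  ad_dropout(tape, h, dropout, training)
}

.fwd_encoder_block <- function(tape, P, prefix, x, B, h, cfg, training) {
  hn <- ad_layernorm(tape, x, P[[paste0(prefix, "_ln1_g")]],
                     P[[paste0(prefix, "_ln1_b")]])
  x <- ad_add(tape, x, .fwd_mha(tape, P, paste0(prefix, "_attn"), hn, hn, B,
                                h, NULL, cfg@scale, cfg@dropout, training))
  hn <- ad_layernorm(tape, x, P[[paste0(prefix, "_ln2_g")]],
                     P[[paste0(prefix, "_ln2_b")]])
  ad_add(tape, x, .fwd_mlp(tape, P, paste0(prefix, "_mlp"), hn, cfg@dropout,
                           training))
}

.fwd_decoder_block <- function(tape, P, prefix, x, B, n, h, cfg, training) {
  cmask <- causalMask(n)
  hn <- ad_layernorm(tape, x, P[[paste0(prefix, "_ln1_g")]],
                     P[[paste0(prefix, "_ln1_b")]])
  x <- ad_add(tape, x, .fwd_mha(tape, P, paste0(prefix, "_attn1"), hn, hn, B,
                                h, cmask, cfg@scale, cfg@dropout, training))
  hn <- ad_layernorm(tape, x, P[[paste0(prefix, "_ln2_g")]],
                     P[[paste0(prefix, "_ln2_b")]])
  x <- ad_add(tape, x, .fwd_mha(tape, P, paste0(prefix, "_attn2"), hn, hn, B,
                                h, NULL, cfg@scale, cfg@dropout, training))
  hn <- ad_layernorm(tape, x, P[[paste0(prefix, "_ln3_g")]],
                     P[[paste0(prefix, "_ln3_b")]])
  ad_add(tape, x, .fwd_mlp(tape, P, paste0(prefix, "_mlp"), hn, cfg@dropout,
                           training))
}

# Cross-attention block: IPSA (windowed local self-attention), CPSA
# (attention from x onto the context stream), IPSA again, each with a
# residual around a pre-LayerNorm sublayer.
.fwd_cab <- function(tape, P, prefix, x, ctx, B, nx, h, cfg, training,
                     window = cfg@ipsaWindow) {
  wm <- windowMask(nx, window)
  hn <- ad_layernorm(tape, x, P[[paste0(prefix, "_ipsa1_ln_g")]],
                     P[[paste0(prefix, "_ipsa1_ln_b")]])
  x <- ad_add(tape, x, .fwd_mha(tape, P, paste0(prefix, "_ipsa1"), hn, hn, B,
                                h, wm, cfg@scale, cfg@dropout, training))
  hn <- ad_layernorm(tape, x, P[[paste0(prefix, "_cpsa_ln_g")]],
                     P[[paste0(prefix, "_cpsa_ln_b")]])
  kv <- if (is.null(ctx)) hn else ctx
  x <- ad_add(tape, x, .fwd_mha(tape, P, paste0(prefix, "_cpsa"), hn, kv, B,
                                h, NULL, cfg@scale, cfg@dropout, training))
  hn <- ad_layernorm(tape, x, P[[paste0(prefix, "_ipsa2_ln_g")]],
                     P[[paste0(prefix, "_ipsa2_ln_b")]])
  ad_add(tape, x, .fwd_mha(tape, P, paste0(prefix, "_ipsa2"), hn, hn, B, h,
                           wm, cfg@scale, cfg@dropout, training))
}

# image encoder: patch embed + positions -> blocks (the learnable image
# query is appended before the final block) -> LayerNorm + MLP head
.fwd_image_encoder <- function(tape, P, cfg, XpNode, B, training) {
  np <- nPatches(cfg)
  x <- ad_bias(tape, ad_matmul(tape, XpNode, ad_param(tape, P$enc_patch_W)),
               ad_param(tape, P$enc_patch_b))
  x <- ad_positional(tape, x, P$enc_pos, B, np)
  x <- ad_dropout(tape, x, cfg@dropout, training)
  n <- np
  for (l in seq_len(cfg@encoderDepth)) {
    if (l == cfg@encoderDepth) {
      x <- ad_insert_token(tape, x, P$img_query, B, n, "back")
      n <- n + 1L
    }
    x <- .fwd_encoder_block(tape, P, paste0("enc", l), x, B,
                            cfg@headsImage, cfg, training)
  }
  x <- ad_layernorm(tape, x, P$enc_head_ln_g, P$enc_head_ln_b)
  x <- ad_linear(tape, x, P$enc_head_W, P$enc_head_b)
  list(node = x, n = n)
}

# unimodal text decoder: embedding + positions, [class_text] prepended,
# causal decoder blocks (no cross-attention to the image side), final linear
.fwd_text_decoder <- function(tape, P, cfg, ids, B, training) {
  x <- ad_embed(tape, P$txt_embed, as.vector(t(ids)))
  x <- ad_positional(tape, x, P$txt_pos, B, 4L)
  x <- ad_insert_token(tape, x, P$txt_cls, B, 4L, "front")
  for (l in seq_len(cfg@unimodalDecoderDepth))
    x <- .fwd_decoder_block(tape, P, paste0("tdec", l), x, B, 5L,
                            cfg@headsText, cfg, training)
  ad_linear(tape, x, P$tdec_out_W, P$tdec_out_b)
}

# multimodal alignment decoder. Stage 1 refreshes the image side through a
# CAB + LayerNorm and splits off the image class token (last row per
# sample); stage 2 alternates a decoder block on the text stream with a CAB
# against the projected image features; stage 3 normalizes and splits off
# the multimodal class token (the [class_mul] slot at the stream front).
.fwd_mran <- function(tape, P, cfg, imgTok, txtTok, B, nImg, training) {
  s1 <- .fwd_cab(tape, P, "mran_s1_cab", imgTok, NULL, B, nImg,
                 cfg@headsImage, cfg, training)
  s1 <- ad_layernorm(tape, s1, P$mran_s1_ln_g, P$mran_s1_ln_b)
  last <- seq_len(B) * nImg
  Img <- ad_rows(tape, s1, last)
  Xin <- ad_rows(tape, s1, setdiff(seq_len(B * nImg), last))
  Xproj <- ad_linear(tape, Xin, P$mran_proj_W, P$mran_proj_b)
  stream <- txtTok
  for (l in seq_len(cfg@multimodalDecoderDepth)) {
    stream <- .fwd_decoder_block(tape, P, paste0("mran", l, "_dec"), stream,
                                 B, 5L, cfg@headsText, cfg, training)
    stream <- .fwd_cab(tape, P, paste0("mran", l, "_cab"), stream, Xproj, B,
                       5L, cfg@headsText, cfg, training)
  }
  stream <- ad_layernorm(tape, stream, P$mran_out_ln_g, P$mran_out_ln_b)
  Mul <- ad_rows(tape, stream, (seq_len(B) - 1L) * 5L + 1L)
  list(stream = stream, Mul = Mul, Img = Img)
}

# full training/eval forward: returns loss nodes and intermediate nodes
.fwd_mmif <- function(tape, model, XpNode, ids, labels, hyper, training) {
  cfg <- model@config
  P <- model@params
  B <- nrow(ids)
  enc <- .fwd_image_encoder(tape, P, cfg, XpNode, B, training)
  txtTok <- .fwd_text_decoder(tape, P, cfg, ids, B, training)
  mr <- .fwd_mran(tape, P, cfg, enc$node, txtTok, B, enc$n, training)
  TxtCls <- ad_rows(tape, txtTok, (seq_len(B) - 1L) * 5L + 1L)
  zi <- ad_l2rows(tape, ad_linear(tape, mr$Img, P$con_proj_W, P$con_proj_b))
  zt <- ad_l2rows(tape, TxtCls)
  lcon <- ad_contrastive(tape, zi, zt, hyper@tau)
  logits <- ad_linear(tape, mr$Mul, P$cap_W, P$cap_b)
  lcap <- ad_softmaxce(tape, logits, labels)
  loss <- ad_wsum2(tape, lcon, lcap, hyper@alpha, hyper@beta)
  list(loss = loss, lcon = lcon, lcap = lcap, enc = enc, txtTok = txtTok,
       mran = mr, zi = zi, zt = zt, logits = logits)
}

# ---------------------------------------------------------------------------
# Patch extraction and user-facing forward operations
# ---------------------------------------------------------------------------

#' Split an image into flattened patch vectors
#'
#' @param img a \code{s x s x 3} array.
#' @param patchSize patch side length; must divide s.
#' @return an \code{(s/patchSize)^2 x (patchSize^2 * 3)} matrix, patches in
#'   row-major grid order.
#' @export
imagePatches <- function(img, patchSize) {
  s <- dim(img)[1]
  if (dim(img)[2] != s || length(dim(img)) != 3L)
    stop("shape error: image must be a square s x s x 3 array")
  if (s %% patchSize != 0L)
    stop("shape error: patchSize must divide the image size")
  g <- s %/% patchSize
  out <- matrix(0, g * g, patchSize * patchSize * 3L)
  k <- 0L
  for (pr in seq_len(g)) {
    rows <- seq.int((pr - 1L) * patchSize + 1L, pr * patchSize)
    for (pc in seq_len(g)) {
      cols <- seq.int((pc - 1L) * patchSize + 1L, pc * patchSize)
      k <- k + 1L
      out[k, ] <- as.vector(img[rows, cols, ])
    }
  }
  out
}

.stack_patches <- function(patchList) do.call(rbind, patchList)

#' Encode one image through the vision-transformer encoder
#'
#' Patchify, embed with positions, run the encoder blocks (the learnable
#' image query token is appended before the final block) and the MLP head.
#'
#' @param model an [MMIFModel-class].
#' @param image a \code{imageSize x imageSize x 3} array.
#' @return list with \code{imgEmbeds} (n_patches x d_i) and
#'   \code{imgQuery} (1 x d_i).
#' @export
imageEncode <- function(model, image) {
  cfg <- model@config
  if (!all(dim(image) == c(cfg@imageSize, cfg@imageSize, 3L)))
    stop("shape error: image must be ", cfg@imageSize, "x", cfg@imageSize, "x3")
  Xp <- imagePatches(image, cfg@patchSize)
  tape <- ad_tape()
  enc <- .fwd_image_encoder(tape, model@params, cfg, ad_const(tape, Xp), 1L,
                            training = FALSE)
  v <- enc$node$val
  list(imgEmbeds = v[-enc$n, , drop = FALSE],
       imgQuery = v[enc$n, , drop = FALSE])
}

#' Decode the text modality through the unimodal text decoder
#'
#' Prepends the learnable [class_text] token and runs the causal decoder
#' blocks; there is no cross-attention to the image side.
#'
#' @param model an [MMIFModel-class].
#' @param tokens a [CaptionTokens-class] (or integer vector of 4 token
#'   ids).
#' @return list with \code{textEmbeds} (4 x d_t) and \code{classText}
#'   (1 x d_t).
#' @export
textDecodeUnimodal <- function(model, tokens) {
  ids <- if (is(tokens, "CaptionTokens")) tokenIds(tokens) else as.integer(tokens)
  if (length(ids) != 4L) stop("shape error: need 4 token ids")
  tape <- ad_tape()
  x <- .fwd_text_decoder(tape, model@params, model@config,
                         matrix(ids, 1L), 1L, training = FALSE)
  v <- x$val
  list(textEmbeds = v[-1L, , drop = FALSE], classText = v[1L, , drop = FALSE])
}

#' Run the full parallel backbone on one image-label pair
#'
#' @param model an [MMIFModel-class].
#' @param image image array.
#' @param label class label 0/1 (selects the caption).
#' @return an [EmbeddingBundle-class].
#' @export
encodeBundle <- function(model, image, label) {
  ie <- imageEncode(model, image)
  td <- textDecodeUnimodal(model, tokenizeCaption(makeCaption(label)))
  new("EmbeddingBundle", imgEmbeds = ie$imgEmbeds, imgQuery = ie$imgQuery,
      textEmbeds = td$textEmbeds, classText = td$classText)
}

#' Fuse a backbone bundle through the multimodal alignment decoder
#'
#' @param model an [MMIFModel-class].
#' @param bundle an [EmbeddingBundle-class].
#' @return a [FusionOutput-class].
#' @export
mranForward <- function(model, bundle) {
  tape <- ad_tape()
  imgTok <- ad_const(tape, rbind(bundle@imgEmbeds, bundle@imgQuery))
  txtTok <- ad_const(tape, rbind(bundle@classText, bundle@textEmbeds))
  mr <- .fwd_mran(tape, model@params, model@config, imgTok, txtTok, 1L,
                  nrow(bundle@imgEmbeds) + 1L, training = FALSE)
  new("FusionOutput", mulEmbeds = mr$stream$val, classMul = mr$Mul$val,
      classImg = mr$Img$val)
}

#' Apply a cross-attention block of the model
#'
#' Runs one of the model's cross-attention blocks (two windowed inner-patch
#' self-attentions around one cross-patch attention onto the context, with
#' residuals) as a plain function of matrices. With \code{context = NULL}
#' the block attends to itself.
#'
#' @param model an [MMIFModel-class].
#' @param x numeric n x d matrix (d = image width for \code{"stage1"},
#'   text width for \code{"fusion"}).
#' @param context optional context matrix with the same width.
#' @param which \code{"stage1"} (image-side CAB) or \code{"fusion"} (first
#'   stage-2 CAB).
#' @param window IPSA window size override.
#' @return the fused n x d matrix.
#' @export
cabForward <- function(model, x, context = NULL, which = c("stage1", "fusion"),
                       window = NULL) {
  which <- match.arg(which)
  cfg <- model@config
  prefix <- if (which == "stage1") "mran_s1_cab" else "mran1_cab"
  d <- if (which == "stage1") cfg@embedDimImage else cfg@embedDimText
  h <- if (which == "stage1") cfg@headsImage else cfg@headsText
  if (ncol(x) != d)
    stop("shape error: x must have width ", d, " for which='", which, "'")
  if (!is.null(context) && ncol(context) != d)
    stop("shape error: context width must match x width after projection")
  if (is.null(window)) window <- cfg@ipsaWindow
  tape <- ad_tape()
  xn <- ad_const(tape, x)
  cn <- if (is.null(context)) NULL else ad_const(tape, context)
  out <- .fwd_cab(tape, model@params, prefix, xn, cn, 1L, nrow(x), h, cfg,
                  training = FALSE, window = window)
  out$val
}

# image-side class embeddings for alignment classification: encoder +
# MRAN stage 1 + contrastive projection, L2-normalized (no text needed)
.image_class_embed <- function(model, patchList, batchSize = 32L) {
  cfg <- model@config
  P <- model@params
  n <- length(patchList)
  out <- matrix(0, n, cfg@embedDimText)
  i <- 1L
  while (i <= n) {
    j <- min(i + batchSize - 1L, n)
    B <- j - i + 1L
    tape <- ad_tape()
    Xp <- ad_const(tape, .stack_patches(patchList[i:j]))
    enc <- .fwd_image_encoder(tape, P, cfg, Xp, B, training = FALSE)
    s1 <- .fwd_cab(tape, P, "mran_s1_cab", enc$node, NULL, B, enc$n,
                   cfg@headsImage, cfg, training = FALSE)
    s1 <- ad_layernorm(tape, s1, P$mran_s1_ln_g, P$mran_s1_ln_b)
    Img <- ad_rows(tape, s1, seq_len(B) * enc$n)
    zi <- ad_l2rows(tape, ad_linear(tape, Img, P$con_proj_W, P$con_proj_b))
    out[i:j, ] <- zi$val
    i <- j + 1L
  }
  out
}

# class-text embeddings of both caption templates, L2-normalized (2 x d_t)
.caption_class_embed <- function(model) {
  zt <- matrix(0, 2L, model@config@embedDimText)
  for (lab in 0:1) {
    td <- textDecodeUnimodal(model, tokenizeCaption(makeCaption(lab)))
    v <- td$classText
    zt[lab + 1L, ] <- v / sqrt(sum(v^2) + 1e-12)
  }
  zt
}

#' Image-to-text alignment probabilities
#'
#' Zero-shot classification through the contrastive alignment: each image's
#' class embedding is compared against the class-text embeddings of the two
#' caption templates; a temperature-scaled softmax over the cosine
#' similarities yields class probabilities. This is how the multimodal
#' model classifies images without a text input.
#'
#' @param model a trained [MMIFModel-class].
#' @param images list of image arrays (or a [GADFStack-class]).
#' @param tau softmax temperature (default 0.07).
#' @return numeric vector of per-image probabilities of class pathological.
#' @export
alignmentProbs <- function(model, images, tau = 0.07) {
  if (is(images, "GADFStack")) images <- stackImages(images)
  patchList <- lapply(images, imagePatches, model@config@patchSize)
  zi <- .image_class_embed(model, patchList)
  zt <- .caption_class_embed(model)
  S <- tcrossprod(zi, zt) / tau
  e <- exp(S - apply(S, 1L, max))
  (e / rowSums(e))[, 2L]
}

# ---------------------------------------------------------------------------
# Checkpointing
# ---------------------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Single-file archive with a schema id, the architecture configuration,
#' all weights, the caption vocabulary and the RNG state.
#'
#' @param model an [MMIFModel-class].
#' @param path checkpoint file path.
#' @return \code{saveCheckpoint}: the path, invisibly;
#'   \code{loadCheckpoint}: an [MMIFModel-class].
#' @export
saveCheckpoint <- function(model, path) {
  cfg <- model@config
  cfgList <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(cfgList) <- slotNames(cfg)
  vals <- lapply(sort(ls(model@params)), function(nm) model@params[[nm]]$val)
  names(vals) <- sort(ls(model@params))
  rng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  saveRDS(list(schema = model@schema, config = cfgList, weights = vals,
               vocab = model@vocab, rng = rng), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$schema, .CKPT_SCHEMA))
    stop("compatibility error: unknown checkpoint schema: ", ck$schema)
  cfg <- do.call(new, c(list("ModelConfig"), ck$config))
  model <- newMMIFModel(cfg, seed = 1L)
  for (nm in names(ck$weights)) {
    if (is.null(model@params[[nm]]))
      stop("compatibility error: unexpected tensor '", nm, "' in checkpoint")
    model@params[[nm]]$val <- ck$weights[[nm]]
    model@params[[nm]]$grad <- ck$weights[[nm]] * 0
    model@params[[nm]]$m <- ck$weights[[nm]] * 0
    model@params[[nm]]$v <- ck$weights[[nm]] * 0
    model@params[[nm]]$t <- 0L
  }
  model
}

# deep copy / restore of parameter values (fold snapshots)
.copy_weights <- function(model) {
  nms <- ls(model@params)
  out <- lapply(nms, function(nm) model@params[[nm]]$val)
  names(out) <- nms
  out
}

.restore_weights <- function(model, weights) {
  for (nm in names(weights)) model@params[[nm]]$val <- weights[[nm]]
  invisible(model)
}
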