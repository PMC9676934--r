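#' @include AllGenerics.R
NULL

# Physiologically plausible FHR range (bpm); samples outside are treated as
# signal loss by the readers.
.FHR_RANGE <- c(30, 300)

#' FHRRecord: one fetal heart-rate trace with clinical metadata
#'
#' Container for a single fetal heart rate (FHR) trace sampled at 4 Hz,
#' together with its missingness mask and the postnatal clinical metadata
#' (umbilical-artery pH, Apgar scores) used for labelling. Missing samples are
#' stored as \code{NA} and flagged in \code{missingMask}.
#'
#' @slot samples numeric vector of heart-rate values in bpm; \code{NA} where
#'   missing.
#' @slot missingMask logical vector, \code{TRUE} where the sample is missing.
#' @slot recordId single character identifier.
#' @slot ph umbilical-artery pH (\code{NA} if unknown).
#' @slot apgar5,apgar10 integer Apgar scores at 5 and 10 minutes
#'   (\code{NA} if unknown).
#' @slot label integer class label: 0 = normal, 1 = pathological,
#'   \code{NA} = unknown.
#' @slot rateHz sampling rate in Hz (4 for cardiotocography exports).
#'
#' @seealso [readFHRRecord()], [generateRecord()], [applyInclusionCriteria()]
#' @export
setClass("FHRRecord",
  representation(
    samples = "numeric",
    missingMask = "logical",
    recordId = "character",
    ph = "numeric",
    apgar5 = "integer",
    apgar10 = "integer",
    label = "integer",
    rateHz = "numeric"
  ),
  prototype(
    ph = NA_real_, apgar5 = NA_integer_, apgar10 = NA_integer_,
    label = NA_integer_, rateHz = 4
  )
)

setValidity("FHRRecord", function(object) {
  msg <- character()
  if (length(object@missingMask) != length(object@samples))
    msg <- c(msg, "missingMask length must equal samples length")
  obs <- object@samples[!object@missingMask]
  if (length(obs) && (any(!is.finite(obs)) ||
      any(obs < .FHR_RANGE[1]) || any(obs > .FHR_RANGE[2])))
    msg <- c(msg, sprintf("non-missing samples must be finite and in [%g, %g] bpm",
                          .FHR_RANGE[1], .FHR_RANGE[2]))
  if (length(object@recordId) != 1L)
    msg <- c(msg, "recordId must be a single string")
  if (!is.na(object@label) && !object@label %in% c(0L, 1L))
    msg <- c(msg, "label must be 0 (normal), 1 (pathological) or NA")
  if (length(object@rateHz) != 1L || !is.finite(object@rateHz) || object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an FHRRecord
#'
#' @param samples numeric vector of FHR values in bpm (\code{NA} allowed where
#'   missing).
#' @param missingMask logical vector; defaults to non-finite samples.
#' @param recordId identifier string.
#' @param ph,apgar5,apgar10 clinical metadata (optional).
#' @param label class label 0/1 or \code{NA}.
#' @param rateHz sampling rate, default 4 Hz.
#' @return an [FHRRecord-class] object.
#' @examples
#' rec <- FHRRecord(rep(140, 1200), recordId = "demo")
#' missingFraction(rec)
#' @export
FHRRecord <- function(samples, missingMask = NULL, recordId = "record",
                      ph = NA_real_, apgar5 = NA_integer_,
                      apgar10 = NA_integer_, label = NA_integer_,
                      rateHz = 4) {
  samples <- as.numeric(samples)
  if (is.null(missingMask)) missingMask <- !is.finite(samples)
  samples[missingMask] <- NA_real_
  new("FHRRecord", samples = samples, missingMask = as.logical(missingMask),
      recordId = as.character(recordId), ph = as.numeric(ph),
      apgar5 = as.integer(apgar5), apgar10 = as.integer(apgar10),
      label = as.integer(label), rateHz = rateHz)
}

setMethod("show", "FHRRecord", function(object) {
  cat(sprintf("FHRRecord '%s': %d samples @ %g Hz (%.1f min), %.1f%% missing\n",
              object@recordId, length(object@samples), object@rateHz,
              length(object@samples) / object@rateHz / 60,
              100 * mean(object@missingMask)))
  lab <- if (is.na(object@label)) "unknown" else
    c("normal", "pathological")[object@label + 1L]
  cat(sprintf("  pH=%s Apgar5=%s Apgar10=%s label=%s\n",
              format(object@ph), format(object@apgar5),
              format(object@apgar10), lab))
})

#' InclusionDecision: outcome of the cohort inclusion rules
#'
#' @slot eligible logical flag.
#' @slot assignedLabel 0, 1 or \code{NA} (when ineligible).
#' @slot reasons character vector of rule identifiers explaining exclusion
#'   (\code{"missingness"}, \code{"length"}, \code{"ph_band"},
#'   \code{"apgar_band"}); empty when eligible.
#' @seealso [applyInclusionCriteria()]
#' @export
setClass("InclusionDecision",
  representation(eligible = "logical", assignedLabel = "integer",
                 reasons = "character"))

setValidity("InclusionDecision", function(object) {
  msg <- character()
  if (!object@eligible && !is.na(object@assignedLabel))
    msg <- c(msg, "ineligible records must have no assigned label")
  if (!object@eligible && length(object@reasons) == 0L)
    msg <- c(msg, "ineligible records must carry at least one reason")
  if (length(msg)) msg else TRUE
})

setMethod("show", "InclusionDecision", function(object) {
  if (object@eligible) {
    cat(sprintf("InclusionDecision: eligible, label %d\n", object@assignedLabel))
  } else {
    cat(sprintf("InclusionDecision: ineligible (%s)\n",
                paste(object@reasons, collapse = ", ")))
  }
})

#' GADFStack: the rendered GADF image stack of one record
#'
#' The multiscale image representation of one FHR record: one Gramian angular
#' difference field image per PAA target dimension in the schedule, rendered
#' to \code{size x size x 3} arrays with values in [0, 1].
#'
#' @slot images list of 3-d arrays (height x width x 3).
#' @slot dims integer vector, the PAA schedule used (one entry per image).
#' @slot recordId identifier of the source record.
#' @seealso [recordToStack()], [paaSchedule()]
#' @export
setClass("GADFStack",
  representation(images = "list", dims = "integer", recordId = "character"))

setValidity("GADFStack", function(object) {
  msg <- character()
  if (length(object@images) != length(object@dims))
    msg <- c(msg, "one PAA dimension per image required")
  for (im in object@images) {
    if (!is.array(im) || length(dim(im)) != 3L || dim(im)[3] != 3L) {
      msg <- c(msg, "each image must be a height x width x 3 array")
      break
    }
    if (min(im) < -1e-9 || max(im) > 1 + 1e-9) {
      msg <- c(msg, "image values must lie in [0, 1]")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GADFStack", function(object) {
  d <- if (length(object@images)) dim(object@images[[1]]) else c(0, 0, 0)
  cat(sprintf("GADFStack '%s': %d images of %dx%dx%d (PAA dims %s..%s)\n",
              object@recordId, length(object@images), d[1], d[2], d[3],
              if (length(object@dims)) max(object@dims) else NA,
              if (length(object@dims)) min(object@dims) else NA))
})

#' CaptionTokens: the tokenized text modality of one record
#'
#' The caption built from the class label ("This object is normal" /
#' "This object is pathological"), tokenized over the closed five-word
#' vocabulary and embedded as a 4 x d matrix (token + position embeddings).
#'
#' @slot tokens integer vector of 4 token ids (1-based into the vocabulary).
#' @slot embeddings numeric 4 x d matrix of token embeddings.
#' @slot label integer class label 0/1.
#' @seealso [makeCaption()], [tokenizeEmbed()]
#' @export
setClass("CaptionTokens",
  representation(tokens = "integer", embeddings = "matrix", label = "integer"))

setValidity("CaptionTokens", function(object) {
  msg <- character()
  if (length(object@tokens) != 4L)
    msg <- c(msg, "captions have exactly 4 tokens")
  if (nrow(object@embeddings) != 4L)
    msg <- c(msg, "embeddings must have 4 rows")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CaptionTokens", function(object) {
  cat(sprintf("CaptionTokens: label %d, '%s', embeddings 4x%d\n",
              object@label, makeCaption(object@label), ncol(object@embeddings)))
})

#' ModelConfig: architecture hyperparameters of the multimodal model
#'
#' Describes the parallel image-encoder / text-decoder backbone and the
#' multimodal alignment decoder. Defaults follow the reference setting:
#' 224-pixel images, 16-pixel patches (the B/16 vision-transformer variant),
#' six encoder blocks with 16 heads, six-block text and multimodal decoders
#' with 8 heads, and a 224-dimensional text stream.
#'
#' @slot imageSize input image side length in pixels.
#' @slot patchSize patch side length in pixels; must divide \code{imageSize}.
#' @slot embedDimImage image token width d_i.
#' @slot embedDimText text token width d_t (224 in the reference setting).
#' @slot encoderDepth,unimodalDecoderDepth,multimodalDecoderDepth block counts.
#' @slot headsImage,headsText attention head counts.
#' @slot mlpRatio MLP expansion factor inside transformer blocks.
#' @slot dropout dropout rate inside blocks.
#' @slot variant label such as "B/16", "B/32", "L/16", "L/32" or "custom".
#' @slot scale attention logit scaling, \code{"sqrt"} (1/sqrt(d_head),
#'   the cited standard) or \code{"linear"} (1/d_head, the formula as
#'   printed).
#' @slot ipsaWindow window size (tokens) of the inner-patch self-attention
#'   inside cross-attention blocks.
#' @seealso [modelConfig()], [newMMIFModel()]
#' @export
setClass("ModelConfig",
  representation(
    imageSize = "integer", patchSize = "integer",
    embedDimImage = "integer", embedDimText = "integer",
    encoderDepth = "integer", unimodalDecoderDepth = "integer",
    multimodalDecoderDepth = "integer",
    headsImage = "integer", headsText = "integer",
    mlpRatio = "numeric", dropout = "numeric",
    variant = "character", scale = "character", ipsaWindow = "integer"
  ))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@imageSize %% object@patchSize != 0L)
    msg <- c(msg, "imageSize must be divisible by patchSize")
  if (object@embedDimImage %% object@headsImage != 0L)
    msg <- c(msg, "embedDimImage must be divisible by headsImage")
  if (object@embedDimText %% object@headsText != 0L)
    msg <- c(msg, "embedDimText must be divisible by headsText")
  if (!object@scale %in% c("sqrt", "linear"))
    msg <- c(msg, "scale must be 'sqrt' or 'linear'")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelConfig
#'
#' @param variant one of "B/16", "B/32", "L/16", "L/32" (sets
#'   \code{embedDimImage} and \code{patchSize}) or "custom".
#' @param imageSize,patchSize,embedDimImage,embedDimText,encoderDepth,unimodalDecoderDepth,multimodalDecoderDepth,headsImage,headsText,mlpRatio,dropout,scale,ipsaWindow
#'   see the class slots; any explicit value overrides the variant preset.
#' @return a [ModelConfig-class].
#' @examples
#' cfg <- modelConfig("B/16")
#' nPatches(cfg)
#' @export
modelConfig <- function(variant = "B/16", imageSize = 224L, patchSize = NULL,
                        embedDimImage = NULL, embedDimText = 224L,
                        encoderDepth = 6L, unimodalDecoderDepth = 6L,
                        multimodalDecoderDepth = 6L, headsImage = 16L,
                        headsText = 8L, mlpRatio = 4, dropout = 0.1,
                        scale = "sqrt", ipsaWindow = 7L) {
  preset <- list(
    "B/16" = list(dim = 768L, patch = 16L),
    "B/32" = list(dim = 768L, patch = 32L),
    "L/16" = list(dim = 1024L, patch = 16L),
    "L/32" = list(dim = 1024L, patch = 32L)
  )[[variant]]
  if (is.null(patchSize))
    patchSize <- if (!is.null(preset)) preset$patch else 16L
  if (is.null(embedDimImage))
    embedDimImage <- if (!is.null(preset)) preset$dim else 768L
  new("ModelConfig",
      imageSize = as.integer(imageSize), patchSize = as.integer(patchSize),
      embedDimImage = as.integer(embedDimImage),
      embedDimText = as.integer(embedDimText),
      encoderDepth = as.integer(encoderDepth),
      unimodalDecoderDepth = as.integer(unimodalDecoderDepth),
      multimodalDecoderDepth = as.integer(multimodalDecoderDepth),
      headsImage = as.integer(headsImage), headsText = as.integer(headsText),
      mlpRatio = mlpRatio, dropout = dropout,
      variant = if (is.null(preset)) "custom" else variant,
      scale = scale, ipsaWindow = as.integer(ipsaWindow))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(paste0(
    "ModelConfig %s: image %dpx / patch %d (%d tokens, d_i=%d, %d heads)\n",
    "  text d_t=%d (%d heads); depths enc/dec/mm = %d/%d/%d; ",
    "mlp x%g, dropout %g, scale=%s\n"),
    object@variant, object@imageSize, object@patchSize, nPatches(object),
    object@embedDimImage, object@headsImage, object@embedDimText,
    object@headsText, object@encoderDepth, object@unimodalDecoderDepth,
    object@multimodalDecoderDepth, object@mlpRatio, object@dropout,
    object@scale))
})

#' Hyperparams: optimization hyperparameters
#'
#' Defaults follow the reference training protocol: batch size 32, 10
#' epochs, learning rate 1e-3, Adam-style moments (0.9, 0.999) with
#' decoupled weight decay 1e-4, contrastive temperature 0.07 and loss
#' weights alpha = 0.3 (constraint) / beta = 0.7 (captioning).
#'
#' @slot batchSize,epochs,lr,weightDecay,beta1,beta2,tau,alpha,beta,seed
#'   numeric hyperparameters (see Details).
#' @slot optimizer "adamw" (default) or "adagrad".
#' @seealso [hyperparams()], [trainFold()]
#' @export
setClass("Hyperparams",
  representation(batchSize = "integer", epochs = "integer", lr = "numeric",
                 weightDecay = "numeric", beta1 = "numeric", beta2 = "numeric",
                 tau = "numeric", alpha = "numeric", beta = "numeric",
                 seed = "integer", optimizer = "character"))

setValidity("Hyperparams", function(object) {
  msg <- character()
  vals <- c(object@batchSize, object@epochs, object@lr, object@beta1,
            object@beta2, object@tau)
  if (any(!is.finite(vals)) || any(vals <= 0))
    msg <- c(msg, "batchSize, epochs, lr, beta1, beta2 and tau must be positive")
  if (object@weightDecay < 0) msg <- c(msg, "weightDecay must be >= 0")
  if (abs(object@alpha + object@beta - 1) > 1e-9)
    msg <- c(msg, "loss weights must satisfy alpha + beta = 1")
  if (!object@optimizer %in% c("adamw", "adagrad"))
    msg <- c(msg, "optimizer must be 'adamw' or 'adagrad'")
  if (length(msg)) msg else TRUE
})

#' Construct optimization hyperparameters
#'
#' @param batchSize,epochs,lr,weightDecay,beta1,beta2,tau,alpha,beta,seed,optimizer
#'   see [Hyperparams-class].
#' @return a [Hyperparams-class].
#' @export
hyperparams <- function(batchSize = 32L, epochs = 10L, lr = 1e-3,
                        weightDecay = 1e-4, beta1 = 0.9, beta2 = 0.999,
                        tau = 0.07, alpha = 0.3, beta = 0.7, seed = 1L,
                        optimizer = "adamw") {
  new("Hyperparams", batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), lr = lr, weightDecay = weightDecay,
      beta1 = beta1, beta2 = beta2, tau = tau, alpha = alpha, beta = beta,
      seed = as.integer(seed), optimizer = optimizer)
}

setMethod("show", "Hyperparams", function(object) {
  cat(sprintf(paste0("Hyperparams: batch %d, %d epochs, lr %g, wd %g, ",
                     "betas (%g, %g), tau %g, alpha/beta %g/%g, %s, seed %d\n"),
              object@batchSize, object@epochs, object@lr, object@weightDecay,
              object@beta1, object@beta2, object@tau, object@alpha,
              object@beta, object@optimizer, object@seed))
})

#' FoldPlan: stratified 1:1 test split plus 5-fold cross-validation
#'
#' @slot testIds record ids held out as the test set (half of all records,
#'   stratified by label).
#' @slot folds list of \code{list(train, val)} id vectors partitioning the
#'   non-test records; validation sets are disjoint across folds.
#' @slot seed integer seed that generated the plan.
#' @seealso [makeFoldPlan()]
#' @export
setClass("FoldPlan",
  representation(testIds = "character", folds = "list", seed = "integer"))

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d test records, %d folds (val sizes %s), seed %d\n",
              length(object@testIds), length(object@folds),
              paste(vapply(object@folds, function(f) length(f$val), 1L),
                    collapse = "/"),
              object@seed))
})

#' EmbeddingBundle: unimodal outputs of the parallel backbone
#'
#' @slot imgEmbeds encoded image patch features Xi' (n_patches x d_i).
#' @slot imgQuery the image query token q_img (1 x d_i).
#' @slot textEmbeds decoded text features Xt' (4 x d_t).
#' @slot classText the class-text token Txt (1 x d_t).
#' @export
setClass("EmbeddingBundle",
  representation(imgEmbeds = "matrix", imgQuery = "matrix",
                 textEmbeds = "matrix", classText = "matrix"))

setMethod("show", "EmbeddingBundle", function(object) {
  cat(sprintf("EmbeddingBundle: Xi' %dx%d, q_img 1x%d, Xt' %dx%d, Txt 1x%d\n",
              nrow(object@imgEmbeds), ncol(object@imgEmbeds),
              ncol(object@imgQuery), nrow(object@textEmbeds),
              ncol(object@textEmbeds), ncol(object@classText)))
})

#' FusionOutput: multimodal decoder outputs
#'
#' @slot mulEmbeds joint image-text sequence Xm' (text-stream length x d_t).
#' @slot classMul the multimodal prediction token Mul (1 x d_t).
#' @slot classImg the image class token Img (1 x d_i).
#' @export
setClass("FusionOutput",
  representation(mulEmbeds = "matrix", classMul = "matrix",
                 classImg = "matrix"))

setMethod("show", "FusionOutput", function(object) {
  cat(sprintf("FusionOutput: Xm' %dx%d, Mul 1x%d, Img 1x%d\n",
              nrow(object@mulEmbeds), ncol(object@mulEmbeds),
              ncol(object@classMul), ncol(object@classImg)))
})

#' MMIFModel: the multimodal image-text fusion model
#'
#' Holds all learnable parameters of the parallel image encoder, unimodal
#' text decoder and multimodal alignment decoder, plus the projection and
#' classifier heads used by the combined contrastive/captioning objective.
#'
#' @slot config the [ModelConfig-class].
#' @slot params environment mapping parameter names to parameter stores
#'   (each with \code{$val}, \code{$grad} and optimizer state).
#' @slot vocab the closed caption vocabulary.
#' @slot schema checkpoint schema identifier.
#' @seealso [newMMIFModel()], [saveCheckpoint()]
#' @export
setClass("MMIFModel",
  representation(config = "ModelConfig", params = "environment",
                 vocab = "character", schema = "character"))

setMethod("show", "MMIFModel", function(object) {
  cat(sprintf("MMIFModel (%s): %s parameters in %d tensors\n",
              object@config@variant,
              format(nParameters(object), big.mark = ","),
              length(ls(object@params))))
  show(object@config)
})

#' FDDModel: frozen-encoder diagnostic test model
#'
#' The downstream image-only classifier: the trained image encoder with
#' frozen weights, topped by a trainable cross-attention block, LayerNorm
#' and a linear softmax head over the two classes.
#'
#' @slot backbone the trained [MMIFModel-class] (encoder weights are used
#'   frozen).
#' @slot head environment of trainable head parameters.
#' @slot config the [ModelConfig-class] of the backbone.
#' @seealso [buildTestModel()], [diagnoseRecord()]
#' @export
setClass("FDDModel",
  representation(backbone = "MMIFModel", head = "environment",
                 config = "ModelConfig"))

setMethod("show", "FDDModel", function(object) {
  cat(sprintf("FDDModel: frozen %s encoder + CAB/LayerNorm/linear head (%d head tensors)\n",
              object@config@variant, length(ls(object@head))))
})

#' DiagnosisResult: record-level diagnosis by image-majority vote
#'
#' @slot recordId record identifier.
#' @slot perImageProbs per-image probabilities of class pathological.
#' @slot votesPathological number of images with probability > 0.5.
#' @slot labelPred predicted record label (1 when more than half of the
#'   images vote pathological; ties resolve to pathological as a clinical
#'   fail-safe).
#' @slot labelTrue true label if known (\code{NA} otherwise).
#' @seealso [diagnoseRecord()], [evaluateDiagnoses()]
#' @export
setClass("DiagnosisResult",
  representation(recordId = "character", perImageProbs = "numeric",
                 votesPathological = "integer", labelPred = "integer",
                 labelTrue = "integer"))

setValidity("DiagnosisResult", function(object) {
  msg <- character()
  if (any(object@perImageProbs < 0 | object@perImageProbs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@votesPathological != sum(object@perImageProbs > 0.5))
    msg <- c(msg, "votesPathological must count probabilities > 0.5")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiagnosisResult", function(object) {
  cat(sprintf("DiagnosisResult '%s': %d/%d pathological votes -> label %d%s\n",
              object@recordId, object@votesPathological,
              length(object@perImageProbs), object@labelPred,
              if (is.na(object@labelTrue)) "" else
                sprintf(" (true %d)", object@labelTrue)))
})
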