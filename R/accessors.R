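#' @include AllClasses.R
NULL

#' @describeIn FHRRecord record identifier.
#' @param x an object.
#' @export
setMethod("recordId", "FHRRecord", function(x) x@recordId)

#' @describeIn FHRRecord the sample vector (bpm, \code{NA} where missing).
#' @export
setMethod("fhrSamples", "FHRRecord", function(x) x@samples)

#' @describeIn FHRRecord the logical missingness mask.
#' @export
setMethod("missingMask", "FHRRecord", function(x) x@missingMask)

#' @describeIn FHRRecord fraction of missing samples.
#' @export
setMethod("missingFraction", "FHRRecord", function(x) mean(x@missingMask))

#' @describeIn FHRRecord class label (0/1/NA).
#' @export
setMethod("recordLabel", "FHRRecord", function(x) x@label)

#' @describeIn FHRRecord set the class label.
#' @param value replacement value.
#' @export
setMethod("recordLabel<-", "FHRRecord", function(x, value) {
  x@label <- as.integer(value)
  validObject(x)
  x
})

#' @describeIn FHRRecord umbilical-artery pH.
#' @export
setMethod("phValue", "FHRRecord", function(x) x@ph)

#' @describeIn FHRRecord named vector of Apgar scores at 5 and 10 minutes.
#' @export
setMethod("apgarScores", "FHRRecord", function(x)
  c(apgar5 = x@apgar5, apgar10 = x@apgar10))

#' @describeIn FHRRecord sampling rate in Hz.
#' @export
setMethod("samplingRate", "FHRRecord", function(x) x@rateHz)

#' @describeIn GADFStack list of rendered images.
#' @param x an object.
#' @export
setMethod("stackImages", "GADFStack", function(x) x@images)

#' @describeIn GADFStack the PAA schedule used.
#' @export
setMethod("stackDims", "GADFStack", function(x) x@dims)

#' @describeIn GADFStack number of images in the stack.
#' @export
setMethod("nImages", "GADFStack", function(x) length(x@images))

#' @describeIn GADFStack identifier of the source record.
#' @export
setMethod("recordId", "GADFStack", function(x) x@recordId)

#' @describeIn CaptionTokens the 4 token ids.
#' @param x an object.
#' @export
setMethod("tokenIds", "CaptionTokens", function(x) x@tokens)

#' @describeIn CaptionTokens the 4 x d embedding matrix.
#' @export
setMethod("tokenEmbeddings", "CaptionTokens", function(x) x@embeddings)

#' @describeIn CaptionTokens the class label.
#' @export
setMethod("recordLabel", "CaptionTokens", function(x) x@label)

#' @describeIn ModelConfig number of image patch tokens
#'   \eqn{(imageSize/patchSize)^2}.
#' @param x an object.
#' @export
setMethod("nPatches", "ModelConfig", function(x)
  as.integer((x@imageSize %/% x@patchSize)^2))

#' @describeIn MMIFModel total number of scalar learnable parameters.
#' @param x an object.
#' @export
setMethod("nParameters", "MMIFModel", function(x) {
  sum(vapply(ls(x@params), function(nm) length(x@params[[nm]]$val), 1))
})

#' @describeIn MMIFModel the architecture configuration.
#' @export
setMethod("modelConfigOf", "MMIFModel", function(x) x@config)

#' @describeIn FoldPlan held-out test record ids.
#' @param x an object.
#' @export
setMethod("testIds", "FoldPlan", function(x) x@testIds)

#' @describeIn FoldPlan list of per-fold \code{list(train, val)} id sets.
#' @export
setMethod("foldSplits", "FoldPlan", function(x) x@folds)
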