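#' Accessor generics
#'
#' Small accessor generics shared by the classes in this package. Each has
#' methods documented on the class pages.
#'
#' @param x an object.
#' @param value replacement value.
#' @name accessor-generics
#' @keywords internal
NULL

#' @rdname accessor-generics
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname accessor-generics
#' @export
setGeneric("fhrSamples", function(x) standardGeneric("fhrSamples"))

#' @rdname accessor-generics
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname accessor-generics
#' @export
setGeneric("missingFraction", function(x) standardGeneric("missingFraction"))

#' @rdname accessor-generics
#' @export
setGeneric("recordLabel", function(x) standardGeneric("recordLabel"))

#' @rdname accessor-generics
#' @export
setGeneric("recordLabel<-", function(x, value) standardGeneric("recordLabel<-"))

#' @rdname accessor-generics
#' @export
setGeneric("phValue", function(x) standardGeneric("phValue"))

#' @rdname accessor-generics
#' @export
setGeneric("apgarScores", function(x) standardGeneric("apgarScores"))

#' @rdname accessor-generics
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessor-generics
#' @export
setGeneric("stackImages", function(x) standardGeneric("stackImages"))

#' @rdname accessor-generics
#' @export
setGeneric("stackDims", function(x) standardGeneric("stackDims"))

#' @rdname accessor-generics
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' @rdname accessor-generics
#' @export
setGeneric("tokenIds", function(x) standardGeneric("tokenIds"))

#' @rdname accessor-generics
#' @export
setGeneric("tokenEmbeddings", function(x) standardGeneric("tokenEmbeddings"))

#' @rdname accessor-generics
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))

#' @rdname accessor-generics
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' @rdname accessor-generics
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))

#' @rdname accessor-generics
#' @export
setGeneric("testIds", function(x) standardGeneric("testIds"))

#' @rdname accessor-generics
#' @export
setGeneric("foldSplits", function(x) standardGeneric("foldSplits"))
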