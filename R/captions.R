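#' @include AllClasses.R
NULL

#' The closed caption vocabulary
#'
#' The five words spanned by the two caption templates. Word-level
#' tokenization over this closed vocabulary is the unique scheme consistent
#' with a 4-token text modality.
#'
#' @return character vector of length 5.
#' @export
ctgVocabulary <- function() c("This", "object", "is", "normal", "pathological")

#' Build the caption of a class label
#'
#' @param label 0 (normal) or 1 (pathological).
#' @return the caption string: "This object is normal" or
#'   "This object is pathological".
#' @examples
#' makeCaption(1)
#' @export
makeCaption <- function(label) {
  if (length(label) != 1L || !label %in% c(0, 1))
    stop("value error: label must be 0 or 1")
  if (label == 0) "This object is normal" else "This object is pathological"
}

#' Tokenize a caption over the closed vocabulary
#'
#' @param caption a caption string.
#' @return integer vector of 1-based token ids.
#' @export
tokenizeCaption <- function(caption) {
  words <- strsplit(trimws(caption), "\\s+")[[1]]
  ids <- match(words, ctgVocabulary())
  if (any(is.na(ids)))
    stop("vocabulary error: unknown word(s): ",
         paste(words[is.na(ids)], collapse = ", "))
  as.integer(ids)
}

#' Tokenize and embed a caption
#'
#' Word-level tokenization over the five-word vocabulary followed by lookup
#' in a learnable 5 x d embedding table plus additive learned position
#' embeddings, yielding the 4 x d text modality (d = 224 in the reference
#' setting).
#'
#' @param caption one of the two caption templates.
#' @param table numeric 5 x d embedding table (rows indexed by vocabulary
#'   position).
#' @param positions numeric 4 x d position embedding table, or NULL for
#'   none.
#' @param label class label stored alongside (inferred from the last token
#'   when NULL).
#' @return a [CaptionTokens-class].
#' @examples
#' tab <- matrix(rnorm(5 * 8), 5, 8)
#' tokenizeEmbed("This object is normal", tab)
#' @export
tokenizeEmbed <- function(caption, table, positions = NULL, label = NULL) {
  ids <- tokenizeCaption(caption)
  if (length(ids) != 4L)
    stop("vocabulary error: captions must have exactly 4 words")
  if (nrow(table) != length(ctgVocabulary()))
    stop("embedding table must have one row per vocabulary word")
  emb <- table[ids, , drop = FALSE]
  if (!is.null(positions)) {
    if (!all(dim(positions) == dim(emb)))
      stop("position table must be 4 x d")
    emb <- emb + positions
  }
  if (is.null(label))
    label <- if (ids[4] == 4L) 0L else 1L
  new("CaptionTokens", tokens = ids, embeddings = emb,
      label = as.integer(label))
}

#' Caption tokens of a label under a model's embedding tables
#'
#' @param model an [MMIFModel-class].
#' @param label 0 or 1.
#' @return a [CaptionTokens-class] using the model's learned tables.
#' @export
captionTokens <- function(model, label) {
  tokenizeEmbed(makeCaption(label), model@params$txt_embed$val,
                model@params$txt_pos$val, label = label)
}
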