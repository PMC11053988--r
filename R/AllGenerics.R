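#' Motif tokens of a sequence or fragmentation
#' @param x a [MotifSequence-class] or [FragmentationResult-class].
#' @return character vector of motif tokens (for a `FragmentationResult`,
#'   the labelled fragment SMILES).
#' @export
setGeneric("motifTokens", function(x) standardGeneric("motifTokens"))

#' Number of motifs
#' @param x a [MotifSequence-class] or [FragmentationResult-class].
#' @return integer count.
#' @export
setGeneric("nMotifs", function(x) standardGeneric("nMotifs"))

#' Fragmentation mode
#' @param x an object carrying a fragmentation mode.
#' @return `"motif"` or `"scaffold"`.
#' @export
setGeneric("fragMode", function(x) standardGeneric("fragMode"))

#' Vocabulary size
#' @param x a [MotifVocabulary-class] or [MotifGenerator-class].
#' @return integer number of tokens (|V|).
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))

#' Token to id / id to token
#' @param x a [MotifVocabulary-class].
#' @param token character vector of tokens.
#' @return `idOf`: integer ids (unknown tokens map to the `unk` id).
#' @export
setGeneric("idOf", function(x, token) standardGeneric("idOf"))

#' @rdname idOf
#' @param id integer vector of ids.
#' @return `tokenOf`: character tokens.
#' @export
setGeneric("tokenOf", function(x, id) standardGeneric("tokenOf"))

#' Per-epoch training loss
#' @param x a [MotifGenerator-class].
#' @return data.frame with columns `epoch` and `nll` (nats/token).
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))

## ---- methods -------------------------------------------------------------

#' @rdname motifTokens
setMethod("motifTokens", "MotifSequence", function(x) x@tokens)

#' @rdname motifTokens
setMethod("motifTokens", "FragmentationResult",
          function(x) vapply(x@fragments, `[[`, "", "smiles"))

#' @rdname nMotifs
setMethod("nMotifs", "MotifSequence", function(x) length(x@tokens))

#' @rdname nMotifs
setMethod("nMotifs", "FragmentationResult", function(x) length(x@fragments))

#' @rdname fragMode
setMethod("fragMode", "MotifSequence", function(x) x@mode)

#' @rdname fragMode
setMethod("fragMode", "FragmentationResult", function(x) x@mode)

#' @rdname fragMode
setMethod("fragMode", "MotifGenerator", function(x) x@mode)

#' @rdname vocabSize
setMethod("vocabSize", "MotifVocabulary", function(x) length(x@tokens))

#' @rdname vocabSize
setMethod("vocabSize", "MotifGenerator",
          function(x) length(x@vocabulary@tokens))

#' @rdname idOf
setMethod("idOf", "MotifVocabulary", function(x, token) {
  i <- match(token, x@tokens)
  unk <- match(x@specials[["unk"]], x@tokens)
  i[is.na(i)] <- unk
  i
})

#' @rdname idOf
setMethod("tokenOf", "MotifVocabulary", function(x, id) x@tokens[id])

#' @rdname trainingLog
setMethod("trainingLog", "MotifGenerator", function(x) x@trainingLog)

setMethod("show", "FragmentationResult", function(object) {
  cat(sprintf("FragmentationResult (%s%s): %d motif(s), %d cut(s), %d fused edge(s)\n",
              object@mode, if (object@fuseSplit) "+fuse" else "",
              length(object@fragments), nrow(object@cuts),
              nrow(object@fuses)))
  cat("  parent: ", object@parentSmiles, "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "MotifSequence", function(object) {
  cat(sprintf("MotifSequence (%s%s), %d token(s):\n", object@mode,
              if (object@fuseSplit) "+fuse" else "", length(object@tokens)))
  cat("  ", paste(object@tokens, collapse = " "), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "MotifVocabulary", function(object) {
  cat(sprintf("MotifVocabulary: %d tokens (%d special)\n",
              length(object@tokens), length(object@specials)))
  invisible(NULL)
})

setMethod("show", "MotifGenerator", function(object) {
  cfg <- object@config
  cat(sprintf("MotifGenerator: d_model=%d heads=%d layers=%d |V|=%d maxLen=%d\n",
              cfg$dModel, cfg$nHeads, cfg$nLayers,
              length(object@vocabulary@tokens), cfg$maxLen))
  if (nrow(object@trainingLog))
    cat(sprintf("  trained %d epochs, final NLL %.4f nats/token\n",
                max(object@trainingLog$epoch),
                object@trainingLog$nll[nrow(object@trainingLog)]))
  invisible(NULL)
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf("FixtureSpec: n=%d, %d ring systems, %d substituents, maxRings=%d, stereo=%.2f, seed=%d\n",
              object@nMolecules, length(object@ringLibrary),
              length(object@substituentLibrary), object@maxRings,
              object@stereoFraction, object@seed))
  invisible(NULL)
})
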