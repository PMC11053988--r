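## Conditioned training sentences: [constraint tokens] [motif-info token]
## <bos> [motif tokens] <eos>.  The motif-info token encodes the total
## number of attachment points in the motif sequence.

.SPECIALS <- c(pad = "<pad>", bos = "<bos>", eos = "<eos>", unk = "<unk>")

#' Default constraint thresholds
#'
#' Half-open `[lo, hi)` windows defining the "good" bin of each conditioned
#' property: QED >= 0.5, logP in \[0, 5), SAS < 4.  These are standard
#' drug-likeness heuristics; they are configuration, not code, and can be
#' loaded from a YAML file with the same structure
#' (`list(qed = c(lo =, hi =), ...)`).
#'
#' @return named list of `c(lo, hi)` numeric windows.
#' @export
defaultThresholds <- function() {
  list(qed = c(lo = 0.5, hi = Inf),
       logp = c(lo = 0, hi = 5),
       sas = c(lo = -Inf, hi = 4))
}

#' Assign discrete constraint labels from descriptors
#'
#' Each conditioned property is binned into `<prop>_good` when its value
#' falls in the half-open window `[lo, hi)` and `<prop>_bad` otherwise;
#' label order follows `names(thresholds)` and is fixed across a corpus.
#'
#' @param descriptors data.frame as returned by [computeDescriptors()] (or
#'   any data.frame containing the threshold columns).
#' @param thresholds named list of `c(lo, hi)` windows, see
#'   [defaultThresholds()].
#' @return character matrix, one row per molecule, one column per property.
#' @export
assignConstraintLabels <- function(descriptors,
                                   thresholds = defaultThresholds()) {
  missing <- setdiff(names(thresholds), names(descriptors))
  if (length(missing))
    stop("missing_descriptor: ", paste(missing, collapse = ", "))
  out <- vapply(names(thresholds), function(p) {
    x <- descriptors[[p]]
    w <- thresholds[[p]]
    ifelse(!is.na(x) & x >= w[["lo"]] & x < w[["hi"]],
           paste0(p, "_good"), paste0(p, "_bad"))
  }, character(nrow(descriptors)))
  if (nrow(descriptors) == 1L) out <- matrix(out, nrow = 1L,
                                             dimnames = list(NULL, names(thresholds)))
  out
}

#' Binary activity labels from a model score
#'
#' @param score numeric prediction scores.
#' @param threshold scores strictly above it are labelled `active`.
#' @return character vector of `"active"` / `"inactive"` tokens.
#' @export
activityLabels <- function(score, threshold) {
  ifelse(score > threshold, "active", "inactive")
}

.attachCount <- function(tokens) {
  sum(vapply(gregexpr("*", tokens, fixed = TRUE), function(m)
    if (m[1] == -1) 0L else length(m), 0L))
}

#' Motif-information token for a sequence
#'
#' Encodes the total number of attachment points of the motif sequence,
#' as exact integers up to 12 and `13+` above.
#'
#' @param tokens character vector of motif tokens.
#' @return a single token such as `"<att:3>"`.
#' @export
motifInfoToken <- function(tokens) {
  k <- .attachCount(tokens)
  paste0("<att:", if (k > 12L) "13+" else k, ">")
}

#' Build conditioned sentences from motif sequences
#'
#' A sentence is `labels, info, <bos>, motifs..., <eos>`.  Constraint and
#' info positions are decoding context; the model's loss is computed on the
#' motif tokens and `<eos>` only.
#'
#' @param seqs list of [MotifSequence-class] (entries that are not motif
#'   sequences are skipped).
#' @param labels character matrix/vector of constraint labels, one row (or
#'   element) per sequence.
#' @return list of character vectors (sentences), with the source SMILES as
#'   names where available.
#' @export
buildSentences <- function(seqs, labels) {
  if (inherits(seqs, "MotifSequence")) seqs <- list(seqs)
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = 1L)
  stopifnot(nrow(labels) == length(seqs))
  out <- list()
  nm <- character()
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (!inherits(s, "MotifSequence")) next
    out[[length(out) + 1L]] <- c(labels[i, ], motifInfoToken(s@tokens),
                                 .SPECIALS[["bos"]], s@tokens,
                                 .SPECIALS[["eos"]])
    nm <- c(nm, if (length(s@sourceSmiles)) s@sourceSmiles else NA_character_)
  }
  names(out) <- nm
  out
}

#' Build a token vocabulary from a sentence corpus
#'
#' Specials (`<pad>`, `<bos>`, `<eos>`, `<unk>`) occupy ids 1-4; all other
#' token types follow, sorted by descending corpus frequency with
#' lexicographic tie-break, so the same corpus always yields the identical
#' vocabulary.
#'
#' @param sentences list of character vectors.
#' @return a [MotifVocabulary-class].
#' @export
buildVocabulary <- function(sentences) {
  if (!length(sentences)) stop("empty_corpus")
  all <- unlist(sentences, use.names = FALSE)
  all <- all[!all %in% .SPECIALS]
  tab <- table(all)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  toks <- c(unname(.SPECIALS), names(tab)[ord])
  cnts <- c(rep(0L, length(.SPECIALS)), as.integer(tab)[ord])
  new("MotifVocabulary", tokens = toks, counts = cnts,
      specials = .SPECIALS)
}

#' Encode sentences to id lists / decode ids to tokens
#'
#' `decodeIds` strips padding and never emits `<pad>`;
#' `decodeIds(encodeSentences(x))` is the identity for in-vocabulary
#' sentences.
#'
#' @param sentences list of character vectors (or one vector).
#' @param vocab a [MotifVocabulary-class].
#' @return `encodeSentences`: list of integer vectors.
#' @export
encodeSentences <- function(sentences, vocab) {
  if (is.character(sentences)) sentences <- list(sentences)
  lapply(sentences, function(s) idOf(vocab, s))
}

#' @rdname encodeSentences
#' @param ids integer vector (or list of them).
#' @return `decodeIds`: character vector (or list) of tokens.
#' @export
decodeIds <- function(ids, vocab) {
  dec <- function(v) {
    toks <- tokenOf(vocab, v)
    toks[toks != vocab@specials[["pad"]] & !is.na(toks)]
  }
  if (is.list(ids)) lapply(ids, dec) else dec(ids)
}

## ---- corpus file formats -------------------------------------------------

#' Read molecules from a SMILES line file or CSV
#'
#' @param path file path; `.csv` files are read with [utils::read.csv()],
#'   anything else as one SMILES per line (lines starting with `#` are
#'   skipped).
#' @param column SMILES column name for CSV input.
#' @return character vector of SMILES.
#' @export
readSmilesFile <- function(path, column = "smiles") {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!column %in% names(df)) stop("no column '", column, "' in ", path)
    return(as.character(df[[column]]))
  }
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write / read a motif-sequence corpus file
#'
#' Interchange format: one record per line, two tab-separated fields — the
#' canonical parent SMILES and the space-separated motif tokens.
#'
#' @param seqs list of [MotifSequence-class].
#' @param path output file.
#' @return `writeMotifCorpus`: invisibly, the path.
#' @export
writeMotifCorpus <- function(seqs, path) {
  seqs <- Filter(function(s) inherits(s, "MotifSequence"), seqs)
  lines <- vapply(seqs, function(s)
    paste(if (length(s@sourceSmiles) && !is.na(s@sourceSmiles))
            s@sourceSmiles else "-",
          paste(s@tokens, collapse = " "), sep = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeMotifCorpus
#' @param mode,fuseSplit fragmentation provenance recorded on the read
#'   sequences.
#' @return `readMotifCorpus`: list of [MotifSequence-class].
#' @export
readMotifCorpus <- function(path, mode = "motif", fuseSplit = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    new("MotifSequence",
        tokens = strsplit(parts[2], " ", fixed = TRUE)[[1]],
        mode = mode, fuseSplit = fuseSplit,
        sourceSmiles = if (parts[1] == "-") NA_character_ else parts[1])
  })
}

#' Write / read a vocabulary as a two-column text file
#'
#' @param vocab a [MotifVocabulary-class].
#' @param path file path (tab-separated `token<TAB>id`).
#' @return `writeVocabulary`: invisibly the path; `readVocabulary`: a
#'   [MotifVocabulary-class].
#' @export
writeVocabulary <- function(vocab, path) {
  writeLines(paste(vocab@tokens, seq_along(vocab@tokens), sep = "\t"), path)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  toks <- vapply(lines, `[[`, "", 1L)
  ids <- as.integer(vapply(lines, `[[`, "", 2L))
  toks <- toks[order(ids)]
  new("MotifVocabulary", tokens = toks,
      counts = rep(0L, length(toks)), specials = .SPECIALS)
}
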