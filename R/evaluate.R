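## Benchmark metrics for generated molecule sets: conditional metrics
## (validity / uniqueness / novelty), distribution metrics in the MOSES
## convention (SNN, Frag, Scaf, IntDiv on 2048-bit Morgan radius-2
## fingerprints), ring-system / functional-group coverage and recovery,
## and enrichment factors for score-ranked lists.

.canonVec <- function(smiles, strip = FALSE) {
  vapply(bkCanonical(smiles, stripStereo = strip), function(x)
    if (is.null(x)) NA_character_ else x, "")
}

#' Validity, uniqueness and novelty of a generated set
#'
#' `validity` = valid / total; `uniqueness` = unique canonical SMILES /
#' valid; `novelty` = valid unique not present in the training set / valid
#' unique.
#'
#' @param generated data.frame with columns `smiles` and `valid` (as from
#'   [sampleMolecules()]), or a character vector (all treated as valid,
#'   `NA` = invalid).
#' @param trainSmiles character vector of training SMILES.
#' @return list with `validity`, `uniqueness`, `novelty`.
#' @export
conditionalMetrics <- function(generated, trainSmiles) {
  if (is.character(generated))
    generated <- data.frame(smiles = generated, valid = !is.na(generated),
                            stringsAsFactors = FALSE)
  if (!nrow(generated)) stop("empty_generated")
  valid <- generated$smiles[generated$valid & !is.na(generated$smiles)]
  validity <- length(valid) / nrow(generated)
  if (!length(valid))
    return(list(validity = 0, uniqueness = NA_real_, novelty = NA_real_))
  can <- .canonVec(valid)
  uniq <- unique(can[!is.na(can)])
  uniqueness <- length(uniq) / length(valid)
  trainCan <- unique(.canonVec(trainSmiles))
  novelty <- mean(!uniq %in% trainCan)
  list(validity = validity, uniqueness = uniqueness, novelty = novelty)
}

.fpMatrix <- function(smiles, nbits = 2048L) {
  fps <- bkFingerprint(smiles, nbits = nbits)
  keep <- !vapply(fps, is.null, TRUE)
  m <- matrix(0, sum(keep), nbits)
  r <- 0L
  for (i in which(keep)) {
    r <- r + 1L
    bits <- unlist(fps[[i]])
    if (length(bits)) m[r, bits + 1L] <- 1
  }
  m
}

.tanimotoCross <- function(A, B) {
  inter <- A %*% t(B)
  union <- outer(rowSums(A), rowSums(B), "+") - inter
  out <- inter / union
  out[union == 0] <- 0
  out
}

.countCosine <- function(a, b) {
  keys <- union(names(a), names(b))
  va <- as.numeric(a[keys]); va[is.na(va)] <- 0
  vb <- as.numeric(b[keys]); vb[is.na(vb)] <- 0
  if (!any(va > 0) || !any(vb > 0)) return(0)
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

#' MOSES-style distribution metrics
#'
#' SNN: mean over generated molecules of the maximum Tanimoto similarity
#' to the reference set.  Frag / Scaf: cosine similarity between the
#' BRICS-fragment / Bemis-Murcko-scaffold count vectors of the two sets.
#' IntDiv: 1 - mean pairwise Tanimoto within the generated set (0 for a
#' single molecule, where no pair exists).
#'
#' @param generated,reference character vectors of valid SMILES.
#' @return list with `snn`, `fragSim`, `scafSim`, `intDiv`.
#' @export
distributionMetrics <- function(generated, reference) {
  if (!length(generated) || !length(reference)) stop("empty_set")
  G <- .fpMatrix(generated)
  R <- .fpMatrix(reference)
  snn <- mean(apply(.tanimotoCross(G, R), 1L, max))
  intDiv <- if (nrow(G) < 2L) 0 else {
    tg <- .tanimotoCross(G, G)
    1 - mean(tg[upper.tri(tg)])
  }
  fragG <- table(unlist(lapply(bkBricsFrags(generated), unlist)))
  fragR <- table(unlist(lapply(bkBricsFrags(reference), unlist)))
  scafG <- table(unlist(bkScaffold(generated)))
  scafR <- table(unlist(bkScaffold(reference)))
  list(snn = snn, fragSim = .countCosine(fragG, fragR),
       scafSim = .countCosine(scafG, scafR), intDiv = intDiv)
}

.coverageRecovery <- function(genItems, trainItems) {
  genAll <- unlist(genItems)
  genUniq <- unique(genAll)
  trainUniq <- unique(unlist(trainItems))
  hits <- sum(genUniq %in% trainUniq)
  list(coverage = if (length(genAll)) hits / length(genAll) else NA_real_,
       recovery = if (length(genUniq)) hits / length(genUniq) else NA_real_,
       trainRecovery = if (length(trainUniq)) hits / length(trainUniq)
                       else NA_real_,
       nGenerated = length(genAll), nGeneratedUnique = length(genUniq),
       nTrainUnique = length(trainUniq))
}

#' Ring-system and functional-group coverage/recovery
#'
#' Ring systems are fused-ring connected components; functional groups are
#' extracted with the Ertl algorithm.  `coverage` is the number of unique
#' generated-set items also present in the training set divided by the
#' total item occurrences of the generated set; `recovery` divides the
#' same numerator by the unique items of the generated set.
#' `trainRecovery` (numerator over the unique items of the *training* set)
#' is reported as an additional diagnostic.
#'
#' @param generated,train character vectors of valid SMILES.
#' @return list with elements `rs` and `fg`, each containing `coverage`,
#'   `recovery`, `trainRecovery` and counts.
#' @export
rsFgMetrics <- function(generated, train) {
  if (!length(generated) || !length(train)) stop("empty_set")
  rsG <- lapply(bkRingSystems(generated), unlist)
  rsT <- lapply(bkRingSystems(train), unlist)
  fgG <- lapply(bkFGs(generated), unlist)
  fgT <- lapply(bkFGs(train), unlist)
  list(rs = .coverageRecovery(rsG, rsT), fg = .coverageRecovery(fgG, fgT))
}

#' Enrichment factors of a score-ranked list
#'
#' `EF[X]` is the hit rate (proportion of actives) within the top `X`
#' fraction of the list sorted by decreasing score, divided by the overall
#' hit rate; the top slice holds `ceiling(X * n)` compounds.  `EF[1] = 1`
#' by construction and no EF can exceed `1 / base rate`.
#'
#' @param scores numeric prediction scores.
#' @param active logical activity flags.
#' @param fractions fractions X to evaluate.
#' @return named numeric vector of enrichment factors.
#' @export
enrichmentFactor <- function(scores, active,
                             fractions = c(0.01, 0.1, 0.5, 1)) {
  stopifnot(length(scores) == length(active))
  if (!length(scores)) stop("empty_scores")
  if (!any(active)) stop("no_actives")
  n <- length(scores)
  ord <- order(-scores)
  act <- as.logical(active)[ord]
  base <- mean(act)
  out <- vapply(fractions, function(x) {
    m <- ceiling(x * n)
    mean(act[seq_len(m)]) / base
  }, 0)
  names(out) <- paste0("EF", fractions * 100, "%")
  out
}
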