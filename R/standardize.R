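#' Standardize raw SMILES into canonical molecules
#'
#' Cleans raw SMILES the way generative-model corpora are prepared:
#' desalination (the largest organic fragment is kept), neutralization of
#' formal charges where chemically possible, validity checking and
#' canonicalization.  Stereochemistry is preserved unless `keepStereo =
#' FALSE`.  Glycoside removal is not part of default standardization; no
#' published rule set is bundled, and downstream encoding/decoding does not
#' depend on it.
#'
#' @param smiles character vector of raw SMILES.
#' @param keepStereo keep stereochemistry annotations (default `TRUE`).
#' @return data.frame with columns `input`, `smiles` (canonical SMILES, `NA`
#'   on rejection), `ok`, `reason` (`parse_failure` or `empty_after_desalt`).
#' @examples \dontrun{
#' standardizeMolecules(c("CC(=O)O.[Na+]", "c1ccccc1", "not_a_smiles"))
#' }
#' @export
standardizeMolecules <- function(smiles, keepStereo = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L)
    return(data.frame(input = character(), smiles = character(),
                      ok = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  res <- bkStandardize(smiles, keepStereo = keepStereo)
  data.frame(
    input = smiles,
    smiles = vapply(res, function(r) if (isTRUE(r$ok)) r$smiles else NA_character_, ""),
    ok = vapply(res, function(r) isTRUE(r$ok), TRUE),
    reason = vapply(res, function(r) if (isTRUE(r$ok)) NA_character_ else r$reason, ""),
    stringsAsFactors = FALSE)
}

#' Compute the descriptor panel used for constraints and metrics
#'
#' Seven descriptors per molecule: QED (quantitative estimate of
#' drug-likeness, 0-1), logP (Crippen octanol/water partition), SAS
#' (Ertl-Schuffenhauer synthetic accessibility, 1 easy - 10 hard), Mw
#' (g/mol), HBD/HBA (hydrogen-bond donor/acceptor counts) and RB (rotatable
#' bonds).  Values are a pure function of the canonical SMILES.
#'
#' @param smiles character vector of (standardized) SMILES.
#' @return data.frame with columns `smiles`, `qed`, `logp`, `sas`, `mw`,
#'   `hbd`, `hba`, `rb`; rows of unparseable input are `NA`.
#' @export
computeDescriptors <- function(smiles) {
  stopifnot(is.character(smiles))
  empty <- data.frame(smiles = character(), qed = numeric(),
                      logp = numeric(), sas = numeric(), mw = numeric(),
                      hbd = integer(), hba = integer(), rb = integer(),
                      stringsAsFactors = FALSE)
  if (length(smiles) == 0L) return(empty)
  res <- bkDescriptors(smiles)
  num <- function(f) vapply(res, function(r)
    if (is.null(r)) NA_real_ else as.numeric(r[[f]]), 0)
  int <- function(f) vapply(res, function(r)
    if (is.null(r)) NA_integer_ else as.integer(r[[f]]), 0L)
  data.frame(smiles = smiles, qed = num("qed"), logp = num("logp"),
             sas = num("sas"), mw = num("mw"), hbd = int("hbd"),
             hba = int("hba"), rb = int("rb"), stringsAsFactors = FALSE)
}

#' Remove duplicate molecules by canonical SMILES
#'
#' Keeps the first occurrence of each canonical structure; order is
#' otherwise preserved.  Inputs are canonicalized before comparison, so two
#' different writings of one molecule count as duplicates.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES without duplicates;
#'   unparseable entries are dropped with a warning.
#' @export
deduplicateMolecules <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character())
  can <- bkCanonical(smiles)
  can <- vapply(can, function(x) if (is.null(x)) NA_character_ else x, "")
  if (anyNA(can)) {
    warning(sum(is.na(can)), " unparseable SMILES dropped")
    can <- can[!is.na(can)]
  }
  can[!duplicated(can)]
}
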