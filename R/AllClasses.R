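#' @import methods
NULL

#' FragmentationResult: a molecule decomposed into attachment-marked motifs
#'
#' Produced by [fragmentMolecule()].  Fragments carry isotope-labelled dummy
#' atoms (`[k*]`) so that every broken bond is represented by one label on
#' each of its two halves; fused-edge separations (scaffold mode with
#' `fuseSplit = TRUE`) carry a *pair* of labels, one per duplicated edge
#' atom.
#'
#' @slot parentSmiles canonical SMILES of the fragmented molecule.
#' @slot mode `"motif"` (ring/off-ring + BRICS bonds) or `"scaffold"`
#'   (Bemis-Murcko scaffold/side-chain bonds).
#' @slot fuseSplit whether fused-ring shared edges of the scaffold were
#'   additionally separated.
#' @slot fragments list; each element has `smiles` (labelled fragment
#'   SMILES) and `origAtoms` (integer, parent atom index of every fragment
#'   atom in SMILES order, `-1` for dummies and duplicated edge atoms).
#' @slot cuts data.frame with columns `u`, `v` (0-based parent atom
#'   indices), `label`.
#' @slot fuses data.frame with columns `labelU`, `labelV`, `order`.
#' @slot parentRanks integer, canonical rank of every parent atom.
#' @slot acyclic scaffold mode only: the molecule had no ring, so the whole
#'   molecule became a single motif.
#' @export
setClass("FragmentationResult",
  representation(parentSmiles = "character", mode = "character",
                 fuseSplit = "logical", fragments = "list",
                 cuts = "data.frame", fuses = "data.frame",
                 parentRanks = "integer", acyclic = "logical"))

setValidity("FragmentationResult", function(object) {
  if (!object@mode %in% c("motif", "scaffold"))
    return("mode must be 'motif' or 'scaffold'")
  if (length(object@fragments) < 1L)
    return("at least one fragment required")
  labs <- c(object@cuts$label, object@fuses$labelU, object@fuses$labelV)
  if (anyDuplicated(labs)) return("bond labels must be unique")
  TRUE
})

#' MotifSequence: the canonical, order-encoded form of a fragmentation
#'
#' An ordered list of motif tokens from which [reconstructMolecule()]
#' rebuilds exactly one molecule without any attachment-point identifiers:
#' the order of the motifs and the positions of the `*` markers inside each
#' token carry all pairing information.
#'
#' @slot tokens character vector of motif SMILES tokens.
#' @slot mode fragmentation mode that produced the sequence.
#' @slot fuseSplit whether fused-edge separation was active.
#' @slot sourceSmiles canonical SMILES of the source molecule (`NA` for
#'   sampled sequences).
#' @export
setClass("MotifSequence",
  representation(tokens = "character", mode = "character",
                 fuseSplit = "logical", sourceSmiles = "character"))

setValidity("MotifSequence", function(object) {
  if (length(object@tokens) < 1L) return("empty motif sequence")
  TRUE
})

#' MotifVocabulary: bijective token/id mapping for motif sentences
#'
#' Token ids are 1-based; the four special tokens occupy ids 1-4 and the
#' remaining tokens are ordered by corpus frequency (ties broken
#' lexicographically), so identical corpora always yield identical
#' vocabularies.
#'
#' @slot tokens all tokens, position = id.
#' @slot counts corpus frequency of each token (0 for specials).
#' @slot specials named character vector (`pad`, `bos`, `eos`, `unk`).
#' @export
setClass("MotifVocabulary",
  representation(tokens = "character", counts = "integer",
                 specials = "character"))

setValidity("MotifVocabulary", function(object) {
  if (anyDuplicated(object@tokens)) return("duplicate tokens")
  if (!all(c("pad", "bos", "eos", "unk") %in% names(object@specials)))
    return("specials must name pad, bos, eos, unk")
  if (!all(object@specials %in% object@tokens))
    return("special tokens missing from vocabulary")
  TRUE
})

#' MotifGenerator: a conditional decoder-only transformer over motif tokens
#'
#' Trained by [trainGenerator()]; sampled with [beamSearch()] and
#' [sampleMolecules()].
#'
#' @slot config model configuration (see [generatorConfig()]).
#' @slot vocabulary the [MotifVocabulary-class] the model was trained on.
#' @slot params list of parameter matrices.
#' @slot trainingLog data.frame with one row per epoch (`epoch`, `nll`).
#' @slot labelTokens constraint tokens observed in the training corpus, in
#'   sentence order.
#' @slot infoTokens motif-information tokens observed in the corpus.
#' @slot mode fragmentation mode of the training corpus.
#' @slot fuseSplit fused-edge flag of the training corpus.
#' @export
setClass("MotifGenerator",
  representation(config = "list", vocabulary = "MotifVocabulary",
                 params = "list", trainingLog = "data.frame",
                 labelTokens = "character", infoTokens = "character",
                 mode = "character", fuseSplit = "logical"))

#' FixtureSpec: recipe for the programmatic natural-product-like test set
#'
#' @slot nMolecules number of molecules to assemble.
#' @slot ringLibrary SMILES of ring systems used as cores.
#' @slot substituentLibrary SMILES of substituents (attachment at atom 1).
#' @slot maxRings maximum number of ring systems joined per molecule.
#' @slot stereoFraction fraction of molecules given random tetrahedral
#'   assignments at unassigned stereocentres.
#' @slot seed RNG seed; a fixed seed yields a byte-identical set.
#' @export
setClass("FixtureSpec",
  representation(nMolecules = "integer", ringLibrary = "character",
                 substituentLibrary = "character", maxRings = "integer",
                 stereoFraction = "numeric", seed = "integer"))

setValidity("FixtureSpec", function(object) {
  if (object@nMolecules < 0L) return("nMolecules must be >= 0")
  if (length(object@ringLibrary) < 1L ||
      length(object@substituentLibrary) < 1L)
    return("ring and substituent libraries must be non-empty")
  if (object@maxRings < 1L) return("maxRings must be >= 1")
  if (object@stereoFraction < 0 || object@stereoFraction > 1)
    return("stereoFraction must be in [0, 1]")
  TRUE
})
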