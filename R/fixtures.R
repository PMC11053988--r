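## Programmatic test molecules: natural-product-like structures assembled
## from a library of common NP ring systems joined by single bonds and
## decorated with small substituents, a fraction of them carrying random
## tetrahedral assignments.  Stands in for large public NP corpora so that
## every stage of the package is testable offline; it does not attempt to
## match any real database's property distributions.

#' Default ring-system library
#'
#' About thirty ring systems common in natural products: carbocycles,
#' fused bicycles (decalin, indane, tetralin, chromane), aromatics and
#' heteroaromatics (indole, quinoline, coumarin, chromone), sugars
#' (pyranose, furanose), lactones, N/O/S heterocycles and a steroid
#' tetracycle.
#'
#' @return character vector of SMILES.
#' @export
defaultRingLibrary <- function() c(
  "C1CCCCC1", "C1CCCC1", "C1CCCCCC1", "C1CC1",
  "c1ccccc1", "c1ccc2ccccc2c1",
  "C1CCC2CCCCC2C1", "C1CCc2ccccc2C1", "C1Cc2ccccc2C1",
  "C1COc2ccccc2C1", "C1CCOC1", "C1CCOCC1",
  "C1CCNC1", "C1CCNCC1", "C1COCCN1",
  "c1ccoc1", "c1ccsc1", "c1ccncc1", "c1cncnc1",
  "c1cc[nH]c1", "c1cc[nH]n1", "c1c[nH]cn1",
  "c1ccc2[nH]ccc2c1", "c1ccc2ncccc2c1",
  "O=c1ccoc2ccccc12", "O=c1ccc2ccccc2o1",
  "O=C1CCCO1", "O=C1CCCCO1",
  "OC1OC(CO)C(O)C(O)C1O", "OC1OC(CO)C(O)C1O",
  "C1=CCCCC1",
  "C1CCC2C(C1)CCC1C2CCC2CCCC12")

#' Default substituent library
#'
#' Small side chains typical of natural products; the attachment point is
#' the first atom of each SMILES.
#'
#' @return character vector of SMILES.
#' @export
defaultSubstituentLibrary <- function() c(
  "C", "CC", "CCC", "C(C)C", "C(C)(C)C",
  "O", "OC", "OCC", "N", "NC", "N(C)C",
  "C(=O)O", "C(=O)C", "C(=O)N", "C=C", "CC=C(C)C",
  "F", "Cl", "Br", "C(F)(F)F", "C#N",
  "S", "SC", "CO", "C(C)O", "CN", "OC(C)=O", "NC(C)=O")

#' Construct a fixture-set specification
#'
#' @param nMolecules molecules to assemble.
#' @param ringLibrary,substituentLibrary SMILES libraries (see
#'   [defaultRingLibrary()], [defaultSubstituentLibrary()]).
#' @param maxRings maximum ring systems joined per molecule.
#' @param stereoFraction fraction of molecules given random tetrahedral
#'   assignments.
#' @param seed RNG seed; a fixed seed yields a byte-identical set.
#' @return a [FixtureSpec-class].
#' @export
fixtureSpec <- function(nMolecules = 1000L,
                        ringLibrary = defaultRingLibrary(),
                        substituentLibrary = defaultSubstituentLibrary(),
                        maxRings = 3L, stereoFraction = 0.3, seed = 42L) {
  new("FixtureSpec", nMolecules = as.integer(nMolecules),
      ringLibrary = ringLibrary,
      substituentLibrary = substituentLibrary,
      maxRings = as.integer(maxRings),
      stereoFraction = as.numeric(stereoFraction), seed = as.integer(seed))
}

.libraryAtomCounts <- function(lib) {
  anns <- bkAnnotate(lib)
  bad <- vapply(anns, is.null, TRUE)
  if (any(bad))
    stop("invalid_library_smiles: ", paste(lib[bad], collapse = ", "))
  vapply(anns, function(a) a$natoms, 0L)
}

## one random assembly plan: rings joined in a chain, substituents attached
## to random ring atoms (all RNG draws from the caller's stream)
.assemblyPlan <- function(spec, nAtomsRing, nAtomsSub) {
  k <- sample.int(spec@maxRings, 1L)
  rings <- sample.int(length(spec@ringLibrary), k, replace = TRUE)
  nSub <- sample.int(5L, 1L) - 1L
  subs <- if (nSub > 0L)
    sample.int(length(spec@substituentLibrary), nSub, replace = TRUE)
  else integer(0)
  parts <- c(spec@ringLibrary[rings], spec@substituentLibrary[subs])
  bonds <- list()
  if (k > 1L) for (j in seq_len(k - 1L))
    bonds[[length(bonds) + 1L]] <- c(
      j - 1L, sample.int(nAtomsRing[rings[j]], 1L) - 1L,
      j, sample.int(nAtomsRing[rings[j + 1L]], 1L) - 1L)
  for (s in seq_len(nSub)) {
    rp <- sample.int(k, 1L)
    bonds[[length(bonds) + 1L]] <- c(
      rp - 1L, sample.int(nAtomsRing[rings[rp]], 1L) - 1L,
      k + s - 1L, 0L)
  }
  list(parts = parts, bonds = bonds)
}

#' Generate the natural-product-like fixture set
#'
#' Assembles `nMolecules` molecules by joining 1..`maxRings` ring systems
#' with single bonds and decorating them with 0-4 substituents; atom
#' choices that violate valence are rejected and redrawn (deterministically
#' under the spec seed).  A `stereoFraction` subset receives random
#' tetrahedral assignments at unassigned stereocentres.  All outputs are
#' standardized canonical SMILES.
#'
#' @param spec a [FixtureSpec-class].
#' @return character vector of canonical SMILES (length `nMolecules`).
#' @export
generateFixtureSet <- function(spec = fixtureSpec()) {
  n <- spec@nMolecules
  if (n == 0L) return(character())
  nAtomsRing <- .libraryAtomCounts(spec@ringLibrary)
  nAtomsSub <- .libraryAtomCounts(spec@substituentLibrary)
  set.seed(spec@seed)
  out <- rep(NA_character_, n)
  pending <- seq_len(n)
  tries <- 0L
  while (length(pending) && tries < 50L) {
    tries <- tries + 1L
    plans <- lapply(pending, function(i)
      .assemblyPlan(spec, nAtomsRing, nAtomsSub))
    res <- bkAssemble(lapply(plans, function(p)
      list(parts = .aslist(p$parts), bonds = p$bonds)))
    okv <- vapply(res, function(r) isTRUE(r$ok), TRUE)
    out[pending[okv]] <- vapply(res[okv], `[[`, "", "smiles")
    pending <- pending[!okv]
  }
  if (length(pending))
    stop("fixture assembly failed for ", length(pending), " molecules")
  ## random stereo assignments on a fixed subset
  nStereo <- round(spec@stereoFraction * n)
  if (nStereo > 0L) {
    pick <- sample.int(n, nStereo)
    centers <- bkStereocenters(out[pick])
    items <- list(); idx <- integer(0)
    for (j in seq_along(pick)) {
      cs <- centers[[j]]
      if (is.null(cs) || !length(cs)) next
      tags <- lapply(cs, function(c)
        list(as.integer(c[[1]]), sample(c(TRUE, FALSE), 1L)))
      items[[length(items) + 1L]] <- list(smiles = out[pick[j]],
                                          tags = tags)
      idx <- c(idx, pick[j])
    }
    if (length(items)) {
      assigned <- bkAssignStereo(items)
      for (j in seq_along(idx))
        if (!is.null(assigned[[j]])) out[idx[j]] <- assigned[[j]]
    }
  }
  std <- standardizeMolecules(out)
  if (!all(std$ok))
    stop("fixture standardization failed for ", sum(!std$ok), " molecules")
  std$smiles
}

#' Generate a two-class conditioned toy corpus
#'
#' Builds ~`nPerClass` sentences per constraint class from two disjoint
#' structural worlds: class A molecules are saturated carbocycles with
#' alkyl/hydroxy decoration, class B are aromatic heterocycles with
#' halogen/methoxy decoration.  Their motif-token inventories are verified
#' disjoint (colliding molecules are dropped), which makes class purity of
#' sampled motifs a parameter-free readout of constraint conditioning.
#'
#' @param seed RNG seed.
#' @param nPerClass target sentences per class.
#' @return list with `sentences`, `classes` (token per sentence),
#'   `sequences`, `smiles`, `poolA`, `poolB` (the motif-token pools).
#' @export
generateConditionedToyCorpus <- function(seed = 7L, nPerClass = 200L) {
  specA <- fixtureSpec(nMolecules = ceiling(nPerClass * 2.5),
                       ringLibrary = c("C1CCCCC1", "C1CCCC1", "C1CCCCCC1"),
                       substituentLibrary = c("C", "CC", "C(C)C", "O"),
                       maxRings = 2L, stereoFraction = 0, seed = seed)
  specB <- fixtureSpec(nMolecules = ceiling(nPerClass * 2.5),
                       ringLibrary = c("c1ccncc1", "c1ccoc1", "c1ccsc1"),
                       substituentLibrary = c("F", "Cl", "Br", "OC"),
                       maxRings = 2L, stereoFraction = 0, seed = seed + 1L)
  molsA <- unique(generateFixtureSet(specA))
  molsB <- unique(generateFixtureSet(specB))
  seqA <- Filter(function(s) inherits(s, "MotifSequence"),
                 .canonicalizeBatch(suppressWarnings(
                   fragmentMolecules(molsA, "motif"))))
  seqB <- Filter(function(s) inherits(s, "MotifSequence"),
                 .canonicalizeBatch(suppressWarnings(
                   fragmentMolecules(molsB, "motif"))))
  poolA <- unique(unlist(lapply(seqA, motifTokens)))
  poolB <- unique(unlist(lapply(seqB, motifTokens)))
  clash <- intersect(poolA, poolB)
  if (length(clash)) {
    seqA <- Filter(function(s) !any(s@tokens %in% clash), seqA)
    seqB <- Filter(function(s) !any(s@tokens %in% clash), seqB)
    poolA <- setdiff(poolA, clash)
    poolB <- setdiff(poolB, clash)
  }
  nKeep <- min(nPerClass, length(seqA), length(seqB))
  seqA <- seqA[seq_len(nKeep)]
  seqB <- seqB[seq_len(nKeep)]
  sentences <- c(buildSentences(seqA, rep("cls_a", length(seqA))),
                 buildSentences(seqB, rep("cls_b", length(seqB))))
  list(sentences = sentences,
       classes = c(rep("cls_a", length(seqA)), rep("cls_b", length(seqB))),
       sequences = c(seqA, seqB),
       smiles = c(vapply(seqA, function(s) s@sourceSmiles, ""),
                  vapply(seqB, function(s) s@sourceSmiles, "")),
       poolA = poolA, poolB = poolB)
}
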