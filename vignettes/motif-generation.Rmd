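---
title: "Motif sequences and conditional generation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif sequences and conditional generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Natural products carry dense stereochemistry and polycyclic ring systems
that character-level SMILES generators handle poorly: two nearly identical
structures can have wildly different SMILES strings, and a single wrong
character invalidates a molecule.  `chemotif` instead treats a molecule as
a short *sentence of fragments*.  Each fragment (a **motif**) is a
chemically meaningful subgraph — a ring system, a side chain, a
BRICS-style synthon — serialized as SMILES with `*` attachment markers.  A
conditional transformer learns the grammar of these sentences under
discrete property constraints, and new molecules are decoded by beam
search followed by exact reconstruction.

The package's central guarantee is *losslessness*: fragmentation followed
by canonicalization followed by reconstruction returns the starting
molecule (disregarding chirality; see "Stereochemistry" below).  Because
every sampled sentence either reconstructs deterministically or is flagged
invalid, the generator never needs to predict attachment points.

## Fragmentation schemes

Two bond-breaking schemes are provided by `fragmentMolecules()`:

* **motif mode** breaks (i) every acyclic single bond joining a ring atom
  to an off-ring atom or to an atom of a different ring, and (ii) every
  BRICS-cleavable bond.  The two rules name bond sets, not cut events: a
  bond matched by both is broken once (the union of the bond sets is taken
  before cutting).  The full standard BRICS table is used.
* **scaffold mode** breaks every single bond between the Bemis–Murcko
  scaffold and its side chains.  Scaffold membership is computed by
  iteratively pruning terminal atoms and then restoring atoms multiply
  bonded directly to the remaining core (so cyclohexanone keeps its
  carbonyl oxygen while acetophenone loses its whole acetyl group); the
  resulting scaffolds agree with the standard RDKit Murcko scaffolds,
  which the test suite checks by heavy-atom count on reference cases.

Ring bonds are never broken.  Each break inserts two dummy atoms sharing a
bond label, so the fragment set memorizes the original connectivity; bond
labels are assigned in canonical-atom-rank order of the bond's
lower-ranked atom, which makes fragmentation deterministic under input
atom renumbering.

With `fuseSplit = TRUE`, scaffold mode additionally separates fused rings
at shared edges: the two edge atoms are duplicated into both subrings and
all four copies become dummy atoms, yielding subring motifs such as
`*1*CCCC1`.  Because the duplicated atoms lose their element identity, the
separation is restricted to edges whose two atoms are unsubstituted
carbons belonging to exactly two non-aromatic SSSR rings.  Three cases are
deliberately left intact:

* *bridged systems* (an atom in more than two rings, or edge removal that
  does not yield two components) — a known structural transform this
  encoding does not attempt;
* *substituted fusion atoms* — replacing them with `*` would orphan their
  substituent markers;
* *aromatic fusions* — a kekulized aromatic ring containing dummies is
  re-aromatized by the toolkit on reparse, which desynchronizes the bond
  order recorded on the two duplicated edge copies and breaks exactness.

On reconstruction, merged edge atoms are restored as carbons — correct by
construction given the carbon-only eligibility rule.

## Canonical sequences without attachment bookkeeping

The fragment-adjacency graph of any fragmentation is a tree (only acyclic
bonds are cut, and each fused-edge separation nests tree-wise).
`canonicalizeMotifs()` serializes this tree so that the explicit bond
labels become redundant:

1. the **root** is the fragment holding the parent atom of lowest
   canonical rank;
2. every non-root fragment's token is written *rooted at its parent-facing
   dummy*, so its first atom is the marker that attaches it to what came
   before;
3. children are visited depth-first in the order their attachment slots
   appear in the parent token's atom order.

Decoding (`reconstructMolecules()`) is then a stack automaton: read tokens
left to right, keep open slots on a stack; each new token binds its first
marker to the most recently opened slot and pushes its remaining slots in
reverse token order.  Two mutually bonded markers inside one token form a
single fused-edge slot that merges with its partner pair by atom
identification (orientation is encoded by the rooting: the child's root
dummy pairs with the first dummy of the parent's pair).  A child ordering
such as "sort children by their canonical SMILES" would *not* be
invertible without labels, which is why slot order in the parent token is
the ordering contract.

Failure modes of arbitrary (model-generated) sequences are data, not
errors: `dangling_marker`, `incompatible_fused_edge`,
`valence_violation`, `invalid_token`, `empty_sequence` — these feed the
validity metric.

### Stereochemistry

Round-trip verification (`verifyRoundtrip()`) reports two rates: the
headline accuracy compares canonical SMILES with stereochemistry stripped,
and a stereo-strict rate is reported alongside.  Tetrahedral tags adjacent
to cut bonds survive cutting and rejoining (the marker stands in for the
departed neighbour), but a minority of centres lose their assignment when
their chirality is only defined in the context of the whole molecule, and
fused-edge separation erases tags on the duplicated edge atoms.  On the
packaged 1,000-molecule fixture set the stereo-stripped rate is 100% in
both schemes and the stereo-strict rate is 93–97%.

## Sentences, vocabulary, conditioning

A training sentence is `[constraint tokens][motif-info token]<bos>[motif
tokens]<eos>`.  Constraint tokens are discrete property bins; the default
thresholds (configurable, half-open `[lo, hi)` windows) are QED ≥ 0.5,
logP ∈ [0, 5), SAS < 4 — standard drug-likeness heuristics declared as
configuration, not inferred from anywhere.  An activity labelling helper
applies a strict score threshold (scores above it are `active`).  The
motif-info token records the total attachment-point count of the
sentence, as exact integers 0–12 and `13+` above (a bounded vocabulary).
One token per motif is the tokenization unit; vocabulary ids are assigned
specials-first, then by descending corpus frequency with lexicographic
tie-break, so a corpus maps to exactly one vocabulary.

## The generator

The model is a decoder-only transformer implemented directly on matrices
in R: token embedding plus sinusoidal positional encoding, post-norm
blocks of masked multi-head scaled dot-product attention
(`softmax(QK'/sqrt(d_k))V`) and a ReLU feed-forward network, residual
connections and layer normalization around each sublayer, and a linear +
softmax head.  Training minimizes the next-token negative log-likelihood
over motif positions only — the constraint and info positions are
conditioning context.  Gradients are hand-derived and verified against
central finite differences in the test suite; optimization is Adam with
linear warm-up; all randomness flows from one seed, so a seed + corpus
pair reproduces the loss curve bit-for-bit.

Default dimensions (`generatorConfig()`: d_model 256, 8 heads, 4 layers,
d_ff 1024, dropout 0.1) are declared, tunable configuration.  The test
suite and the worked examples use deliberately small instantiations
(d_model 32–48, 1–4 layers, corpora of 10–400 sentences) so that every
training run finishes in seconds to a few minutes on one CPU; the
architecture is size-agnostic.

Sampling is beam search over accumulated log-probability with no length
normalization, deterministic token-id tie-breaks, always-banned specials
and context tokens, optional banned-token lists and repeat suppression,
and optional seed motifs forced at the start of every hypothesis (for
scaffold-anchored generation).  Beam width 1 is greedy decoding; a beam
wide enough to cover the whole sequence space reproduces the
exhaustive-enumeration argmax, which the tests check on tiny
vocabularies.  `sampleMolecules()` diversifies draws by cycling the
observed motif-info tokens and sampling among the top-K continuations at
a temperature; the mechanism by which one trained model yields thousands
of distinct molecules is not fully pinned down by the underlying method
description, so this scheme is a declared design choice with a recorded
seed.

## Metrics

`conditionalMetrics()` computes validity (valid/total), uniqueness
(unique canonical SMILES/valid) and novelty (valid unique not in
training/valid unique).  `distributionMetrics()` follows the MOSES
conventions on 2048-bit Morgan radius-2 fingerprints: SNN (mean nearest
-neighbour Tanimoto to the reference), Frag/Scaf (cosine similarity of
BRICS-fragment / Murcko-scaffold count vectors) and IntDiv (1 − mean
pairwise Tanimoto; defined as 0 for a single molecule, where no pair
exists).  Ring systems are fused-ring connected components; functional
groups come from the Ertl extraction algorithm.  Coverage divides the
unique generated items found in the training set by the *total* generated
occurrences; recovery divides the same numerator by the *unique* generated
items — both denominators reference the generated set, as that convention
defines them; a third ratio over the unique training items
(`trainRecovery`) is reported as an additional diagnostic since it is
often what "recovery" intuitively suggests.  Enrichment factors use
`ceiling(X·n)` top slices of the score-ranked list; EF[100%] is exactly 1
and no EF can exceed the reciprocal base rate.  The Fréchet ChemNet
Distance is excluded: it requires externally downloaded network weights,
which this package deliberately avoids.

## The fixture generator

`generateFixtureSet()` assembles natural-product-like molecules from ~30
embedded ring systems (decalin, steroid tetracycle, chromone, indole,
pyranose, lactones, ...) joined by single bonds and decorated with 0–4
small substituents; invalid valence choices are rejected and redrawn
deterministically under the spec seed.  A configurable fraction (default
0.3) receives random tetrahedral assignments.  The default study set is
1,000 molecules at seed 42.  What it emulates: ring-system diversity,
fused and isolated rings, stereocentres, heteroatom decoration — enough
for every fragmentation rule to fire.  What it does not emulate: real NP
property distributions, glycosides, macrocycles, bridged cages, E/Z
olefin stereochemistry.  Passing round-trip and conditioning tests on
these fixtures therefore demonstrates correctness of the encoding and the
learning machinery, not chemical coverage of any real database.

`generateConditionedToyCorpus()` builds two constraint classes from
disjoint structural worlds (saturated carbocycles + alkyl/hydroxy
substituents vs aromatic heterocycles + halogen/methoxy substituents),
verifies the motif-token pools are disjoint, and balances the classes
exactly.  Class purity of sampled motifs is then a parameter-free readout
of whether constraint conditioning works.

## Numerical choices and degenerate inputs

* Layer-norm epsilon 1e-5; attention mask uses additive −Inf with the
  diagonal always visible (padding rows would otherwise normalize over an
  empty set).
* Bond labels are positive integers carried as dummy-atom isotopes during
  fragmentation and stripped from the emitted tokens.
* Acyclic molecules in scaffold mode become a single flagged
  whole-molecule motif; a motif with no markers is a complete molecule.
* Charged or isotopic atoms are fragmented as-is.
* Memorization checks use sentences with pairwise distinct
  constraint/info prefixes, because greedy decoding is a function of the
  prefix — two different continuations of one prefix cannot both be
  reproduced.
* Empty inputs: empty corpora, zero-molecule specs and `n = 0` sampling
  requests return empty structures rather than erroring, except where an
  empty input is meaningless (`buildVocabulary`, metrics), which raise
  typed errors.

## Glycoside handling

Sugar removal is named as a corpus-preparation step in this problem
domain but no published rule set defines it precisely; default
standardization therefore skips it, and nothing downstream depends on it
(round trips and generation operate on whatever molecule they are given).

## Known limitations

* Fused-edge separation skips aromatic fusions, bridgeheads and
  substituted fusion atoms (exactness over aggressiveness).
* Ring opening/closing and bridged-ring transforms are out of scope.
* The stereo-strict round-trip rate is below the stereo-stripped rate
  (93–97% vs 100% on the fixture set).
* The transformer is CPU-oriented R; it is intended for method-scale
  corpora (10²–10⁴ sentences), not for training on hundreds of thousands
  of molecules.
* The RDKit helper process is required at run time; all chemistry
  primitives (parsing, canonicalization, descriptors, BRICS perception,
  fingerprints) are delegated to it, while every algorithm of the package
  itself — fragmentation rules, sequence canonicalization, the stack
  decoder, the transformer, beam search, metrics — is implemented in R.
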