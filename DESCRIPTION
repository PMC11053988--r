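Package: chemotif
Title: Motif-Sequence Encoding and Conditional Transformer Generation of
    Natural-Product-Like Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Losslessly encodes a molecule as a canonical sequence of
    fragment motifs with attachment markers, using either a motif-level
    fragmentation scheme (ring/off-ring single bonds plus BRICS bonds) or a
    scaffold-level scheme (Bemis-Murcko scaffold/side-chain cuts, optionally
    with fused-ring shared-edge separation).  An exact stack-based decoder
    reconstructs molecules from motif sequences without attachment-point
    bookkeeping.  A conditional decoder-only transformer, implemented and
    trained entirely in R, learns motif-sequence grammar under discrete
    property constraints and samples new molecules by beam search.  Includes
    benchmark metrics (validity, uniqueness, novelty, nearest-neighbour
    similarity, fragment/scaffold similarity, internal diversity,
    ring-system and functional-group coverage/recovery, enrichment factors)
    and a programmatic generator of natural-product-like test molecules.
    Standard cheminformatics primitives are delegated to a bundled RDKit
    helper process.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    processx
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    optparse
SystemRequirements: Python (>= 3.8) with the RDKit package importable as
    'rdkit'; the interpreter is located via the chemotif.python option, the
    CHEMOTIF_PYTHON environment variable, or 'python' on the PATH.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
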