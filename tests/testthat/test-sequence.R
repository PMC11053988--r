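test_that("canonical sequences reconstruct their molecules exactly", {
  for (smi in c("CC1CCCCC1", "CC(=O)Nc1ccccc1", "C[C@H](O)c1ccccc1",
                "CC1CCC2CCCCC2C1")) {
    for (mode in c("motif", "scaffold")) {
      seqc <- canonicalizeMotifs(fragmentMolecule(smi, mode))
      expect_identical(reconstructMolecule(seqc), smi,
                       label = paste(smi, mode))
    }
  }
  ## single whole-molecule motif decodes to itself
  expect_identical(reconstructMolecule(
    canonicalizeMotifs(fragmentMolecule("c1ccccc1", "motif"))), "c1ccccc1")
})

test_that("canonical order is invariant to input atom renumbering", {
  set.seed(11)
  smis <- smallFixtureSet(30L)[1:10]
  anns <- chemotif:::bkAnnotate(smis)
  for (i in seq_along(smis)) {
    ref <- canonicalizeMotifs(fragmentMolecule(smis[i], "motif"))@tokens
    n <- anns[[i]]$natoms
    for (k in 1:3) {
      perm <- sample.int(n) - 1L
      alt <- chemotif:::bkRenumber(list(list(smiles = smis[i],
                                             perm = as.list(perm))))[[1]]
      expect_false(is.null(alt))
      altTokens <- canonicalizeMotifs(fragmentMolecule(alt, "motif"))@tokens
      expect_identical(altTokens, ref, label = paste(smis[i], "perm", k))
    }
  }
})

test_that("canonicalization is idempotent through a round trip", {
  smis <- smallFixtureSet(30L)[11:25]
  for (mode in c("motif", "scaffold")) {
    seqs <- canonicalizeMotifs(fragmentMolecules(smis, mode))
    rec <- reconstructMolecules(seqs)
    expect_true(all(rec$valid))
    again <- canonicalizeMotifs(fragmentMolecules(rec$smiles, mode))
    for (i in seq_along(seqs))
      expect_identical(again[[i]]@tokens, seqs[[i]]@tokens)
  }
})

test_that("invalid sequences are flagged with reasons, not errors", {
  ## unmatched marker: one open slot never filled
  r1 <- reconstructMolecules(list(c("*C1CCCCC1")))
  expect_false(r1$valid[1])
  expect_equal(r1$reason[1], "dangling_marker")
  ## extra motif with no open slot
  r2 <- reconstructMolecules(list(c("c1ccccc1", "*C")))
  expect_false(r2$valid[1])
  expect_equal(r2$reason[1], "dangling_marker")
  ## fused-edge slot paired against a bond slot
  r3 <- reconstructMolecules(list(c("C1CC(*)(*)CC1", "*1*CCCC1")))
  expect_false(r3$valid[1])
  ## empty sequence
  r4 <- reconstructMolecules(list(character(0)))
  expect_false(r4$valid[1])
  expect_error(reconstructMolecule(c("*C1CCCCC1")), "dangling_marker")
})

test_that("reconstruction is total on the image of canonicalization", {
  smis <- smallFixtureSet(30L)
  for (mode in c("motif", "scaffold")) {
    seqs <- canonicalizeMotifs(fragmentMolecules(smis, mode))
    ok <- vapply(seqs, function(s) inherits(s, "MotifSequence"), TRUE)
    expect_true(all(ok))
    rec <- reconstructMolecules(seqs)
    expect_true(all(rec$valid))
  }
})

test_that("round-trip verification counts failures as data", {
  v <- verifyRoundtrip(c("C"), "motif")
  expect_equal(v$accuracy, 1)
  smis <- c("CC1CCCCC1", "CCc1ccccc1", "CC(C)C1CCC(C)CC1O")
  v2 <- verifyRoundtrip(smis, "motif")
  expect_equal(v2$accuracy, 1)
  expect_equal(nrow(v2$failures), 0L)
  expect_length(v2$sequences, 3L)
})

test_that("corpus file round trip preserves sequences", {
  seqs <- canonicalizeMotifs(
    fragmentMolecules(c("CC1CCCCC1", "CCc1ccccc1"), "motif"))
  path <- tempfile(fileext = ".tsv")
  writeMotifCorpus(seqs, path)
  back <- readMotifCorpus(path)
  expect_equal(length(back), 2L)
  expect_identical(back[[1]]@tokens, seqs[[1]]@tokens)
  expect_identical(back[[2]]@sourceSmiles, seqs[[2]]@sourceSmiles)
})
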