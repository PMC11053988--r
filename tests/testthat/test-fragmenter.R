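test_that("motif-mode rules cut ring/off-ring and ring/ring single bonds", {
  fr <- fragmentMolecule("CC1CCCCC1", "motif")
  expect_s4_class(fr, "FragmentationResult")
  expect_equal(nMotifs(fr), 2L)                 # methyl + cyclohexane
  toks <- sort(gsub("\\[[0-9]+\\*\\]", "*", motifTokens(fr)))
  expect_identical(toks, c("*C", "*C1CCCCC1"))

  ## benzene: no acyclic single bonds, no BRICS bonds -> whole molecule
  fr2 <- fragmentMolecule("c1ccccc1", "motif")
  expect_equal(nMotifs(fr2), 1L)
  expect_equal(nrow(fr2@cuts), 0L)

  ## bicyclohexyl: the single ring-ring bond qualifies
  fr3 <- fragmentMolecule("C1CCC(CC1)C1CCCCC1", "motif")
  expect_equal(nMotifs(fr3), 2L)
  expect_true(all(vapply(motifTokens(fr3), function(t)
    length(gregexpr("\\*", t)[[1]]) == 1L, TRUE)))
})

test_that("scaffold-mode cuts separate Bemis-Murcko side chains", {
  fr <- fragmentMolecule("CCc1ccccc1", "scaffold")
  toks <- sort(gsub("\\[[0-9]+\\*\\]", "*", motifTokens(fr)))
  expect_identical(toks, c("*CC", "*c1ccccc1"))

  ## scaffold equals molecule: nothing to cut
  fr2 <- fragmentMolecule("C1CCCCC1", "scaffold")
  expect_equal(nMotifs(fr2), 1L)

  ## acetophenone: the whole acetyl side chain leaves the benzene scaffold
  fr3 <- fragmentMolecule("CC(=O)c1ccccc1", "scaffold")
  toks3 <- sort(gsub("\\[[0-9]+\\*\\]", "*", motifTokens(fr3)))
  expect_identical(toks3, c("*C(C)=O", "*c1ccccc1"))

  ## cyclohexanone: exocyclic double-bonded O stays on the scaffold
  fr4 <- fragmentMolecule("O=C1CCCCC1", "scaffold")
  expect_equal(nMotifs(fr4), 1L)

  ## acyclic molecule: flagged single whole-molecule motif
  fr5 <- fragmentMolecule("CCOCC", "scaffold")
  expect_true(fr5@acyclic)
  expect_equal(nMotifs(fr5), 1L)
})

test_that("scaffold membership agrees with the RDKit Murcko oracle", {
  smis <- c("CCc1ccccc1", "CC(=O)c1ccccc1", "O=C1CCCCC1",
            "C=Cc1ccccc1", "CC1CCC2CCCCC2C1", "OCC1OC(O)C(O)C1O")
  sc <- unlist(bkScaffold(smis))
  for (i in seq_along(smis)) {
    fr <- fragmentMolecule(smis[i], "scaffold")
    scafTok <- NULL
    member <- chemotif:::murckoMembership(
      chemotif:::.annotationFrames(chemotif:::bkAnnotate(smis[i])[[1]]))
    for (f in fr@fragments) {
      oa <- f$origAtoms[f$origAtoms >= 0L]
      if (length(oa) && all(member[oa + 1L]) && sum(member) == length(oa))
        scafTok <- f$smiles
    }
    expect_false(is.null(scafTok))
    ## every scaffold atom ends up in exactly the scaffold fragment
    expect_equal(sum(member),
                 sum(unlist(lapply(fr@fragments, function(f)
                   sum(member[f$origAtoms[f$origAtoms >= 0L] + 1L]))))
    )
    ## and the RDKit scaffold of the parent has the same heavy-atom count
    annSc <- chemotif:::bkAnnotate(sc[i])[[1]]
    expect_equal(sum(member), annSc$natoms)
  }
})

test_that("fuse splitting separates saturated fused rings losslessly", {
  fr <- fragmentMolecule("C1CCC2CCCCC2C1", "scaffold", fuseSplit = TRUE)
  expect_equal(nMotifs(fr), 2L)
  expect_equal(nrow(fr@fuses), 1L)
  toks <- gsub("\\[[0-9]+\\*\\]", "*", motifTokens(fr))
  expect_true(all(grepl("\\*.*\\*", toks)))   # two markers per subring
  ## steroid tetracycle: three shared edges -> four subrings
  fr2 <- fragmentMolecule("C1CCC2C(C1)CCC1C2CCC2CCCC12", "scaffold",
                          fuseSplit = TRUE)
  expect_equal(nrow(fr2@fuses), 3L)
  expect_equal(nMotifs(fr2), 4L)
  ## aromatic fusions are not separated (exactness first)
  fr3 <- fragmentMolecule("c1ccc2ccccc2c1", "scaffold", fuseSplit = TRUE)
  expect_equal(nMotifs(fr3), 1L)
})

test_that("fragmentation conserves atoms and pairs every marker", {
  fx <- smallFixtureSet(60L)
  for (mode in c("motif", "scaffold")) {
    frs <- fragmentMolecules(fx, mode)
    anns <- chemotif:::bkAnnotate(fx)
    for (i in seq_along(frs)) {
      fr <- frs[[i]]
      orig <- unlist(lapply(fr@fragments, function(f)
        f$origAtoms[f$origAtoms >= 0L]))
      expect_false(anyDuplicated(orig) > 0)
      expect_equal(sort(orig), seq_len(anns[[i]]$natoms) - 1L)
      labs <- unlist(lapply(fr@fragments, function(f)
        chemotif:::.fragLabels(f$smiles)))
      expect_true(all(table(labs) == 2L))
      expect_setequal(unique(labs), fr@cuts$label)
    }
  }
  ## fused-edge mode: the two duplicated edge atoms per split are counted
  ## once in the parent and appear as dummies in the motifs
  frs <- fragmentMolecules(fx, "scaffold", fuseSplit = TRUE)
  anns <- chemotif:::bkAnnotate(fx)
  for (i in seq_along(frs)) {
    fr <- frs[[i]]
    orig <- unlist(lapply(fr@fragments, function(f)
      f$origAtoms[f$origAtoms >= 0L]))
    expect_false(anyDuplicated(orig) > 0)
    expect_equal(length(orig) + 2L * nrow(fr@fuses), anns[[i]]$natoms)
  }
})

test_that("motif-mode motifs are lighter than their parents on average", {
  fx <- smallFixtureSet(60L)
  frs <- fragmentMolecules(fx, "motif")
  st <- motifStatistics(frs)
  parents <- chemotif:::bkBasic(fx)
  meanParent <- mean(vapply(parents, `[[`, 0, "mw"))
  expect_lt(st$meanMotifWeight, meanParent)
  expect_equal(st$nMotifs, sum(as.integer(st$attachHistogram)))
  ## no motif larger than its parent
  for (fr in frs) {
    sizes <- vapply(fr@fragments, function(f)
      sum(f$origAtoms >= 0L), 0L)
    expect_true(all(sizes <= length(fr@parentRanks)))
  }
})

test_that("motif statistics of single fragments follow hand arithmetic", {
  frC <- fragmentMolecule("C", "motif")
  expect_equal(motifStatistics(list(frC))$meanMotifSize, 1)
  st <- motifStatistics(fragmentMolecule("CC1CCCC1", "motif"))
  expect_equal(st$meanMotifSize, mean(c(1, 5)))   # methyl + cyclopentane
})
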