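test_that("standardization desalts, neutralizes and canonicalizes", {
  res <- standardizeMolecules(c("CC(=O)O.[Na+]", "CC(=O)[O-].[Na+]",
                                "c1ccccc1", "not_a_smiles", ""))
  expect_equal(res$smiles[1], "CC(=O)O")     # sodium stripped
  expect_equal(res$smiles[2], "CC(=O)O")     # acetate neutralized
  expect_equal(res$smiles[3], "c1ccccc1")    # already standard
  expect_false(res$ok[4])
  expect_equal(res$reason[4], "parse_failure")
  expect_false(res$ok[5])
})

test_that("standardization is idempotent and keeps one connected fragment", {
  smis <- c("OCC", "C[C@H](N)C(=O)O", "c1ccc(CC2CCNC2)cc1",
            smallFixtureSet(30L)[1:10])
  once <- standardizeMolecules(smis)
  twice <- standardizeMolecules(once$smiles)
  expect_identical(once$smiles, twice$smiles)
  expect_false(any(grepl(".", once$smiles, fixed = TRUE)))
})

test_that("descriptor panel matches hand-derived values", {
  d <- computeDescriptors(c("C", "CCO", "c1ccccc1"))
  expect_identical(d$hbd, c(0L, 1L, 0L))     # methane none, ethanol 1 O-H
  expect_identical(d$hba, c(0L, 1L, 0L))
  expect_identical(d$rb, c(0L, 0L, 0L))
  ## benzene C6H6: 6*12.011 + 6*1.008
  expect_equal(d$mw[3], 6 * 12.011 + 6 * 1.008, tolerance = 1e-3)
  expect_true(all(is.finite(unlist(d[, -1]))))
  expect_true(all(d$qed >= 0 & d$qed <= 1))
  expect_true(all(d$sas >= 1 & d$sas <= 10))
})

test_that("molecular weight agrees with the OpenBabel oracle", {
  smis <- c("CCO", "c1ccccc1", "CC(=O)Nc1ccccc1")
  mine <- computeDescriptors(smis)$mw
  ob <- vapply(smis, function(s) {
    ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", s, identity))$MW
  }, 0)
  expect_equal(mine, unname(ob), tolerance = 1e-3)
})

test_that("descriptors are a pure function of the canonical SMILES", {
  a <- computeDescriptors(c("OCC", "C(O)C"))
  expect_equal(a[1, -1], a[2, -1], ignore_attr = TRUE)
})

test_that("deduplication keeps first occurrences by canonical identity", {
  expect_identical(deduplicateMolecules(c("CCO", "OCC")), "CCO")
  expect_identical(deduplicateMolecules(c("CCO", "CCN")), c("CCO", "CCN"))
  expect_identical(deduplicateMolecules(character()), character())
})
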