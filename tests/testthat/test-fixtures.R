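test_that("fixture generation is deterministic and degenerate-safe", {
  expect_identical(generateFixtureSet(fixtureSpec(nMolecules = 0L)),
                   character())
  a <- generateFixtureSet(fixtureSpec(nMolecules = 25L, seed = 9L))
  b <- generateFixtureSet(fixtureSpec(nMolecules = 25L, seed = 9L))
  expect_identical(a, b)
  c <- generateFixtureSet(fixtureSpec(nMolecules = 25L, seed = 10L))
  expect_false(identical(a, c))
})

test_that("invalid library SMILES are rejected", {
  expect_error(generateFixtureSet(fixtureSpec(
    nMolecules = 2L, ringLibrary = c("C1CCCCC1", "not_smiles"))),
    "invalid_library_smiles")
})

test_that("fixtures standardize and fragment under both schemes", {
  fx <- smallFixtureSet(60L)
  std <- standardizeMolecules(fx)
  expect_true(all(std$ok))
  expect_identical(std$smiles, fx)            # already canonical
  for (mode in c("motif", "scaffold")) {
    frs <- fragmentMolecules(fx, mode)
    expect_false(any(vapply(frs, is.null, TRUE)))
    expect_true(all(vapply(frs, nMotifs, 0L) >= 1L))
  }
  ## the requested stereo fraction carries tetrahedral centres
  expect_gt(mean(grepl("@", fx)), 0.1)
})

test_that("the conditioned toy corpus has disjoint, balanced classes", {
  toy <- toyCorpus()
  expect_length(intersect(toy$poolA, toy$poolB), 0L)
  nA <- sum(toy$classes == "cls_a")
  nB <- sum(toy$classes == "cls_b")
  expect_lt(abs(nA - nB) / max(nA, nB), 0.05)
  expect_gte(min(nA, nB), 150L)
  ## every sentence reconstructs to a valid molecule
  idx <- seq(1L, length(toy$sequences), by = 10L)
  rec <- reconstructMolecules(toy$sequences[idx])
  expect_true(all(rec$valid))
  ## class labels sit first in each sentence
  expect_true(all(vapply(seq_along(toy$sentences), function(i)
    toy$sentences[[i]][1] == toy$classes[i], TRUE)))
})
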