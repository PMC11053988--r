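test_that("validity, uniqueness and novelty match hand counts", {
  gen <- data.frame(
    smiles = c("CCO", "CCN", "CCO", "c1ccccc1", "CC", "CCC", "CCCC",
               "CCCCC", "CO", NA),
    valid = c(rep(TRUE, 9), FALSE))
  m <- conditionalMetrics(gen, trainSmiles = c("CCO", "CC"))
  expect_equal(m$validity, 0.9)
  expect_equal(m$uniqueness, 8 / 9)          # CCO counted once among 9 valid
  expect_equal(m$novelty, 6 / 8)             # CCO and CC known from training
  ## degenerate directions
  allTrain <- conditionalMetrics(c("CCO", "OCC"), "CCO")
  expect_equal(allTrain$novelty, 0)
  allDistinct <- conditionalMetrics(c("CCO", "CCN"), "CCCCCCCC")
  expect_equal(allDistinct$uniqueness, 1)
  expect_error(conditionalMetrics(data.frame()), "empty_generated")
})

test_that("distribution metrics are exact on self-comparison", {
  S <- c("CCO", "CC(=O)Nc1ccccc1", "CC1CCCCC1")
  d <- distributionMetrics(S, S)
  expect_equal(d$snn, 1)
  expect_equal(d$fragSim, 1)
  expect_equal(d$scafSim, 1)
  expect_gte(d$intDiv, 0)
  ## a single molecule has no pair: IntDiv defined as 0
  expect_equal(distributionMetrics("CCO", S)$intDiv, 0)
})

test_that("SNN agrees with set-arithmetic Tanimoto on tiny sets", {
  gen <- c("CCO", "CCCO")
  ref <- c("CCN", "CCC")
  fps <- chemotif:::bkFingerprint(c(gen, ref))
  sets <- lapply(fps, function(b) sort(unlist(b)))
  tani <- function(a, b)
    length(intersect(a, b)) / length(union(a, b))
  expected <- mean(c(max(tani(sets[[1]], sets[[3]]), tani(sets[[1]], sets[[4]])),
                     max(tani(sets[[2]], sets[[3]]), tani(sets[[2]], sets[[4]]))))
  d <- distributionMetrics(gen, ref)
  expect_equal(d$snn, expected, tolerance = 1e-12)
})

test_that("ring-system/functional-group coverage and recovery denominators", {
  gen <- c("CC1CCCCC1", "CC1CCCCC1O", "c1ccccc1CC1CCCCC1")
  train <- c("C1CCCCC1", "CCO")
  r <- rsFgMetrics(gen, train)
  ## generated ring systems: cyclohexane x3 (in train), benzene x1 (not)
  expect_equal(r$rs$coverage, 1 / 4)
  expect_equal(r$rs$recovery, 1 / 2)
  expect_equal(r$rs$trainRecovery, 1 / 1)
  ## structurally contained generation recovers everything
  r2 <- rsFgMetrics(c("C1CCCCC1", "C1CCCCC1"), c("C1CCCCC1"))
  expect_equal(r2$rs$recovery, 1)
  ## disjoint ring chemistry covers nothing
  r3 <- rsFgMetrics("c1ccncc1", "C1CCCCC1")
  expect_equal(r3$rs$coverage, 0)
})

test_that("enrichment factors follow the ranked hit-rate definition", {
  ## all actives ranked first, base rate 10%: EF[10%] = 10
  scores <- 100:1
  active <- c(rep(TRUE, 10), rep(FALSE, 90))
  ef <- enrichmentFactor(scores, active, c(0.1, 1))
  expect_equal(unname(ef["EF10%"]), 10)
  expect_equal(unname(ef["EF100%"]), 1)
  ## EF can never exceed 1 / base rate
  expect_true(all(ef <= 1 / mean(active) + 1e-12))
  ## uniformly interleaved actives: EF ~ 1 at every fraction
  act2 <- rep(c(TRUE, rep(FALSE, 9)), 10)
  ef2 <- enrichmentFactor(100:1, act2, c(0.1, 0.5, 1))
  expect_equal(unname(ef2), rep(1, 3))
  expect_error(enrichmentFactor(1:3, c(FALSE, FALSE, FALSE)), "no_actives")
  expect_error(enrichmentFactor(numeric(0), logical(0)), "empty_scores")
})

test_that("metrics are invariant to permutations of their inputs", {
  gen <- c("CCO", "CC1CCCCC1", "c1ccccc1")
  ref <- c("CCN", "CC(C)O")
  d1 <- distributionMetrics(gen, ref)
  d2 <- distributionMetrics(rev(gen), rev(ref))
  expect_equal(d1, d2)
  ef1 <- enrichmentFactor(c(3, 2, 1), c(TRUE, FALSE, TRUE))
  ef2 <- enrichmentFactor(c(1, 3, 2), c(TRUE, TRUE, FALSE))
  expect_equal(ef1, ef2)
})
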