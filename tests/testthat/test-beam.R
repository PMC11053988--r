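test_that("beam width 1 equals stepwise greedy decoding", {
  m <- randomTinyModel(2)
  vocab <- m@vocabulary
  h <- beamSearch(m, "cls", "<att:2>",
                  beamConfig(beamWidth = 1L, nReturn = 1L))[[1]]
  ## manual greedy loop over the same model
  ids <- idOf(vocab, c("cls", "<att:2>", "<bos>"))
  banned <- chemotif:::.bannedIds(m, beamConfig())
  eosId <- match("<eos>", vocab@tokens)
  toks <- character(0)
  repeat {
    lp <- chemotif:::.nextLogProbs(m, list(ids))[1, ]
    lp[banned] <- -Inf
    nxt <- which.max(lp)
    ids <- c(ids, nxt)
    if (nxt == eosId || length(ids) >= m@config$maxLen) break
    toks <- c(toks, tokenOf(vocab, nxt))
  }
  expect_identical(h$tokens, toks)
})

test_that("beam search equals exhaustive-enumeration argmax on a tiny vocabulary", {
  m <- randomTinyModel(3)
  oracle <- enumerateArgmax(m, "cls", "<att:2>", maxTokens = 3L)
  K <- 4^3 + 4^2 + 4 + 1
  h <- beamSearch(m, "cls", "<att:2>",
                  beamConfig(beamWidth = K, nReturn = 1L))[[1]]
  expect_identical(h$tokens, oracle$tokens)
  expect_equal(h$logprob, oracle$score, tolerance = 1e-8)
})

test_that("beam scores are accumulated log-probabilities, never positive", {
  m <- randomTinyModel(4)
  hs <- beamSearch(m, "cls", "<att:2>",
                   beamConfig(beamWidth = 6L, nReturn = 6L))
  lp <- vapply(hs, `[[`, 0, "logprob")
  expect_true(all(lp <= 0))
  expect_true(all(diff(lp) <= 1e-12))      # sorted decreasing
  expect_true(all(vapply(hs, `[[`, TRUE, "finished")))
})

test_that("seed prefixes and banned tokens constrain every hypothesis", {
  m <- randomTinyModel(5)
  hs <- beamSearch(m, "cls", "<att:2>", beamConfig(beamWidth = 4L),
                   seedPrefix = "*O")
  for (h in hs) expect_identical(h$tokens[1], "*O")
  expect_error(beamSearch(m, "cls", "<att:2>", seedPrefix = "no_such"),
               "seed_token_unknown")
  hs2 <- beamSearch(m, "cls", "<att:2>",
                    beamConfig(beamWidth = 4L, bannedTokens = "*C"))
  for (h in hs2) expect_false("*C" %in% h$tokens)
  hs3 <- beamSearch(m, "cls", "<att:2>",
                    beamConfig(beamWidth = 4L, noRepeat = TRUE))
  for (h in hs3) expect_false(anyDuplicated(h$tokens) > 0)
})

test_that("sampling returns n flagged candidates and honours n = 0", {
  expect_equal(nrow(sampleMolecules(randomTinyModel(6), "cls", 0L)), 0L)
  toy <- toyCorpus()
  cfg <- generatorConfig(dModel = 32L, nHeads = 4L, nLayers = 2L,
                         dFF = 64L, dropout = 0, seed = 1L)
  m <- trainGenerator(toy$sentences[1:60], cfg, epochs = 8L,
                      batchSize = 30L, lr = 2e-3)
  sm <- sampleMolecules(m, "cls_a", 12L,
                        beam = beamConfig(beamWidth = 4L, nReturn = 4L),
                        seed = 3L)
  expect_equal(nrow(sm), 12L)
  expect_type(sm$valid, "logical")
  expect_true(all(is.na(sm$smiles[!sm$valid])))
})
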