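test_that("constraint labelling follows half-open bins in fixed order", {
  d <- data.frame(qed = c(0.7, 0.5, 0.49), logp = c(2, -0.1, 5),
                  sas = c(2.5, 3.99, 4.0))
  lab <- assignConstraintLabels(d)
  expect_identical(colnames(lab), c("qed", "logp", "sas"))
  expect_identical(unname(lab[1, ]), c("qed_good", "logp_good", "sas_good"))
  ## values exactly at the bin edge fall in the bin opening there
  expect_identical(unname(lab[2, ]), c("qed_good", "logp_bad", "sas_good"))
  expect_identical(unname(lab[3, ]), c("qed_bad", "logp_bad", "sas_bad"))
  expect_error(assignConstraintLabels(d[, 1:2]), "missing_descriptor")
})

test_that("activity labelling applies a strict score threshold", {
  expect_identical(activityLabels(c(50, 44.36, 10), 44.36),
                   c("active", "inactive", "inactive"))
})

test_that("vocabulary construction is deterministic and counts types", {
  sent <- list(c("qed_good", "<att:2>", "<bos>", "*C", "*C1CCCCC1", "*O",
                 "<eos>"))
  v <- buildVocabulary(sent)
  ## 3 motifs + 1 label + 1 info + 4 specials
  expect_equal(vocabSize(v), 3L + 1L + 1L + 4L)
  expect_identical(v@tokens[1:4], unname(v@specials))
  expect_identical(buildVocabulary(sent)@tokens, v@tokens)
  ## frequency-major, lexicographic tie-break ordering
  sent2 <- list(c("<bos>", "b", "a", "b", "<eos>"))
  v2 <- buildVocabulary(sent2)
  expect_identical(v2@tokens[5:6], c("b", "a"))
})

test_that("encode/decode is the identity on in-vocabulary sentences", {
  toy <- toyCorpus()
  v <- buildVocabulary(toy$sentences)
  enc <- encodeSentences(toy$sentences[1:20], v)
  dec <- decodeIds(enc, v)
  for (i in 1:20) expect_identical(dec[[i]], toy$sentences[[i]])
  ## unseen token maps to <unk>; <pad> is never decoded
  unkId <- match(v@specials[["unk"]], v@tokens)
  expect_equal(encodeSentences(list("never_seen_token"), v)[[1]], unkId)
  padId <- match(v@specials[["pad"]], v@tokens)
  expect_false(v@specials[["pad"]] %in% decodeIds(c(padId, 2L, 3L), v))
})

test_that("sentences carry labels, attachment info, and BOS/EOS framing", {
  seqs <- canonicalizeMotifs(fragmentMolecules(c("CC1CCCCC1"), "motif"))
  s <- buildSentences(seqs, matrix("qed_good", 1, 1))[[1]]
  expect_identical(s[1], "qed_good")
  expect_identical(s[2], "<att:2>")        # one cut = two markers
  expect_identical(s[3], "<bos>")
  expect_identical(s[length(s)], "<eos>")
  expect_equal(sum(s == "<bos>"), 1L)
  expect_equal(sum(s == "<eos>"), 1L)
  ## empty motif list still frames correctly
  expect_identical(motifInfoToken(character(0)), "<att:0>")
})

test_that("vocabulary files round-trip", {
  v <- buildVocabulary(list(c("<bos>", "*C", "<eos>")))
  p <- tempfile()
  writeVocabulary(v, p)
  v2 <- readVocabulary(p)
  expect_identical(v2@tokens, v@tokens)
})
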