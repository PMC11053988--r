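## shared lazy fixtures so expensive objects are built once per test run

.testCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.testCache[[key]])) .testCache[[key]] <- force(expr)
  .testCache[[key]]
}

## the packaged 1000-molecule fixture set under its default study conditions
fullFixtureSet <- function() cached("fx1000", generateFixtureSet(
  fixtureSpec(nMolecules = 1000L, stereoFraction = 0.3, seed = 42L)))

smallFixtureSet <- function(n = 60L) cached(paste0("fx", n),
  generateFixtureSet(fixtureSpec(nMolecules = as.integer(n),
                                 stereoFraction = 0.3, seed = 42L)))

toyCorpus <- function() cached("toy", generateConditionedToyCorpus(
  seed = 7L, nPerClass = 200L))

## 10 memorization sentences with pairwise distinct constraint/info
## prefixes (greedy decoding is a function of the prefix)
memorizationSentences <- function() cached("mem10", {
  toy <- toyCorpus()
  pref <- vapply(toy$sentences, function(s)
    paste(s[seq_len(match("<bos>", s) - 1L)], collapse = " "), "")
  toy$sentences[!duplicated(pref)][1:10]
})

memorizedModel <- function() cached("memModel", {
  cfg <- generatorConfig(dModel = 48L, nHeads = 4L, nLayers = 4L,
                         dFF = 96L, dropout = 0, seed = 1L)
  trainGenerator(memorizationSentences(), cfg, epochs = 300L,
                 batchSize = 10L, lr = 2e-3, warmup = 20L)
})

sentencePrefix <- function(s) {
  bos <- match("<bos>", s)
  list(labels = s[seq_len(bos - 2L)], info = s[bos - 1L],
       target = s[(bos + 1L):(length(s) - 1L)])
}

## tiny random generator instances over a 4-motif vocabulary, for
## search-correctness checks
randomTinyModel <- function(seed) {
  toks <- c("*C", "*CC", "*O", "*N")
  sent <- list(c("cls", "<att:2>", "<bos>", toks[1], toks[2], "<eos>"),
               c("cls", "<att:2>", "<bos>", toks[3], toks[4], "<eos>"))
  vocab <- buildVocabulary(sent)
  cfg <- generatorConfig(dModel = 16L, nHeads = 2L, nLayers = 1L,
                         dFF = 24L, maxLen = 7L, dropout = 0,
                         seed = as.integer(seed))
  trainGenerator(sent, cfg, vocab = vocab, epochs = 1L, batchSize = 2L,
                 lr = 1e-4)
}

## exhaustive enumeration of EOS-terminated sequences up to `maxTokens`
## content tokens, scored by accumulated model log-probability
enumerateArgmax <- function(model, constraint, info, maxTokens) {
  vocab <- model@vocabulary
  content <- setdiff(vocab@tokens,
                     c(vocab@specials, model@labelTokens, model@infoTokens))
  ctx <- idOf(vocab, c(constraint, info, vocab@specials[["bos"]]))
  eosId <- match(vocab@specials[["eos"]], vocab@tokens)
  contentIds <- match(content, vocab@tokens)
  scoreSeq <- function(ids) {
    full <- c(ctx, ids, eosId)
    tot <- 0
    for (k in seq_along(c(ids, eosId))) {
      pref <- full[seq_len(length(ctx) + k - 1L)]
      lp <- chemotif:::.nextLogProbs(model, list(pref))
      tot <- tot + lp[1, full[length(ctx) + k]]
    }
    tot
  }
  best <- list(score = -Inf, ids = NULL)
  grids <- lapply(0:maxTokens, function(L)
    if (L == 0L) list(integer(0))
    else asplit(as.matrix(expand.grid(rep(list(contentIds), L))), 1L))
  for (g in grids) for (ids in g) {
    sc <- scoreSeq(as.integer(ids))
    if (sc > best$score) best <- list(score = sc, ids = as.integer(ids))
  }
  list(score = best$score, tokens = tokenOf(vocab, best$ids))
}
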