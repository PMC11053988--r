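test_that("scaled dot-product attention matches hand-computed cases", {
  ## zero queries: uniform weights, output = mean of visible value rows
  V <- matrix(c(1, 0, 0, 1, 2, 2), 3, 2, byrow = TRUE)
  r <- scaledDotAttention(matrix(0, 3, 2), matrix(rnorm(6), 3, 2), V)
  expect_equal(r$weights, matrix(1 / 3, 3, 3))
  expect_equal(r$output[1, ], colMeans(V))

  ## a single visible position passes its value row through
  mask <- matrix(c(TRUE, FALSE, FALSE), 1, 3)
  r2 <- scaledDotAttention(matrix(1, 1, 2), matrix(rnorm(6), 3, 2), V, mask)
  expect_equal(r2$output[1, ], V[1, ])

  ## 2x2 hand case with d_k = 1: weights = softmax(q*k)
  Q <- matrix(c(1, 2), 2, 1)
  K <- matrix(c(0.5, -1), 2, 1)
  Vv <- matrix(c(3, 7), 2, 1)
  r3 <- scaledDotAttention(Q, K, Vv)
  w11 <- exp(0.5) / (exp(0.5) + exp(-1))
  expect_equal(r3$weights[1, 1], w11)
  expect_equal(r3$output[1, 1], w11 * 3 + (1 - w11) * 7)
  expect_equal(rowSums(r3$weights), c(1, 1))
})

test_that("analytic gradients match finite differences", {
  set.seed(3)
  cfg <- generatorConfig(dModel = 8L, nHeads = 2L, nLayers = 2L, dFF = 12L,
                         maxLen = 5L, dropout = 0, seed = 3L)
  params <- chemotif:::.initParams(cfg, 7L)
  ## scale up so gradient magnitudes dominate finite-difference noise
  params <- lapply(params, function(p) p * 5)
  ids <- matrix(c(2, 5, 6, 7, 3, 2, 6, 5, 3, 1), 2, 5, byrow = TRUE)
  tr <- c(1:4, 6:8)
  tid <- c(5, 6, 7, 3, 6, 5, 3)
  lg <- chemotif:::.tfLossGrad(params, cfg, ids, 1L, tr, tid)
  eps <- 1e-5
  for (nm in c("E", "Wout", "L1.Wq", "L1.Wv", "L1.W1", "L1.ln1g",
               "L2.Wk", "L2.Wo", "L2.ln2b")) {
    idx <- sample(length(params[[nm]]), 3L)
    for (k in idx) {
      p1 <- params; p1[[nm]][k] <- p1[[nm]][k] + eps
      p2 <- params; p2[[nm]][k] <- p2[[nm]][k] - eps
      num <- (chemotif:::.tfLossGrad(p1, cfg, ids, 1L, tr, tid)$loss -
              chemotif:::.tfLossGrad(p2, cfg, ids, 1L, tr, tid)$loss) /
        (2 * eps)
      expect_equal(lg$grad[[nm]][k], num, tolerance = 1e-4,
                   label = paste("grad", nm, k))
    }
  }
})

test_that("the causal mask blocks information from future positions", {
  toy <- toyCorpus()
  sent <- toy$sentences[1:8]
  cfg <- generatorConfig(dModel = 16L, nHeads = 2L, nLayers = 2L,
                         dFF = 24L, dropout = 0, seed = 2L)
  m <- trainGenerator(sent, cfg, epochs = 1L, batchSize = 8L)
  vocab <- m@vocabulary
  enc <- encodeSentences(sent, vocab)[[1]]
  fw1 <- chemotif:::.tfForward(m@params, m@config,
                               matrix(enc, 1L), 1L)
  enc2 <- enc
  enc2[length(enc2)] <- 5L          # perturb the last token
  fw2 <- chemotif:::.tfForward(m@params, m@config,
                               matrix(enc2, 1L), 1L)
  upto <- length(enc) - 1L
  expect_equal(fw1$logits[seq_len(upto), ], fw2$logits[seq_len(upto), ])
  expect_false(isTRUE(all.equal(fw1$logits[length(enc), ],
                                fw2$logits[length(enc), ])))
})

test_that("an untrained model is near-uniform and training is deterministic", {
  toy <- toyCorpus()
  sent <- toy$sentences[1:16]
  cfg <- generatorConfig(dModel = 16L, nHeads = 2L, nLayers = 1L,
                         dFF = 24L, dropout = 0, seed = 5L)
  m0 <- trainGenerator(sent, cfg, epochs = 1L, batchSize = 16L, lr = 0)
  V <- vocabSize(m0)
  expect_equal(sentenceNLL(m0, sent), log(V), tolerance = 0.05)
  ## identical seed + corpus -> identical loss curve
  m1 <- trainGenerator(sent, cfg, epochs = 3L, batchSize = 8L)
  m2 <- trainGenerator(sent, cfg, epochs = 3L, batchSize = 8L)
  expect_identical(trainingLog(m1)$nll, trainingLog(m2)$nll)
})

test_that("emitted next-token distributions are normalized", {
  m <- randomTinyModel(1)
  lp <- chemotif:::.nextLogProbs(m, list(c(5L, 6L, 2L)))
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-10)
})
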