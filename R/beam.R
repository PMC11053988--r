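## Beam-search decoding of motif sequences, y* = argmax p(y | x, c).
##
## The search keeps the K locally highest-probability candidates at each
## time step, scoring pure accumulated log-probability (no length
## normalization), until every kept hypothesis ends in <eos> or the
## model's maximum time step T is reached.  The expanded-node count is
## bounded by T * K * |V|.

#' Beam-search configuration
#'
#' @param beamWidth K, hypotheses kept per step.
#' @param nReturn N, hypotheses returned (`1 <= N <= K`).
#' @param bannedTokens tokens never proposed (on top of the always-banned
#'   specials/constraint/info tokens).
#' @param noRepeat forbid a motif token from occurring twice in one
#'   hypothesis.
#' @return config list.
#' @export
beamConfig <- function(beamWidth = 8L, nReturn = beamWidth,
                       bannedTokens = character(), noRepeat = FALSE) {
  stopifnot(nReturn >= 1L, nReturn <= beamWidth)
  list(beamWidth = as.integer(beamWidth), nReturn = as.integer(nReturn),
       bannedTokens = bannedTokens, noRepeat = noRepeat)
}

.contextIds <- function(model, constraint, motifInfo, seedPrefix) {
  vocab <- model@vocabulary
  unkId <- match(vocab@specials[["unk"]], vocab@tokens)
  ctx <- c(constraint, motifInfo, vocab@specials[["bos"]], seedPrefix)
  ids <- idOf(vocab, ctx)
  if (length(seedPrefix) && any(ids[match(seedPrefix, ctx)] == unkId))
    stop("seed_token_unknown")
  ids
}

.bannedIds <- function(model, beam) {
  vocab <- model@vocabulary
  banned <- c(unname(vocab@specials[c("pad", "bos", "unk")]),
              model@labelTokens, model@infoTokens, beam$bannedTokens)
  unique(match(banned, vocab@tokens, nomatch = 0L))
}

#' Sample motif sequences by beam search
#'
#' Decodes from the conditioning context `[constraint tokens, motif-info
#' token, <bos>, seed motifs...]`.  With `beamWidth = 1` this is greedy
#' decoding.  Ties are broken deterministically by token id.  With
#' `temperature > 0` the K continuations kept at each step are sampled from
#' the top candidates instead of taken greedily (used by
#' [sampleMolecules()] to diversify draws); `temperature = 0` is exact
#' beam search.
#'
#' @param model a [MotifGenerator-class].
#' @param constraint character vector of constraint tokens.
#' @param motifInfo motif-info token (e.g. `"<att:4>"`); defaults to the
#'   most frequent one seen in training.
#' @param beam a [beamConfig()].
#' @param seedPrefix optional motif tokens forced at the start of every
#'   hypothesis (a scaffold or privileged motif seed).
#' @param temperature softmax temperature for stochastic continuation
#'   choice (0 = deterministic).
#' @return list of hypotheses, each `list(tokens, logprob, finished)`,
#'   sorted by decreasing accumulated log-probability; at most `nReturn`.
#'   Unterminated hypotheses are returned (flagged) only when nothing
#'   terminated.
#' @export
beamSearch <- function(model, constraint, motifInfo = NULL,
                       beam = beamConfig(), seedPrefix = character(),
                       temperature = 0) {
  vocab <- model@vocabulary
  if (is.null(motifInfo)) motifInfo <- .defaultInfoToken(model)
  eosId <- match(vocab@specials[["eos"]], vocab@tokens)
  ctx <- .contextIds(model, constraint, motifInfo, seedPrefix)
  nCtx <- length(ctx)
  banned <- .bannedIds(model, beam)
  K <- beam$beamWidth
  Tmax <- model@config$maxLen
  hyps <- list(list(ids = ctx, score = 0, done = FALSE))
  repeat {
    live <- which(!vapply(hyps, `[[`, TRUE, "done"))
    if (!length(live)) break
    if (max(lengths(lapply(hyps[live], `[[`, "ids"))) >= Tmax) break
    lp <- .nextLogProbs(model, lapply(hyps[live], `[[`, "ids"))
    cand <- list()
    for (j in seq_along(live)) {
      h <- hyps[[live[j]]]
      row <- lp[j, ]
      row[banned] <- -Inf
      if (beam$noRepeat) row[h$ids[-seq_len(nCtx)]] <- -Inf
      keep <- order(row, decreasing = TRUE)[seq_len(min(K, sum(is.finite(row))))]
      for (tok in keep)
        cand[[length(cand) + 1L]] <- list(
          ids = c(h$ids, tok), score = h$score + row[tok],
          done = tok == eosId)
    }
    for (i in which(vapply(hyps, `[[`, TRUE, "done")))
      cand[[length(cand) + 1L]] <- hyps[[i]]
    if (!length(cand)) break
    sc <- vapply(cand, `[[`, 0, "score")
    lastTok <- vapply(cand, function(h) h$ids[length(h$ids)], 0L)
    if (temperature > 0) {
      nk <- min(K, length(cand))
      w <- pmax(exp((sc - max(sc)) / temperature), 1e-300)
      pick <- integer(0)
      avail <- seq_along(cand)
      for (s in seq_len(nk)) {
        i <- avail[sample.int(length(avail), 1L, prob = w[avail])]
        pick <- c(pick, i)
        avail <- setdiff(avail, i)
      }
      hyps <- cand[pick]
    } else {
      ord <- order(-sc, lastTok)
      hyps <- cand[ord[seq_len(min(K, length(cand)))]]
    }
  }
  finished <- Filter(function(h) h$done, hyps)
  flaggedUnfinished <- length(finished) == 0L
  if (flaggedUnfinished) finished <- hyps
  sc <- vapply(finished, `[[`, 0, "score")
  finished <- finished[order(-sc)]
  finished <- finished[seq_len(min(beam$nReturn, length(finished)))]
  lapply(finished, function(h) {
    toks <- tokenOf(vocab, h$ids[-seq_len(nCtx - length(seedPrefix))])
    toks <- toks[toks != vocab@specials[["eos"]]]
    list(tokens = toks, logprob = h$score,
         finished = h$done && !flaggedUnfinished)
  })
}

.defaultInfoToken <- function(model) {
  if (length(model@infoTokens)) model@infoTokens[[1]] else "<att:2>"
}

#' Sample molecules from a trained generator
#'
#' Runs repeated beam searches under the given constraint, cycling through
#' the motif-info tokens observed in training and drawing stochastic
#' continuations at the given temperature, until `n` candidate sequences
#' are collected; every sequence is passed through the reconstruction
#' decoder and invalid ones are flagged (they feed the validity metric,
#' they are not dropped).
#'
#' @param model a [MotifGenerator-class].
#' @param constraint character vector of constraint tokens.
#' @param n number of candidate sequences.
#' @param beam a [beamConfig()].
#' @param seedPrefix optional motif tokens fixed at the start.
#' @param temperature sampling temperature among top-K continuations.
#' @param seed RNG seed for the stochastic draws.
#' @param motifInfo optional fixed motif-info token; by default the info
#'   tokens observed in training are cycled to diversify draws.
#' @return data.frame with columns `smiles`, `valid`, `reason`, `tokens`
#'   (space-separated motif tokens), `logprob`.
#' @export
sampleMolecules <- function(model, constraint, n, beam = beamConfig(),
                            seedPrefix = character(), temperature = 0.8,
                            seed = 1L, motifInfo = NULL) {
  if (n == 0L)
    return(data.frame(smiles = character(), valid = logical(),
                      reason = character(), tokens = character(),
                      logprob = numeric(), stringsAsFactors = FALSE))
  set.seed(seed)
  infos <- if (!is.null(motifInfo)) motifInfo
           else if (length(model@infoTokens)) model@infoTokens
           else "<att:2>"
  hyps <- list()
  round <- 0L
  while (length(hyps) < n && round < 10L * ceiling(n / beam$nReturn) + 10L) {
    info <- infos[[(round %% length(infos)) + 1L]]
    hs <- beamSearch(model, constraint, info, beam, seedPrefix,
                     temperature = if (round == 0L) 0 else temperature)
    for (h in hs) if (length(hyps) < n) hyps[[length(hyps) + 1L]] <- h
    round <- round + 1L
  }
  tokenLists <- lapply(hyps, `[[`, "tokens")
  rec <- reconstructMolecules(tokenLists)
  data.frame(smiles = rec$smiles, valid = rec$valid, reason = rec$reason,
             tokens = vapply(tokenLists, paste, "", collapse = " "),
             logprob = vapply(hyps, `[[`, 0, "logprob"),
             stringsAsFactors = FALSE)
}
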