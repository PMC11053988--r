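## Conditional decoder-only transformer over motif sentences, implemented
## directly on matrices: token embedding + sinusoidal positional encoding,
## post-norm decoder blocks (masked multi-head self-attention, ReLU
## feed-forward, residual connections, layer normalization), and a linear
## + softmax output head.  Training minimizes the next-token negative
## log-likelihood over the motif positions, with the constraint and
## motif-info positions acting as conditioning context only.
##
## A batch of B sequences of length T is laid out as an (B*T) x d matrix
## (row (b-1)*T + t is position t of sequence b); attention then works on
## one (B*T) x (B*T) score matrix with a block-diagonal causal mask, which
## keeps everything inside BLAS calls.

.LN_EPS <- 1e-5

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, with an optional visibility mask.  Each
#' output row is a convex combination of the visible `V` rows; fully masked
#' rows are undefined and must not be consumed (the package's decoder
#' always leaves the diagonal visible).
#'
#' @param Q,K,V numeric matrices; `Q` is n_q x d_k, `K` n_k x d_k, `V`
#'   n_k x d_v.
#' @param mask optional logical n_q x n_k matrix, `TRUE` where key j is
#'   visible to query i.
#' @return list with `output` (n_q x d_v) and `weights` (n_q x n_k).
#' @export
scaledDotAttention <- function(Q, K, V, mask = NULL) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  S <- Q %*% t(K) / sqrt(ncol(Q))
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), c(nrow(Q), nrow(K))))
    S[!mask] <- -Inf
  }
  S <- S - apply(S, 1L, max)
  P <- exp(S)
  P <- P / rowSums(P)
  list(output = P %*% V, weights = P)
}

#' Generator model configuration
#'
#' @param dModel embedding width (must be a multiple of `nHeads`).
#' @param nHeads attention heads; the per-head width `d_k = dModel/nHeads`
#'   is the attention scaling factor.
#' @param nLayers decoder blocks.
#' @param dFF feed-forward hidden width.
#' @param maxLen maximum sentence length T (set automatically from the
#'   corpus by [trainGenerator()] when `NA`).
#' @param dropout dropout fraction on sublayer outputs during training.
#' @param seed integer seed controlling initialization and batching.
#' @return a config list.
#' @export
generatorConfig <- function(dModel = 256L, nHeads = 8L, nLayers = 4L,
                            dFF = 1024L, maxLen = NA_integer_,
                            dropout = 0.1, seed = 1L) {
  stopifnot(dModel %% nHeads == 0L)
  list(dModel = as.integer(dModel), nHeads = as.integer(nHeads),
       nLayers = as.integer(nLayers), dFF = as.integer(dFF),
       maxLen = as.integer(maxLen), dropout = dropout,
       seed = as.integer(seed))
}

.sinusoidalPE <- function(T, d) {
  pos <- seq_len(T) - 1L
  i <- seq_len(d) - 1L
  angle <- outer(pos, 10000^(-(i %/% 2L) * 2 / d))
  pe <- matrix(0, T, d)
  even <- (i %% 2L) == 0L
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}

.initParams <- function(cfg, V) {
  d <- cfg$dModel; dff <- cfg$dFF
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  p <- list(E = rn(V, d), Wout = rn(d, V), bout = numeric(V))
  for (l in seq_len(cfg$nLayers)) {
    pre <- paste0("L", l, ".")
    p[[paste0(pre, "Wq")]] <- rn(d, d); p[[paste0(pre, "bq")]] <- numeric(d)
    p[[paste0(pre, "Wk")]] <- rn(d, d); p[[paste0(pre, "bk")]] <- numeric(d)
    p[[paste0(pre, "Wv")]] <- rn(d, d); p[[paste0(pre, "bv")]] <- numeric(d)
    p[[paste0(pre, "Wo")]] <- rn(d, d); p[[paste0(pre, "bo")]] <- numeric(d)
    p[[paste0(pre, "W1")]] <- rn(d, dff); p[[paste0(pre, "b1")]] <- numeric(dff)
    p[[paste0(pre, "W2")]] <- rn(dff, d); p[[paste0(pre, "b2")]] <- numeric(d)
    p[[paste0(pre, "ln1g")]] <- rep(1, d); p[[paste0(pre, "ln1b")]] <- numeric(d)
    p[[paste0(pre, "ln2g")]] <- rep(1, d); p[[paste0(pre, "ln2b")]] <- numeric(d)
  }
  p
}

.lnForward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + .LN_EPS)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

.lnBackward <- function(dy, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, g, "*")
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

.addBias <- function(x, b) x + rep(b, each = nrow(x))

## forward pass; ids: B x T integer matrix (1-based, padId for padding)
## returns logits and (optionally) caches for backprop
.tfForward <- function(params, cfg, ids, padId, cache = FALSE,
                       dropMask = NULL) {
  B <- nrow(ids); T <- ncol(ids); d <- cfg$dModel
  H <- cfg$nHeads; dk <- d %/% H
  N <- B * T
  idsVec <- as.integer(t(ids))
  X0 <- params$E[idsVec, , drop = FALSE] +
    .sinusoidalPE(T, d)[rep(seq_len(T), B), , drop = FALSE]
  seqid <- rep(seq_len(B), each = T)
  pos <- rep(seq_len(T), B)
  notPad <- idsVec != padId
  allowed <- outer(seqid, seqid, "==") & outer(pos, pos, ">=")
  allowed[, !notPad] <- FALSE
  diag(allowed) <- TRUE
  M <- matrix(0, N, N)
  M[!allowed] <- -Inf
  caches <- if (cache) vector("list", cfg$nLayers)
  X <- X0
  for (l in seq_len(cfg$nLayers)) {
    pre <- paste0("L", l, ".")
    Q <- .addBias(X %*% params[[paste0(pre, "Wq")]], params[[paste0(pre, "bq")]])
    K <- .addBias(X %*% params[[paste0(pre, "Wk")]], params[[paste0(pre, "bk")]])
    Vm <- .addBias(X %*% params[[paste0(pre, "Wv")]], params[[paste0(pre, "bv")]])
    A <- matrix(0, N, d)
    Ps <- if (cache) vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk) + M
      S <- S - apply(S, 1L, max)
      P <- exp(S)
      P <- P / rowSums(P)
      if (cache) Ps[[h]] <- P
      A[, cols] <- P %*% Vm[, cols, drop = FALSE]
    }
    Aout <- .addBias(A %*% params[[paste0(pre, "Wo")]], params[[paste0(pre, "bo")]])
    dm1 <- NULL
    if (!is.null(dropMask)) {
      dm1 <- dropMask[[l]]$attn
      Aout <- Aout * dm1
    }
    res1 <- X + Aout
    ln1 <- .lnForward(res1, params[[paste0(pre, "ln1g")]],
                      params[[paste0(pre, "ln1b")]])
    X1 <- ln1$y
    Hff <- .addBias(X1 %*% params[[paste0(pre, "W1")]], params[[paste0(pre, "b1")]])
    Hrelu <- pmax(Hff, 0)
    Fout <- .addBias(Hrelu %*% params[[paste0(pre, "W2")]], params[[paste0(pre, "b2")]])
    dm2 <- NULL
    if (!is.null(dropMask)) {
      dm2 <- dropMask[[l]]$ffn
      Fout <- Fout * dm2
    }
    res2 <- X1 + Fout
    ln2 <- .lnForward(res2, params[[paste0(pre, "ln2g")]],
                      params[[paste0(pre, "ln2b")]])
    if (cache)
      caches[[l]] <- list(X = X, Q = Q, K = K, V = Vm, Ps = Ps, A = A,
                          ln1 = ln1, X1 = X1, Hrelu = Hrelu, ln2 = ln2,
                          dm1 = dm1, dm2 = dm2)
    X <- ln2$y
  }
  logits <- .addBias(X %*% params$Wout, params$bout)
  list(logits = logits, Xfinal = X, caches = caches, idsVec = idsVec)
}

## mean NLL over target positions + full gradient
.tfLossGrad <- function(params, cfg, ids, padId, targetRows, targetIds,
                        dropMask = NULL) {
  fw <- .tfForward(params, cfg, ids, padId, cache = TRUE,
                   dropMask = dropMask)
  logits <- fw$logits[targetRows, , drop = FALSE]
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  picked <- logits[cbind(seq_along(targetIds), targetIds)]
  loss <- mean(lse - picked)

  nT <- length(targetIds)
  dsel <- exp(logits - lse)
  dsel[cbind(seq_along(targetIds), targetIds)] <-
    dsel[cbind(seq_along(targetIds), targetIds)] - 1
  dsel <- dsel / nT
  N <- nrow(fw$Xfinal)
  dlogits <- matrix(0, N, ncol(dsel))
  dlogits[targetRows, ] <- dsel

  g <- list()
  g$Wout <- t(fw$Xfinal) %*% dlogits
  g$bout <- colSums(dlogits)
  dX <- dlogits %*% t(params$Wout)
  H <- cfg$nHeads; d <- cfg$dModel; dk <- d %/% H
  for (l in rev(seq_len(cfg$nLayers))) {
    pre <- paste0("L", l, ".")
    cc <- fw$caches[[l]]
    bk2 <- .lnBackward(dX, cc$ln2, params[[paste0(pre, "ln2g")]])
    g[[paste0(pre, "ln2g")]] <- bk2$dg
    g[[paste0(pre, "ln2b")]] <- bk2$db
    dres2 <- bk2$dx
    dFout <- dres2
    if (!is.null(cc$dm2)) dFout <- dFout * cc$dm2
    g[[paste0(pre, "W2")]] <- t(cc$Hrelu) %*% dFout
    g[[paste0(pre, "b2")]] <- colSums(dFout)
    dHrelu <- dFout %*% t(params[[paste0(pre, "W2")]])
    dHff <- dHrelu * (cc$Hrelu > 0)
    g[[paste0(pre, "W1")]] <- t(cc$X1) %*% dHff
    g[[paste0(pre, "b1")]] <- colSums(dHff)
    dX1 <- dres2 + dHff %*% t(params[[paste0(pre, "W1")]])
    bk1 <- .lnBackward(dX1, cc$ln1, params[[paste0(pre, "ln1g")]])
    g[[paste0(pre, "ln1g")]] <- bk1$dg
    g[[paste0(pre, "ln1b")]] <- bk1$db
    dres1 <- bk1$dx
    dAout <- dres1
    if (!is.null(cc$dm1)) dAout <- dAout * cc$dm1
    g[[paste0(pre, "Wo")]] <- t(cc$A) %*% dAout
    g[[paste0(pre, "bo")]] <- colSums(dAout)
    dA <- dAout %*% t(params[[paste0(pre, "Wo")]])
    dQ <- matrix(0, N, d); dK <- matrix(0, N, d); dV <- matrix(0, N, d)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      P <- cc$Ps[[h]]
      dHh <- dA[, cols, drop = FALSE]
      dP <- dHh %*% t(cc$V[, cols, drop = FALSE])
      dV[, cols] <- t(P) %*% dHh
      dS <- P * (dP - rowSums(dP * P))
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE] / sqrt(dk)
      dK[, cols] <- t(dS) %*% cc$Q[, cols, drop = FALSE] / sqrt(dk)
    }
    g[[paste0(pre, "Wq")]] <- t(cc$X) %*% dQ
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "Wk")]] <- t(cc$X) %*% dK
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "Wv")]] <- t(cc$X) %*% dV
    g[[paste0(pre, "bv")]] <- colSums(dV)
    dX <- dres1 + dQ %*% t(params[[paste0(pre, "Wq")]]) +
      dK %*% t(params[[paste0(pre, "Wk")]]) +
      dV %*% t(params[[paste0(pre, "Wv")]])
  }
  gE <- matrix(0, nrow(params$E), d)
  agg <- rowsum(dX, fw$idsVec)
  gE[as.integer(rownames(agg)), ] <- agg
  g$E <- gE
  list(loss = loss, grad = g)
}

.adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adamStep <- function(params, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grad)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grad[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, st = st)
}

.isInfoToken <- function(x) grepl("^<att:", x)

#' Train the conditional motif generator
#'
#' Minimizes the next-token negative log-likelihood
#' `L(x) = -sum_i log p(x_i | x_0..x_{i-1}, c)` over the motif positions of
#' each sentence; the constraint tokens `c` and the motif-info token are
#' conditioning context and carry no loss.  Training is deterministic for a
#' fixed `config$seed`.
#'
#' @param sentences list of character-vector sentences from
#'   [buildSentences()].
#' @param config model configuration, see [generatorConfig()].
#' @param vocab optional [MotifVocabulary-class]; built from the corpus
#'   when `NULL`.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param warmup linear learning-rate warm-up steps.
#' @param batchSize minibatch size.
#' @param verbose print the per-epoch loss.
#' @param mode,fuseSplit fragmentation provenance stored on the model (used
#'   when reconstructing samples).
#' @return a [MotifGenerator-class].
#' @export
trainGenerator <- function(sentences, config = generatorConfig(),
                           vocab = NULL, epochs = 50L, lr = 1e-3,
                           warmup = 20L, batchSize = 32L, verbose = FALSE,
                           mode = "motif", fuseSplit = FALSE) {
  if (!length(sentences)) stop("empty_corpus")
  if (is.null(vocab)) vocab <- buildVocabulary(sentences)
  lens <- lengths(sentences)
  if (is.na(config$maxLen)) config$maxLen <- max(lens)
  if (max(lens) > config$maxLen)
    stop("sentence_exceeds_T: longest sentence ", max(lens),
         " > maxLen ", config$maxLen)
  Tlen <- config$maxLen
  padId <- match(vocab@specials[["pad"]], vocab@tokens)
  bosTok <- vocab@specials[["bos"]]
  enc <- encodeSentences(sentences, vocab)
  B0 <- length(enc)
  ids <- matrix(padId, B0, Tlen)
  for (i in seq_len(B0)) ids[i, seq_len(lens[i])] <- enc[[i]]
  bosPos <- vapply(sentences, function(s) match(bosTok, s), 0L)
  if (anyNA(bosPos)) stop("every sentence needs a <bos> token")

  labelTokens <- unique(unlist(lapply(sentences, function(s) {
    pre <- s[seq_len(match(bosTok, s) - 1L)]
    pre[!.isInfoToken(pre)]
  })))
  infoTokens <- sort(unique(unlist(lapply(sentences, function(s)
    s[.isInfoToken(s)]))))

  set.seed(config$seed)
  params <- .initParams(config, length(vocab@tokens))
  st <- .adamInit(params)
  log <- data.frame(epoch = integer(), nll = numeric())
  step <- 0L
  for (ep in seq_len(epochs)) {
    ordIdx <- sample.int(B0)
    totLoss <- 0
    totN <- 0L
    for (start in seq(1L, B0, by = batchSize)) {
      sel <- ordIdx[start:min(start + batchSize - 1L, B0)]
      bids <- ids[sel, , drop = FALSE]
      B <- length(sel)
      tr <- integer(0); tid <- integer(0)
      for (bi in seq_len(B)) {
        i <- sel[bi]
        ts <- bosPos[i]:(lens[i] - 1L)          # predict positions ts+1
        tr <- c(tr, (bi - 1L) * Tlen + ts)
        tid <- c(tid, ids[i, ts + 1L])
      }
      dropMask <- NULL
      if (config$dropout > 0) {
        d <- config$dModel
        keep <- 1 - config$dropout
        dropMask <- lapply(seq_len(config$nLayers), function(l)
          list(attn = matrix(stats::rbinom(B * Tlen * d, 1L, keep),
                             B * Tlen, d) / keep,
               ffn = matrix(stats::rbinom(B * Tlen * d, 1L, keep),
                            B * Tlen, d) / keep))
      }
      lg <- .tfLossGrad(params, config, bids, padId, tr, tid, dropMask)
      step <- step + 1L
      lrNow <- lr * min(1, step / max(1L, warmup))
      upd <- .adamStep(params, lg$grad, st, lrNow)
      params <- upd$params
      st <- upd$st
      totLoss <- totLoss + lg$loss * length(tid)
      totN <- totN + length(tid)
    }
    log <- rbind(log, data.frame(epoch = ep, nll = totLoss / totN))
    if (verbose) message(sprintf("epoch %d  nll %.4f", ep, totLoss / totN))
  }
  new("MotifGenerator", config = config, vocabulary = vocab,
      params = params, trainingLog = log, labelTokens = labelTokens,
      infoTokens = infoTokens, mode = mode, fuseSplit = fuseSplit)
}

#' Mean NLL of sentences under a trained model
#'
#' @param model a [MotifGenerator-class].
#' @param sentences list of character-vector sentences.
#' @return mean negative log-likelihood in nats/token over motif positions.
#' @export
sentenceNLL <- function(model, sentences) {
  vocab <- model@vocabulary
  cfg <- model@config
  padId <- match(vocab@specials[["pad"]], vocab@tokens)
  bosTok <- vocab@specials[["bos"]]
  lens <- lengths(sentences)
  Tlen <- cfg$maxLen
  enc <- encodeSentences(sentences, vocab)
  ids <- matrix(padId, length(enc), Tlen)
  for (i in seq_along(enc)) ids[i, seq_len(lens[i])] <- enc[[i]]
  tr <- integer(0); tid <- integer(0)
  for (i in seq_along(enc)) {
    bp <- match(bosTok, sentences[[i]])
    ts <- bp:(lens[i] - 1L)
    tr <- c(tr, (i - 1L) * Tlen + ts)
    tid <- c(tid, ids[i, ts + 1L])
  }
  fw <- .tfForward(model@params, cfg, ids, padId)
  logits <- fw$logits[tr, , drop = FALSE]
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  mean(lse - logits[cbind(seq_along(tid), tid)])
}

## next-token log-probabilities for a set of equal-length prefixes
.nextLogProbs <- function(model, prefixes) {
  cfg <- model@config
  vocab <- model@vocabulary
  padId <- match(vocab@specials[["pad"]], vocab@tokens)
  L <- length(prefixes[[1]])
  ids <- do.call(rbind, prefixes)
  fw <- .tfForward(model@params, cfg, ids, padId)
  rows <- (seq_len(nrow(ids)) - 1L) * L + L
  logits <- fw$logits[rows, , drop = FALSE]
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  logits - lse
}
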