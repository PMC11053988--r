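## Canonical motif sequences and exact reconstruction.
##
## A fragmentation is an unordered set of fragments whose dummy atoms carry
## explicit bond labels.  Canonicalization turns it into an ordered token
## sequence from which the labels can be dropped entirely:
##
##   * the fragment-adjacency graph is a tree (only acyclic bonds are cut;
##     fused-edge separations also nest tree-wise);
##   * the root is the fragment holding the lowest-canonical-rank parent
##     atom; every other fragment's token is written ROOTED at its
##     parent-facing dummy, so its first atom is the marker that attaches
##     it to what came before;
##   * children are visited depth-first in the order their slots appear in
##     the parent token's atom order.
##
## Reconstruction is then a stack automaton: read tokens left to right,
## maintain open slots (LIFO); each new token binds its first marker to the
## most recently opened slot and pushes its remaining slots.  Two mutually
## bonded markers in one token form a single fused-edge slot that merges
## with a partner pair by atom identification instead of bond formation.

.fragLabels <- function(smiles) {
  m <- gregexpr("\\[([0-9]+)\\*\\]", smiles)[[1]]
  if (m[1] == -1) return(integer())
  as.integer(gsub("\\D", "", regmatches(smiles, gregexpr("\\[([0-9]+)\\*\\]", smiles))[[1]]))
}

## adjacency of the fragment tree; errors: unpaired_marker, cyclic_fragmentation
.fragmentTree <- function(fr) {
  labs <- lapply(fr@fragments, function(f) .fragLabels(f$smiles))
  nfrag <- length(fr@fragments)
  edges <- list()
  fragsWith <- function(l) which(vapply(labs, function(x) l %in% x, TRUE))
  for (l in fr@cuts$label) {
    w <- fragsWith(l)
    if (length(w) != 2L) stop("unpaired_marker: label ", l)
    edges[[length(edges) + 1L]] <- list(a = w[1], b = w[2], kind = "bond",
                                        labels = l)
  }
  if (nrow(fr@fuses)) for (k in seq_len(nrow(fr@fuses))) {
    lu <- fr@fuses$labelU[k]; lv <- fr@fuses$labelV[k]
    wu <- fragsWith(lu); wv <- fragsWith(lv)
    if (length(wu) != 2L || !identical(wu, wv))
      stop("unpaired_marker: fused edge ", lu, "/", lv)
    edges[[length(edges) + 1L]] <- list(a = wu[1], b = wu[2], kind = "fuse",
                                        labels = c(lu, lv))
  }
  if (length(edges) != nfrag - 1L)
    stop("cyclic_fragmentation: ", length(edges), " edges for ", nfrag,
         " fragments")
  ## connectivity + parent assignment by BFS from the root fragment
  minRank <- vapply(fr@fragments, function(f) {
    oa <- f$origAtoms[f$origAtoms >= 0L]
    if (!length(oa)) return(.Machine$integer.max)
    min(fr@parentRanks[oa + 1L])
  }, 0L)
  root <- which.min(minRank)
  parent <- rep(NA_integer_, nfrag)
  entryEdge <- rep(NA_integer_, nfrag)
  seen <- rep(FALSE, nfrag)
  seen[root] <- TRUE
  queue <- root
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (ei in seq_along(edges)) {
      e <- edges[[ei]]
      other <- if (e$a == cur) e$b else if (e$b == cur) e$a else next
      if (seen[other]) next
      seen[other] <- TRUE
      parent[other] <- cur
      entryEdge[other] <- ei
      queue <- c(queue, other)
    }
  }
  if (!all(seen)) stop("unpaired_marker: disconnected fragmentation")
  list(edges = edges, root = root, parent = parent, entryEdge = entryEdge)
}

## group a token's dummies (label list in atom order + adjacency pairs)
## into ordered slots
.buildSlots <- function(labels, fusePairs) {
  n <- length(labels)
  partner <- rep(NA_integer_, n)
  for (p in fusePairs) {
    i <- p[[1]] + 1L; j <- p[[2]] + 1L
    partner[i] <- j; partner[j] <- i
  }
  slots <- list()
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (used[i]) next
    if (is.na(partner[i])) {
      slots[[length(slots) + 1L]] <- list(kind = "bond", pos = i - 1L,
                                          labels = labels[i])
      used[i] <- TRUE
    } else {
      j <- partner[i]
      slots[[length(slots) + 1L]] <- list(kind = "fuse",
                                          pos = c(i - 1L, j - 1L),
                                          labels = c(labels[i], labels[j]))
      used[c(i, j)] <- TRUE
    }
  }
  slots
}

## Vectorised canonicalization core: one or more FragmentationResults in,
## MotifSequence (or condition message) out, with batched token requests.
.canonicalizeBatch <- function(frs) {
  n <- length(frs)
  trees <- vector("list", n)
  state <- vector("list", n)    # per fr: tokens/slots per fragment
  err <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.null(frs[[i]])) { err[i] <- "missing_fragmentation"; next }
    trees[[i]] <- tryCatch(.fragmentTree(frs[[i]]), error = function(e)
      conditionMessage(e))
    if (is.character(trees[[i]])) { err[i] <- trees[[i]]; next }
    state[[i]] <- vector("list", length(frs[[i]]@fragments))
  }
  ## request rounds: a fragment's token can be computed once its root label
  ## is known (root: no label; bond child: its entry label; fuse child: the
  ## first-in-token-order label of the parent's slot -> needs parent token)
  repeat {
    reqIdx <- list(); reqItems <- list()
    for (i in seq_len(n)) {
      if (!is.na(err[i])) next
      tr <- trees[[i]]
      for (f in seq_along(state[[i]])) {
        if (!is.null(state[[i]][[f]])) next
        rootLab <- NULL
        if (f == tr$root) {
          rootLab <- NA
        } else {
          e <- tr$edges[[tr$entryEdge[f]]]
          if (e$kind == "bond") {
            rootLab <- e$labels
          } else {
            pstate <- state[[i]][[tr$parent[f]]]
            if (is.null(pstate)) next       # wait for parent token
            for (s in pstate$slots)
              if (s$kind == "fuse" && all(sort(s$labels) == sort(e$labels)))
                rootLab <- s$labels[1]      # parent's first-in-order label
            if (is.null(rootLab)) { err[i] <- "unpaired_marker"; break }
          }
        }
        if (is.null(rootLab)) next
        reqIdx[[length(reqIdx) + 1L]] <- c(i, f)
        it <- list(smiles = frs[[i]]@fragments[[f]]$smiles)
        if (!identical(rootLab, NA)) it$root_label <- rootLab
        reqItems[[length(reqItems) + 1L]] <- it
      }
    }
    if (!length(reqItems)) break
    res <- bkMotifToken(reqItems)
    for (k in seq_along(res)) {
      i <- reqIdx[[k]][1]; f <- reqIdx[[k]][2]
      r <- res[[k]]
      if (!isTRUE(r$ok)) { err[i] <- paste0("token_failure:", r$reason); next }
      labels <- vapply(r$slots, as.integer, 0L)
      pairs <- lapply(r$fuse_adjacent, function(p) c(p[[1]], p[[2]]))
      state[[i]][[f]] <- list(token = r$token,
                              slots = .buildSlots(labels, pairs))
    }
  }
  ## depth-first emission
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(err[i])) { out[[i]] <- err[i]; next }
    tr <- trees[[i]]; st <- state[[i]]; fr <- frs[[i]]
    childAt <- function(f, lab) {
      for (ei in seq_along(tr$edges)) {
        e <- tr$edges[[ei]]
        if (lab %in% e$labels && (e$a == f || e$b == f)) {
          other <- if (e$a == f) e$b else e$a
          if (identical(tr$parent[other], f)) return(other)
        }
      }
      NA_integer_
    }
    tokens <- character(0)
    bad <- FALSE
    emit <- function(f, entryLabels) {
      tokens <<- c(tokens, st[[f]]$token)
      for (s in st[[f]]$slots) {
        if (!is.null(entryLabels) && all(s$labels %in% entryLabels)) next
        ch <- childAt(f, s$labels[1])
        if (is.na(ch)) { bad <<- TRUE; return() }
        emit(ch, s$labels)
      }
    }
    emit(tr$root, NULL)
    if (bad || length(tokens) != length(st)) {
      out[[i]] <- "unpaired_marker"
    } else {
      out[[i]] <- new("MotifSequence", tokens = tokens, mode = fr@mode,
                      fuseSplit = fr@fuseSplit,
                      sourceSmiles = fr@parentSmiles)
    }
  }
  out
}

#' Canonicalize a fragmentation into a motif sequence
#'
#' Orders the fragments of a [FragmentationResult-class] deterministically
#' and rewrites each motif so that all attachment-marker identifiers become
#' redundant: the same molecule yields a byte-identical sequence whatever
#' the atom ordering of the input SMILES, and [reconstructMolecule()]
#' rebuilds the molecule from the token order alone.  Canonicalizing the
#' fragmentation of a reconstructed molecule reproduces the sequence
#' (idempotence).
#'
#' @param frags a [FragmentationResult-class], or a list of them.
#' @return a [MotifSequence-class] (or a list of them / error-message
#'   strings for invalid entries when a list was given).  Errors:
#'   `unpaired_marker` when a bond label does not occur on exactly two
#'   fragments.
#' @export
canonicalizeMotifs <- function(frags) {
  if (inherits(frags, "FragmentationResult")) {
    res <- .canonicalizeBatch(list(frags))[[1]]
    if (is.character(res)) stop(res)
    return(res)
  }
  .canonicalizeBatch(frags)
}

## ---- reconstruction ------------------------------------------------------

## stack automaton: token slot layouts in, join plan out
.reconstructPlan <- function(slotsPerToken) {
  nt <- length(slotsPerToken)
  if (nt == 0L) return(list(reason = "empty_sequence"))
  for (i in seq_len(nt))
    if (is.null(slotsPerToken[[i]])) return(list(reason = "invalid_token"))
  bonds <- list(); fuses <- list()
  stack <- list()
  pushRev <- function(fragIdx, slots) {
    for (s in rev(slots))
      stack[[length(stack) + 1L]] <<- list(frag = fragIdx, slot = s)
  }
  pushRev(1L, slotsPerToken[[1]])
  if (nt > 1L) for (i in 2:nt) {
    if (!length(stack)) return(list(reason = "dangling_marker"))
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    si <- slotsPerToken[[i]]
    if (!length(si)) return(list(reason = "dangling_marker"))
    first <- si[[1]]
    if (first$pos[1] != 0L) return(list(reason = "dangling_marker"))
    if (top$slot$kind != first$kind)
      return(list(reason = "incompatible_fused_edge"))
    if (first$kind == "bond") {
      bonds[[length(bonds) + 1L]] <-
        c(top$frag - 1L, top$slot$pos, i - 1L, first$pos)
    } else {
      fuses[[length(fuses) + 1L]] <-
        c(top$frag - 1L, top$slot$pos[1], top$slot$pos[2],
          i - 1L, first$pos[1], first$pos[2])
    }
    pushRev(i, si[-1])
  }
  if (length(stack)) return(list(reason = "dangling_marker"))
  list(bonds = bonds, fuses = fuses)
}

#' Reconstruct molecules from motif sequences
#'
#' The reverse of fragmentation + canonicalization: paired markers are
#' joined by single bonds, fused-edge marker pairs are merged by atom
#' identification (the duplicated edge atoms become carbons and the edge
#' keeps its recorded bond order), and the result is returned as canonical
#' SMILES.  Invalid sequences are reported, not raised: they are exactly
#' what the validity metric of a generative model counts.
#'
#' @param seqs a [MotifSequence-class], a character vector of motif tokens
#'   (one sequence), or a list of either.
#' @return data.frame with columns `smiles` (`NA` when invalid), `valid`,
#'   `reason` (`dangling_marker`, `valence_violation`,
#'   `incompatible_fused_edge`, `invalid_token`).
#' @export
reconstructMolecules <- function(seqs) {
  if (inherits(seqs, "MotifSequence") || is.character(seqs))
    seqs <- list(seqs)
  tokenLists <- lapply(seqs, function(s)
    if (inherits(s, "MotifSequence")) s@tokens else as.character(s))
  uniq <- unique(unlist(tokenLists))
  info <- bkTokenInfo(uniq)
  slotOf <- vector("list", length(uniq))
  names(slotOf) <- uniq
  for (k in seq_along(uniq)) {
    r <- info[[k]]
    if (isTRUE(r$ok)) {
      labs <- rep(NA_integer_, r$n_dummy)    # labels unused at decode time
      pairs <- lapply(r$fuse_pairs, function(p) c(p[[1]], p[[2]]))
      slotOf[[k]] <- .buildSlots(labs, pairs)
    }
  }
  plans <- lapply(tokenLists, function(tk) .reconstructPlan(slotOf[tk]))
  todo <- which(vapply(plans, function(p) is.null(p$reason), TRUE))
  items <- lapply(todo, function(i)
    list(tokens = .aslist(tokenLists[[i]]),
         bonds = lapply(plans[[i]]$bonds, as.integer),
         fuses = lapply(plans[[i]]$fuses, as.integer)))
  joined <- if (length(items)) bkJoin(items) else list()
  smiles <- rep(NA_character_, length(seqs))
  reason <- vapply(plans, function(p)
    if (is.null(p$reason)) NA_character_ else p$reason, "")
  for (j in seq_along(todo)) {
    r <- joined[[j]]
    if (isTRUE(r$ok)) smiles[todo[j]] <- r$smiles
    else reason[todo[j]] <- r$reason
  }
  data.frame(smiles = smiles, valid = !is.na(smiles), reason = reason,
             stringsAsFactors = FALSE)
}

#' @rdname reconstructMolecules
#' @param seq a single [MotifSequence-class] or character token vector.
#' @return `reconstructMolecule`: a single canonical SMILES; errors with
#'   the failure reason on an invalid sequence.
#' @export
reconstructMolecule <- function(seq) {
  df <- reconstructMolecules(list(seq))
  if (!df$valid[1]) stop("invalid_sequence: ", df$reason[1])
  df$smiles[1]
}

#' Verify fragmentation/reconstruction round trips
#'
#' Fragments, canonicalizes and reconstructs every molecule, then compares
#' the result with the input by canonical SMILES.  The headline accuracy
#' disregards chirality (stereo-stripped comparison); the stereo-strict
#' rate is reported alongside.  Failures are data, not errors; corpus
#' construction drops them.
#'
#' @param smiles character vector of standardized SMILES.
#' @param mode fragmentation mode, see [fragmentMolecules()].
#' @param fuseSplit see [fragmentMolecules()].
#' @return list with `accuracy` (stereo-stripped fraction), `accuracyStereo`
#'   (strict), `n`, `failures` (data.frame `smiles`, `stage`, `reason`),
#'   and `sequences` (list of [MotifSequence-class], `NULL` where failed).
#' @export
verifyRoundtrip <- function(smiles, mode = c("motif", "scaffold"),
                            fuseSplit = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(smiles) > 0L)
  frs <- suppressWarnings(fragmentMolecules(smiles, mode, fuseSplit))
  seqs <- .canonicalizeBatch(frs)
  isSeq <- vapply(seqs, function(s) inherits(s, "MotifSequence"), TRUE)
  recon <- rep(NA_character_, length(smiles))
  reasons <- rep(NA_character_, length(smiles))
  reasons[!isSeq] <- vapply(seqs[!isSeq], function(s)
    if (is.character(s)) s else "canonicalization_failure", "")
  if (any(isSeq)) {
    rd <- reconstructMolecules(seqs[isSeq])
    recon[isSeq] <- rd$smiles
    reasons[isSeq] <- rd$reason
  }
  both <- c(smiles, recon)
  strip <- unlist(lapply(bkCanonical(both, stripStereo = TRUE),
                         function(x) if (is.null(x)) NA_character_ else x))
  keep <- unlist(lapply(bkCanonical(both, stripStereo = FALSE),
                        function(x) if (is.null(x)) NA_character_ else x))
  n <- length(smiles)
  okStrip <- !is.na(recon) & strip[seq_len(n)] == strip[n + seq_len(n)]
  okStrict <- !is.na(recon) & keep[seq_len(n)] == keep[n + seq_len(n)]
  okStrip[is.na(okStrip)] <- FALSE
  okStrict[is.na(okStrict)] <- FALSE
  fails <- which(!okStrip)
  failures <- data.frame(
    smiles = smiles[fails],
    stage = ifelse(is.na(recon[fails]), "decode", "mismatch"),
    reason = ifelse(is.na(recon[fails]),
                    ifelse(is.na(reasons[fails]), "unknown", reasons[fails]),
                    "smiles_mismatch"),
    stringsAsFactors = FALSE)
  list(accuracy = mean(okStrip), accuracyStereo = mean(okStrict), n = n,
       failures = failures,
       sequences = lapply(seq_len(n), function(i)
         if (isSeq[i]) seqs[[i]] else NULL))
}
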