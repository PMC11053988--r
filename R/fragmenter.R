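## Fragmentation rules: decompose a molecule into attachment-marked motifs.
##
## motif mode:    cut every acyclic single bond joining a ring atom to an
##                off-ring atom or to an atom of another ring, plus every
##                BRICS-cleavable bond (union of the two bond sets).
## scaffold mode: cut every single bond between the Bemis-Murcko scaffold
##                and its side chains; with fuseSplit additionally separate
##                fused rings of the scaffold at shared edges, duplicating
##                the two edge atoms into both subrings as dummy atoms.

.annotationFrames <- function(ann) {
  atoms <- do.call(rbind, lapply(ann$atoms, function(a)
    data.frame(z = a$z, aromatic = isTRUE(a$aromatic), charge = a$charge,
               inring = isTRUE(a$inring), nrings = a$nrings,
               degree = a$degree, isotope = a$isotope, rank = a$rank)))
  bonds <- if (length(ann$bonds)) do.call(rbind, lapply(ann$bonds, function(b)
    data.frame(u = b$b, v = b$e, order = b$order, ring = isTRUE(b$ring),
               nrings = b$nrings, aromatic = isTRUE(b$aromatic))))
  else data.frame(u = integer(), v = integer(), order = numeric(),
                  ring = logical(), nrings = integer(), aromatic = logical())
  brics <- if (length(ann$brics))
    t(vapply(ann$brics, function(p) c(p[[1]], p[[2]]), c(0, 0)))
  else matrix(0, 0, 2)
  list(atoms = atoms, bonds = bonds, brics = brics,
       natoms = ann$natoms, rings = ann$rings)
}

## Bemis-Murcko scaffold membership: iteratively prune all terminal atoms
## (leaving the ring systems and their linkers), then restore atoms that
## are multiply bonded directly to that core (e.g. exocyclic =O), matching
## the field's standard scaffold definition.
murckoMembership <- function(g) {
  n <- g$natoms
  if (!any(g$atoms$inring)) return(rep(FALSE, n))
  member <- rep(TRUE, n)
  b <- g$bonds
  repeat {
    deg <- integer(n)
    for (i in seq_len(nrow(b))) {
      if (member[b$u[i] + 1L] && member[b$v[i] + 1L]) {
        deg[b$u[i] + 1L] <- deg[b$u[i] + 1L] + 1L
        deg[b$v[i] + 1L] <- deg[b$v[i] + 1L] + 1L
      }
    }
    drop <- member & deg == 1L
    if (!any(drop)) break
    member[drop] <- FALSE
  }
  for (i in seq_len(nrow(b))) {
    if (b$order[i] >= 2 && !b$aromatic[i]) {
      mu <- member[b$u[i] + 1L]; mv <- member[b$v[i] + 1L]
      if (mu && !mv) member[b$v[i] + 1L] <- TRUE
      if (mv && !mu) member[b$u[i] + 1L] <- TRUE
    }
  }
  member
}

.selectCutsMotif <- function(g) {
  b <- g$bonds
  inring <- g$atoms$inring
  sel <- !b$ring & !b$aromatic & b$order == 1 &
    (inring[b$u + 1L] | inring[b$v + 1L]) &
    g$atoms$z[b$u + 1L] > 0 & g$atoms$z[b$v + 1L] > 0
  cuts <- b[sel, c("u", "v"), drop = FALSE]
  if (nrow(g$brics)) {
    key <- paste(pmin(cuts$u, cuts$v), pmax(cuts$u, cuts$v))
    bk <- paste(pmin(g$brics[, 1], g$brics[, 2]),
                pmax(g$brics[, 1], g$brics[, 2]))
    add <- !bk %in% key & !duplicated(bk)
    if (any(add))
      cuts <- rbind(cuts, data.frame(u = g$brics[add, 1],
                                     v = g$brics[add, 2]))
  }
  cuts
}

.selectCutsScaffold <- function(g) {
  member <- murckoMembership(g)
  if (!any(member)) return(NULL)                     # acyclic molecule
  b <- g$bonds
  sel <- xor(member[b$u + 1L], member[b$v + 1L]) & b$order == 1 &
    !b$aromatic
  b[sel, c("u", "v"), drop = FALSE]
}

.orderCuts <- function(cuts, ranks) {
  if (is.null(cuts) || nrow(cuts) == 0L)
    return(data.frame(u = integer(), v = integer(), label = integer()))
  lo <- pmin(ranks[cuts$u + 1L], ranks[cuts$v + 1L])
  hi <- pmax(ranks[cuts$u + 1L], ranks[cuts$v + 1L])
  o <- order(lo, hi)
  data.frame(u = as.integer(cuts$u[o]), v = as.integer(cuts$v[o]),
             label = seq_len(nrow(cuts)))
}

## eligible fused-ring shared edges of a (scaffold) fragment: an edge in
## exactly two SSSR rings, both rings non-aromatic, whose two atoms are
## unsubstituted carbons each in exactly two rings.  Bridged systems,
## aromatic fusions and substituted fusion atoms are left intact so that
## reconstruction stays exact.
.eligibleFuseEdges <- function(g) {
  b <- g$bonds
  a <- g$atoms
  ok <- b$nrings == 2 &
    a$z[b$u + 1L] == 6 & a$z[b$v + 1L] == 6 &
    a$charge[b$u + 1L] == 0 & a$charge[b$v + 1L] == 0 &
    a$nrings[b$u + 1L] == 2 & a$nrings[b$v + 1L] == 2 &
    a$degree[b$u + 1L] == 3 & a$degree[b$v + 1L] == 3
  if (any(ok)) {
    aromaticRingFree <- vapply(which(ok), function(i) {
      rings <- Filter(function(r) {
        r <- unlist(r)
        b$u[i] %in% r && b$v[i] %in% r
      }, g$rings)
      !any(vapply(rings, function(r) any(a$aromatic[unlist(r) + 1L]), TRUE))
    }, TRUE)
    ok[ok] <- aromaticRingFree
  }
  e <- b[ok, c("u", "v"), drop = FALSE]
  if (nrow(e) == 0L) return(e)
  lo <- pmin(a$rank[e$u + 1L], a$rank[e$v + 1L])
  hi <- pmax(a$rank[e$u + 1L], a$rank[e$v + 1L])
  e[order(lo, hi), , drop = FALSE]
}

.composeOrig <- function(parentOrig, childOrig) {
  vapply(childOrig, function(o) {
    o <- as.integer(o)
    if (o < 0L) -1L else parentOrig[o + 1L]
  }, 0L)
}

## split fused edges of one fragment until none is eligible; returns
## list(fragments = <records>, fuses = data.frame(labelU, labelV, order),
## nextLabel)
.fuseSplitFragment <- function(frag, nextLabel) {
  queue <- list(frag)
  done <- list()
  fuses <- data.frame(labelU = integer(), labelV = integer(),
                      order = numeric())
  while (length(queue)) {
    f <- queue[[1]]
    queue <- queue[-1]
    ann <- bkAnnotate(f$smiles)[[1]]
    g <- .annotationFrames(ann)
    edges <- .eligibleFuseEdges(g)
    split <- NULL
    if (nrow(edges)) {
      for (i in seq_len(nrow(edges))) {
        res <- bkFuseSplit(list(list(smiles = f$smiles,
                                     u = edges$u[i], v = edges$v[i],
                                     lu = nextLabel, lv = nextLabel + 1L)))[[1]]
        if (isTRUE(res$ok)) { split <- res; break }
      }
    }
    if (is.null(split)) {
      done[[length(done) + 1L]] <- f
    } else {
      fuses <- rbind(fuses, data.frame(labelU = nextLabel,
                                       labelV = nextLabel + 1L,
                                       order = split$edge_order))
      nextLabel <- nextLabel + 2L
      for (sf in split$frags) {
        queue[[length(queue) + 1L]] <- list(
          smiles = sf$smiles,
          origAtoms = .composeOrig(f$origAtoms, sf$orig_atoms))
      }
    }
  }
  list(fragments = done, fuses = fuses, nextLabel = nextLabel)
}

#' Fragment molecules into attachment-marked motifs
#'
#' Applies one of two bond-breaking schemes and returns one
#' [FragmentationResult-class] per molecule.  In `"motif"` mode every
#' acyclic single bond between a ring atom and an off-ring atom (or an atom
#' of a different ring) is broken, together with every BRICS-cleavable
#' bond; a bond matched by both rules is broken once.  In `"scaffold"` mode
#' all single bonds between the Bemis-Murcko scaffold and its side chains
#' are broken; with `fuseSplit = TRUE` fused rings of the scaffold are
#' additionally separated at shared edges, the two edge atoms being
#' duplicated into both subrings and replaced by dummy atoms.
#'
#' Each break inserts two dummy atoms sharing a bond label, so fragments
#' memorize the original connectivity; ring bonds are never broken (a
#' fused-edge separation duplicates, it does not break).  Tetrahedral tags
#' adjacent to a cut are preserved, the marker standing in for the departed
#' neighbour.
#'
#' @param smiles character vector of standardized SMILES.
#' @param mode `"motif"` or `"scaffold"`.
#' @param fuseSplit scaffold mode only: separate fused-ring shared edges.
#' @return list of [FragmentationResult-class] (`NULL`, with a warning, for
#'   unparseable entries).
#' @seealso [canonicalizeMotifs()], [verifyRoundtrip()]
#' @export
fragmentMolecules <- function(smiles, mode = c("motif", "scaffold"),
                              fuseSplit = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.character(smiles))
  if (fuseSplit && mode != "scaffold")
    stop("fuseSplit applies to scaffold mode only")
  if (length(smiles) == 0L) return(list())
  anns <- bkAnnotate(smiles)
  graphs <- lapply(anns, function(a)
    if (is.null(a)) NULL else .annotationFrames(a))
  cutsList <- vector("list", length(smiles))
  acyclic <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    g <- graphs[[i]]
    if (is.null(g)) next
    cuts <- if (mode == "motif") .selectCutsMotif(g)
            else .selectCutsScaffold(g)
    if (is.null(cuts)) { acyclic[i] <- TRUE; cuts <- g$bonds[0, c("u", "v")] }
    cutsList[[i]] <- .orderCuts(cuts, g$atoms$rank)
  }
  okIdx <- which(!vapply(graphs, is.null, TRUE))
  items <- lapply(okIdx, function(i) {
    cc <- cutsList[[i]]
    list(smiles = smiles[i],
         cuts = lapply(seq_len(nrow(cc)), function(k)
           c(cc$u[k], cc$v[k], cc$label[k])))
  })
  fragRes <- if (length(items)) bkFragment(items) else list()
  out <- vector("list", length(smiles))
  for (j in seq_along(okIdx)) {
    i <- okIdx[j]
    fr <- fragRes[[j]]
    if (!isTRUE(fr$ok)) { warning("fragmentation failed: ", smiles[i]); next }
    g <- graphs[[i]]
    frags <- lapply(fr$frags, function(f)
      list(smiles = f$smiles,
           origAtoms = vapply(f$orig_atoms, as.integer, 0L)))
    fuses <- data.frame(labelU = integer(), labelV = integer(),
                        order = numeric())
    if (mode == "scaffold" && fuseSplit && !acyclic[i]) {
      member <- murckoMembership(g)
      scafIdx <- which(vapply(frags, function(f) {
        oa <- f$origAtoms[f$origAtoms >= 0L]
        length(oa) > 0L && all(member[oa + 1L])
      }, TRUE))[1]
      if (!is.na(scafIdx)) {
        sp <- .fuseSplitFragment(frags[[scafIdx]],
                                 nextLabel = nrow(cutsList[[i]]) + 1L)
        frags <- c(frags[-scafIdx], sp$fragments)
        fuses <- sp$fuses
      }
    }
    out[[i]] <- new("FragmentationResult",
                    parentSmiles = smiles[i], mode = mode,
                    fuseSplit = fuseSplit, fragments = frags,
                    cuts = cutsList[[i]], fuses = fuses,
                    parentRanks = as.integer(g$atoms$rank),
                    acyclic = acyclic[i])
  }
  nbad <- sum(vapply(out, is.null, TRUE))
  if (nbad > 0L) warning(nbad, " molecule(s) could not be fragmented")
  out
}

#' @rdname fragmentMolecules
#' @param x a single SMILES string.
#' @return `fragmentMolecule`: one [FragmentationResult-class]; errors on
#'   unparseable input.
#' @export
fragmentMolecule <- function(x, mode = c("motif", "scaffold"),
                             fuseSplit = FALSE) {
  res <- suppressWarnings(fragmentMolecules(x, mode, fuseSplit))[[1]]
  if (is.null(res)) stop("parse_failure: ", x)
  res
}

#' Aggregate motif statistics over fragmentations
#'
#' Mean motif weight (g/mol) and mean motif size (heavy atoms), markers
#' excluded, plus a histogram of attachment-point counts per motif.
#'
#' @param frags list of [FragmentationResult-class] (NULL entries ignored).
#' @return list with `meanMotifWeight`, `meanMotifSize`, `attachHistogram`
#'   (named table), `nMotifs`.
#' @export
motifStatistics <- function(frags) {
  if (inherits(frags, "FragmentationResult")) frags <- list(frags)
  frags <- Filter(Negate(is.null), frags)
  if (length(frags) == 0L) stop("empty_input")
  lab <- unlist(lapply(frags, motifTokens))
  plain <- gsub("\\[[0-9]+\\*\\]", "[*]", lab)
  info <- bkBasic(plain)
  mw <- vapply(info, function(x) x$mw, 0)
  heavy <- vapply(info, function(x) x$heavy, 0)
  nat <- vapply(info, function(x) x$n_dummy, 0)
  list(meanMotifWeight = mean(mw), meanMotifSize = mean(heavy),
       attachHistogram = table(nat), nMotifs = length(lab))
}
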