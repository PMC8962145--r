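## Matched molecular pairs: single-cut fragment indexing in the
## Hussain-Rea style. Each molecule is fragmented at every acyclic single
## bond into (core, R-group) with a dummy-atom attachment point; two
## molecules form an MMP when they share a core with differing R-groups.
## Hydrogen counts as an R-group with zero heavy atoms, so additions and
## deletions of a substituent (e.g. benzene vs toluene) also match.

## all (core, R-group) decompositions of a molecule, as a data.frame with
## columns core, r, r_heavy
mmpFragmentIndex <- function(x) {
  mol <- .asMolecule(x)
  key <- paste0("mmpidx:", mol@smiles)
  hit <- .molCache[[key]]
  if (!is.null(hit)) return(hit)
  g <- mol@graph
  graphs <- list()
  meta <- list()
  ## bond cuts at acyclic single bonds
  rb <- .ringBonds(g)
  cuts <- which(g$bonds$order == 1L & !rb)
  for (ci in cuts) {
    a <- g$bonds$a[ci]; b <- g$bonds$b[ci]
    g2 <- g
    g2$bonds <- g2$bonds[-ci, , drop = FALSE]
    memb <- .componentsOf(g2)
    sideA <- which(memb == memb[a])
    sideB <- which(memb == memb[b])
    fragA <- .attachStar(g2, sideA, a)
    fragB <- .attachStar(g2, sideB, b)
    graphs <- c(graphs, list(fragA, fragB))
    meta <- c(meta, list(c(length(sideA), length(sideB)),
                         c(length(sideB), length(sideA))))
  }
  ## hydrogen cuts: the whole molecule as core, H as R-group
  impH <- .implicitH(g)
  hpos <- which(impH >= 1L)
  for (i in hpos) {
    graphs <- c(graphs, list(.attachStar(g, seq_along(g$elem), i)))
    meta <- c(meta, list(c(length(g$elem), 0L)))
  }
  if (length(graphs) == 0L) {
    idx <- data.frame(core = character(0), r = character(0),
                      r_heavy = integer(0))
    .molCache[[key]] <- idx
    return(idx)
  }
  smis <- .graphCanonical(graphs)
  ncut <- length(cuts)
  rows <- list()
  for (k in seq_len(ncut)) {
    sa <- smis[2 * k - 1]; sb <- smis[2 * k]
    ha <- meta[[2 * k - 1]][1]; hb <- meta[[2 * k - 1]][2]
    ## each side serves once as core and once as R-group
    rows[[length(rows) + 1]] <- data.frame(core = sa, r = sb, r_heavy = hb)
    rows[[length(rows) + 1]] <- data.frame(core = sb, r = sa, r_heavy = ha)
  }
  for (k in seq_along(hpos)) {
    rows[[length(rows) + 1]] <- data.frame(core = smis[2 * ncut + k],
                                           r = "[H]", r_heavy = 0L)
  }
  idx <- unique(do.call(rbind, rows))
  rownames(idx) <- NULL
  .molCache[[key]] <- idx
  idx
}

## subgraph over `atoms` plus a dummy "*" bonded to `attach`
.attachStar <- function(g, atoms, attach) {
  sub <- .dropAtoms(g, setdiff(seq_along(g$elem), atoms))
  pos <- match(attach, sort(atoms))
  sub$elem <- c(sub$elem, "*")
  sub$charge <- c(sub$charge, 0L)
  sub$bonds <- rbind(sub$bonds,
                     data.frame(a = pos, b = length(sub$elem), order = 1L))
  sub
}

#' Are two molecules a matched molecular pair?
#'
#' TRUE when a single acyclic single-bond cut (or a hydrogen replacement)
#' in each molecule yields an identical core with differing R-groups, and
#' for both molecules the R-group contributes at most a 0.33 fraction of
#' the molecule's heavy atoms.
#'
#' @param a,b SMILES strings or [CanonicalMolecule-class] objects.
#' @param maxRatio maximum R-group heavy-atom fraction (default 0.33).
#' @return logical.
#' @export
isMmp <- function(a, b, maxRatio = 0.33) {
  ma <- .asMolecule(a); mb <- .asMolecule(b)
  if (ma@smiles == mb@smiles) return(FALSE)
  ia <- mmpFragmentIndex(ma)
  ib <- mmpFragmentIndex(mb)
  if (nrow(ia) == 0L || nrow(ib) == 0L) return(FALSE)
  m <- merge(ia, ib, by = "core", suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) return(FALSE)
  eps <- 1e-9
  ok <- m$r_a != m$r_b &
    m$r_heavy_a / ma@heavyAtomCount <= maxRatio + eps &
    m$r_heavy_b / mb@heavyAtomCount <= maxRatio + eps
  any(ok)
}
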