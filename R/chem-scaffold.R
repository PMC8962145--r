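## Murcko and generic scaffolds.

#' Murcko scaffold of a molecule
#'
#' The ring systems plus the linkers connecting them, with side chains
#' removed. Terminal atoms attached by single bonds are pruned
#' iteratively; atoms held by a double/triple bond (e.g. exocyclic
#' carbonyl oxygens) are retained.
#'
#' @param x a SMILES string or [CanonicalMolecule-class]; must contain at
#'   least one ring.
#' @return canonical SMILES of the scaffold.
#' @export
murckoScaffold <- function(x) {
  mol <- .asMolecule(x)
  if (mol@ringCount < 1L)
    stop("no-scaffold error: acyclic molecule ", mol@smiles)
  key <- paste0("murcko:", mol@smiles)
  hit <- .molCache[[key]]
  if (!is.null(hit)) return(hit)
  g <- .scaffoldGraph(mol@graph)
  smi <- .graphCanonical(list(g))
  .molCache[[key]] <- smi
  smi
}

## iteratively prune degree-1 atoms bonded by a single bond
.scaffoldGraph <- function(g) {
  repeat {
    deg <- .degrees(g)
    term <- which(deg == 1L)
    if (length(term) == 0L) break
    drop <- integer(0)
    for (i in term) {
      bi <- which(g$bonds$a == i | g$bonds$b == i)
      if (length(bi) == 1L && g$bonds$order[bi] == 1L) drop <- c(drop, i)
    }
    if (length(drop) == 0L) break
    g <- .dropAtoms(g, drop)
  }
  g
}

#' Generic scaffold (topology skeleton)
#'
#' The Murcko scaffold with every atom replaced by carbon and every bond
#' order set to single, then canonicalized: a pure graph-topology
#' skeleton invariant under heteroatom substitution.
#'
#' @inheritParams murckoScaffold
#' @return canonical SMILES of the generic scaffold.
#' @export
genericScaffold <- function(x) {
  mol <- .asMolecule(x)
  if (mol@ringCount < 1L)
    stop("no-scaffold error: acyclic molecule ", mol@smiles)
  key <- paste0("generic:", mol@smiles)
  hit <- .molCache[[key]]
  if (!is.null(hit)) return(hit)
  g <- .scaffoldGraph(mol@graph)
  g$elem[] <- "C"
  g$charge[] <- 0L
  if (nrow(g$bonds) > 0L) g$bonds$order[] <- 1L
  smi <- .graphCanonical(list(g))
  .molCache[[key]] <- smi
  smi
}
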