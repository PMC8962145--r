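## Hashed circular (Morgan-style, radius 2, ECFP4-equivalent) fingerprints
## and Tanimoto similarity. Implemented directly on the molecular graph:
## no installed R package provides an ECFP4-class fingerprint.

## double-width polynomial hash: two independent components combined by
## the Chinese remainder construction, so distinct inputs below p1*p2
## keep distinct residue pairs and joint collisions are ~1/(p1*p2).
## All intermediates stay below 2^53, exact in doubles.
.HASH_P1 <- 67108859   # primes just under 2^26
.HASH_P2 <- 67108837

.intHash <- function(v) {
  h1 <- 7; h2 <- 13
  for (x in v) {
    h1 <- (h1 * 31 + x %% .HASH_P1) %% .HASH_P1
    h2 <- (h2 * 37 + x %% .HASH_P2) %% .HASH_P2
  }
  h1 * .HASH_P2 + h2
}

#' Morgan-style circular fingerprint
#'
#' Circular atom environments of radius 0..`radius` (bond diameter
#' 2*`radius`), from initial atom invariants (element, degree, formal
#' charge, implicit hydrogens, ring membership) iteratively refined over
#' bonded neighbours, hashed into a fixed-length binary vector. With the
#' defaults this is the ECFP4-equivalent 2048-bit fingerprint commonly
#' used for Tanimoto similarity.
#'
#' @param x a SMILES string or [CanonicalMolecule-class].
#' @param nbits fingerprint length (default 2048).
#' @param radius neighbourhood radius (default 2).
#' @return sorted integer vector of set bit positions (0-based, sparse
#'   representation of the binary vector).
#' @export
morganFingerprint <- function(x, nbits = 2048L, radius = 2L) {
  mol <- .asMolecule(x)
  key <- paste0("fp:", mol@smiles, ":", nbits, ":", radius)
  hit <- .molCache[[key]]
  if (!is.null(hit)) return(hit)
  feats <- .morganFeatures(mol@graph, radius)
  bits <- sort(unique(feats %% nbits))
  .molCache[[key]] <- bits
  bits
}

## the underlying feature identifiers (pre-hash-folding); exposed for the
## feature-set route used in cross-checks
.morganFeatures <- function(g, radius = 2L) {
  n <- length(g$elem)
  deg <- .degrees(g)
  impH <- .implicitH(g)
  ring <- .ringAtoms(g)
  elemIdx <- vapply(g$elem, function(e) {
    i <- match(e, names(.STD_VALENCE))
    if (is.na(i)) 99L else i
  }, integer(1), USE.NAMES = FALSE)
  inv <- vapply(seq_len(n), function(i) {
    .intHash(c(elemIdx[i], deg[i], g$charge[i] + 10L, impH[i],
               as.integer(ring[i])))
  }, numeric(1))
  ## neighbour lists with bond orders
  nbr <- vector("list", n)
  if (nrow(g$bonds) > 0L) {
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[i]; b <- g$bonds$b[i]; o <- g$bonds$order[i]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }
  feats <- inv
  cur <- inv
  for (r in seq_len(radius)) {
    nxt <- numeric(n)
    for (i in seq_len(n)) {
      if (is.null(nbr[[i]])) { nxt[i] <- .intHash(c(r, cur[i])); next }
      pairs <- nbr[[i]]
      ord <- order(pairs[, 2], cur[pairs[, 1]])
      acc <- c(r, cur[i])
      for (k in ord) acc <- c(acc, pairs[k, 2], cur[pairs[k, 1]])
      nxt[i] <- .intHash(acc)
    }
    cur <- nxt
    feats <- c(feats, cur)
  }
  unique(feats)
}

#' Tanimoto similarity between two molecules
#'
#' Computed over the Morgan-style radius-2 binary fingerprints:
#' `|A & B| / |A | B|`. Symmetric, in [0, 1], and 1 exactly when the two
#' fingerprints are identical.
#'
#' @param a,b SMILES strings or [CanonicalMolecule-class] objects.
#' @param nbits fingerprint length.
#' @return numeric similarity in [0, 1].
#' @export
tanimotoSimilarity <- function(a, b, nbits = 2048L) {
  fa <- morganFingerprint(a, nbits = nbits)
  fb <- morganFingerprint(b, nbits = nbits)
  inter <- length(intersect(fa, fb))
  uni <- length(fa) + length(fb) - inter
  if (uni == 0L) return(0)
  inter / uni
}
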