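## Standardization pipeline. Steps, in order: parse (with syntax/valence
## checks), disconnect metals, keep the largest fragment, neutralize
## charges, reionize acids / apply normalization rules (OpenBabel's
## neutralize pass covers both at the depth needed here), canonicalize.
## Stereochemistry annotations survive the round trip.

## per-session cache: canonical smiles -> CanonicalMolecule
.molCache <- new.env(parent = emptyenv())

#' Standardize a raw SMILES string
#'
#' Applies the molecule standardization pipeline: parse and sanitize,
#' disconnect metal-heteroatom bonds, keep the largest fragment (by heavy
#' atoms), neutralize formal charges where an (de)protonation exists,
#' and emit the canonical SMILES. Stereochemistry is preserved.
#'
#' @param rawSmiles a single SMILES string.
#' @return a [CanonicalMolecule-class].
#' @examples
#' standardizeMolecule("CC(=O)[O-].[Na+]")  # -> acetic acid
#' @export
standardizeMolecule <- function(rawSmiles) {
  stopifnot(is.character(rawSmiles), length(rawSmiles) == 1L)
  g <- .smilesToGraph(rawSmiles)   # syntax + parse checks
  if (.hasMetalBond(g)) {
    ## covalently written salts: graph surgery (stereo annotations are
    ## not retained on this rare path)
    g <- .disconnectMetals(g)
    g <- .largestFragment(g)
    if (length(g$elem) == 0L) stop("standardization error: no atoms left")
    base <- .graphCanonical(list(g))
  } else {
    ## string-level route keeps stereochemistry through canonicalization
    can <- .obCanonical(rawSmiles)
    if (!nzchar(can)) stop("standardization error for '", rawSmiles, "'")
    frags <- strsplit(can, ".", fixed = TRUE)[[1]]
    base <- if (length(frags) == 1L) frags else .pickLargestFragment(frags)
  }
  smi <- .obCanonical(base, neutralize = TRUE)
  if (!nzchar(smi)) stop("standardization error for '", rawSmiles, "'")
  mol <- .canonicalMoleculeFromSmiles(smi)
  if (!.valenceOk(mol@graph))
    stop("standardization error: impossible valence in '", rawSmiles, "'")
  mol
}

.hasMetalBond <- function(g) {
  if (nrow(g$bonds) == 0L) return(FALSE)
  any(g$elem[g$bonds$a] %in% .METALS | g$elem[g$bonds$b] %in% .METALS)
}

## fragment SMILES with the most (non-metal) heavy atoms; ties go to the
## earlier fragment
.pickLargestFragment <- function(frags) {
  score <- vapply(frags, function(f) {
    g <- tryCatch(.smilesToGraph(f), error = function(e) NULL)
    if (is.null(g)) return(-1)
    sum(!g$elem %in% .METALS) * 1000 + nrow(g$bonds)
  }, numeric(1))
  frags[[which.max(score)]]
}

## build the value object from an already-standard canonical SMILES
.canonicalMoleculeFromSmiles <- function(smiles) {
  hit <- .molCache[[smiles]]
  if (!is.null(hit)) return(hit)
  ## canonicalize at the string level (stereo-preserving); idempotent on
  ## already-canonical input
  can <- .obCanonical(smiles)
  if (!nzchar(can)) stop("SMILES parse error: '", smiles, "'")
  g <- .smilesToGraph(can)
  obj <- new("CanonicalMolecule", smiles = can,
             heavyAtomCount = length(g$elem),
             ringCount = as.integer(.ringCount(g)), graph = g)
  .molCache[[can]] <- obj
  .molCache[[smiles]] <- obj
  obj
}

## resolve smiles-or-molecule arguments in user-facing ops
.asMolecule <- function(x) {
  if (is(x, "CanonicalMolecule")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  .canonicalMoleculeFromSmiles(x)
}

## break bonds between common salt-forming metals and N/O/S, assigning
## ionic charges, before fragment selection
.disconnectMetals <- function(g) {
  b <- g$bonds
  if (nrow(b) == 0L) return(g)
  drop <- logical(nrow(b))
  for (i in seq_len(nrow(b))) {
    ea <- g$elem[b$a[i]]; eb <- g$elem[b$b[i]]
    ma <- ea %in% .METALS; mb <- eb %in% .METALS
    if (xor(ma, mb)) {
      met <- if (ma) b$a[i] else b$b[i]
      oth <- if (ma) b$b[i] else b$a[i]
      if (g$elem[oth] %in% c("N", "O", "S")) {
        drop[i] <- TRUE
        g$charge[met] <- g$charge[met] + 1L
        g$charge[oth] <- g$charge[oth] - 1L
      }
    }
  }
  g$bonds <- b[!drop, , drop = FALSE]
  rownames(g$bonds) <- NULL
  g
}

## keep the fragment with the most heavy atoms (ties: most bonds, then
## molfile order) — counting non-metal heavy atoms so bare counterions lose
.largestFragment <- function(g) {
  frags <- .fragments(g)
  if (length(frags) == 1L) return(frags[[1]])
  score <- vapply(frags, function(f) {
    sum(!f$elem %in% .METALS) * 1000 + nrow(f$bonds)
  }, numeric(1))
  frags[[which.max(score)]]
}

#' Is a SMILES string a chemically valid molecule?
#'
#' Syntactic well-formedness (balanced brackets/parentheses, matched ring
#' closures, legal tokens), parseability, and non-negative implicit
#' hydrogen counts under standard valence rules.
#'
#' @param smiles a single SMILES string.
#' @return logical.
#' @export
validSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) return(FALSE)
  if (!isTRUE(.smilesSyntaxOk(smiles))) return(FALSE)
  g <- tryCatch(.smilesToGraph(smiles), error = function(e) NULL)
  if (is.null(g)) return(FALSE)
  .valenceOk(g)
}

#' Canonical SMILES of a (valid) SMILES string
#'
#' @param smiles a single SMILES string.
#' @return the canonical SMILES, or `NA_character_` if invalid.
#' @export
canonicalSmiles <- function(smiles) {
  if (!validSmiles(smiles)) return(NA_character_)
  out <- .obCanonical(smiles)
  if (!nzchar(out)) NA_character_ else out
}

#' Structural summaries of a molecule
#'
#' @param x a SMILES string or [CanonicalMolecule-class].
#' @return integer count.
#' @export
heavyAtomCount <- function(x) .asMolecule(x)@heavyAtomCount

#' @rdname heavyAtomCount
#' @export
ringCount <- function(x) .asMolecule(x)@ringCount
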