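## Molecular graph layer.
##
## SMILES parsing and canonical SMILES writing are delegated to OpenBabel
## (via ChemmineOB); everything graph-topological (rings, valence, implicit
## hydrogens, fragment surgery) operates on a light internal representation
## parsed from V2000 molfiles:
##
##   list(elem   = character,   # element symbols, heavy atoms only
##        charge = integer,     # formal charges
##        bonds  = data.frame(a, b, order))   # 1-based, kekulized orders

.STD_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
                  Cl = 1, Br = 1, I = 1, "*" = 1)

## hypervalent alternatives tried in increasing order
.ALT_VALENCE <- list(P = c(3, 5), S = c(2, 4, 6), N = c(3, 5))

.METALS <- c("Li", "Na", "K", "Rb", "Cs", "Mg", "Ca", "Sr", "Ba", "Zn",
             "Al", "Fe", "Cu", "Mn", "Ag")

## one conversion round trip through OpenBabel; `source` may hold several
## records (newline-separated SMILES or concatenated molfiles)
.obConvert <- function(from, to, source, options = NULL) {
  .muteStderr()
  on.exit(.unmuteStderr())
  if (is.null(options)) {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source))
  } else {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source,
                                               options = options))
  }
}

## vector of SMILES -> vector of OpenBabel canonical SMILES ("" on failure)
.obCanonical <- function(smiles, neutralize = FALSE) {
  if (length(smiles) == 0L) return(character(0))
  opts <- if (neutralize) data.frame(names = "neutralize", args = "") else NULL
  out <- .obConvert("SMI", "CAN", paste0(paste(smiles, collapse = "\n"), "\n"),
                    options = opts)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- sub("\t.*$", "", lines)
  lines <- trimws(lines)
  if (length(lines) != length(smiles)) {
    ## a record failed to convert and was dropped: fall back one by one
    lines <- vapply(smiles, function(s) {
      o <- .obConvert("SMI", "CAN", paste0(s, "\n"), options = opts)
      o <- trimws(sub("\t.*$", "", strsplit(o, "\n", fixed = TRUE)[[1]][1]))
      if (length(o) == 0L || is.na(o)) "" else o
    }, character(1), USE.NAMES = FALSE)
  }
  lines
}

# ---------------------------------------------------------------------------
# SMILES syntax validation (OpenBabel silently repairs malformed input, so
# structural well-formedness is checked here first)

.SMILES_TOKEN_RE <- "\\[[^][]*\\]|Cl|Br|%[0-9]{2}|."

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I",
                     "b", "c", "n", "o", "p", "s", "*")

## TRUE/FALSE with the failure reason as attribute
.smilesSyntaxOk <- function(s) {
  fail <- function(msg) structure(FALSE, reason = msg)
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    return(fail("empty SMILES"))
  ## bracket balance must be checked before tokenization: an unclosed "["
  ## swallows the rest of the string under the token regex
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth_b <- 0L; depth_p <- 0L
  for (ch in chars) {
    if (ch == "[") { if (depth_b > 0L) return(fail("nested bracket")); depth_b <- depth_b + 1L }
    else if (ch == "]") { depth_b <- depth_b - 1L; if (depth_b < 0L) return(fail("unmatched ]")) }
    else if (ch == "(") depth_p <- depth_p + 1L
    else if (ch == ")") { depth_p <- depth_p - 1L; if (depth_p < 0L) return(fail("unmatched )")) }
  }
  if (depth_b != 0L) return(fail("unclosed bracket"))
  if (depth_p != 0L) return(fail("unbalanced parentheses"))
  toks <- regmatches(s, gregexpr(.SMILES_TOKEN_RE, s, perl = TRUE))[[1]]
  ring <- integer(0)
  for (tk in toks) {
    if (grepl("^\\[", tk)) {
      if (!grepl("^\\[[0-9]*[A-Za-z*][a-z]?[@H0-9+-]*(:[0-9]+)?\\]$", tk))
        return(fail(paste0("bad bracket atom ", tk)))
    } else if (grepl("^%[0-9]{2}$", tk) || grepl("^[0-9]$", tk)) {
      n <- as.integer(sub("^%", "", tk))
      if (n %in% ring) ring <- setdiff(ring, n) else ring <- c(ring, n)
    } else if (!tk %in% c(.ORGANIC_SUBSET, "(", ")", "-", "=", "#", ":",
                          "/", "\\", ".", "~", "$", "+")) {
      return(fail(paste0("illegal token ", tk)))
    }
  }
  if (length(ring) > 0L) return(fail("unmatched ring closure"))
  TRUE
}

# ---------------------------------------------------------------------------
# molfile <-> graph

.parseMolfile <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("truncated molfile")
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || natoms < 1L) stop("molfile with no atoms")
  elem <- trimws(substr(lines[4L + seq_len(natoms)], 32, 34))
  bondLines <- lines[4L + natoms + seq_len(nbonds)]
  o <- as.integer(substr(bondLines, 7, 9))
  o[o == 4L] <- 1L                       # aromatic orders come kekulized
  bonds <- data.frame(a = as.integer(substr(bondLines, 1, 3)),
                      b = as.integer(substr(bondLines, 4, 6)),
                      order = o)
  charge <- integer(natoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    flds <- strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]]
    n <- as.integer(flds[1])
    for (k in seq_len(n)) {
      idx <- as.integer(flds[2 * k])
      charge[idx] <- as.integer(flds[2 * k + 1])
    }
  }
  ## drop explicit hydrogens (standardization keeps the heavy-atom graph)
  hyd <- which(elem == "H")
  g <- list(elem = elem, charge = charge, bonds = bonds)
  if (length(hyd) > 0L) g <- .dropAtoms(g, hyd)
  g
}

.dropAtoms <- function(g, drop) {
  keep <- setdiff(seq_along(g$elem), drop)
  remap <- integer(length(g$elem))
  remap[keep] <- seq_along(keep)
  b <- g$bonds
  b <- b[!(b$a %in% drop) & !(b$b %in% drop), , drop = FALSE]
  b$a <- remap[b$a]; b$b <- remap[b$b]
  rownames(b) <- NULL
  list(elem = g$elem[keep], charge = g$charge[keep], bonds = b)
}

.writeMolfile <- function(g) {
  n <- length(g$elem); m <- nrow(g$bonds)
  hdr <- c("", "  MolPairGen", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   rep(0, n), rep(0, n), rep(0, n), g$elem)
  bonds <- if (m > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", g$bonds$a, g$bonds$b, g$bonds$order)
  } else character(0)
  chg <- which(g$charge != 0L)
  chglines <- if (length(chg) > 0L) {
    vapply(chg, function(i) sprintf("M  CHG  1 %3d %3d", i, g$charge[i]),
           character(1))
  } else character(0)
  paste(c(hdr, atoms, bonds, chglines, "M  END", "$$$$"), collapse = "\n")
}

## canonical SMILES of one or more graphs (batched through OpenBabel)
.graphCanonical <- function(graphs) {
  if (length(graphs) == 0L) return(character(0))
  sdf <- paste(vapply(graphs, .writeMolfile, character(1)), collapse = "\n")
  out <- .obConvert("SDF", "CAN", paste0(sdf, "\n"))
  lines <- trimws(sub("\t.*$", "", strsplit(out, "\n", fixed = TRUE)[[1]]))
  if (length(lines) != length(graphs))
    stop("canonicalization failed for a fragment")
  lines
}

## SMILES -> graph (through an OpenBabel molfile round trip)
.smilesToGraph <- function(smiles) {
  ok <- .smilesSyntaxOk(smiles)
  if (!isTRUE(ok)) stop("SMILES parse error: ", attr(ok, "reason"),
                        " in '", smiles, "'")
  sdf <- .obConvert("SMI", "SDF", paste0(smiles, "\n"))
  if (!nzchar(sdf) || !grepl("V2000", sdf, fixed = TRUE))
    stop("SMILES parse error: OpenBabel could not read '", smiles, "'")
  .parseMolfile(sdf)
}

# ---------------------------------------------------------------------------
# graph utilities

.degrees <- function(g) {
  d <- integer(length(g$elem))
  if (nrow(g$bonds) > 0L) {
    t1 <- tabulate(g$bonds$a, nbins = length(g$elem))
    t2 <- tabulate(g$bonds$b, nbins = length(g$elem))
    d <- t1 + t2
  }
  d
}

.asIgraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$bonds) > 0L) g$bonds[, c("a", "b")] else
      data.frame(a = integer(0), b = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(g$elem)))
}

.componentsOf <- function(g) {
  igraph::components(.asIgraph(g))$membership
}

## cyclomatic number: bonds - atoms + connected components
.ringCount <- function(g) {
  comp <- if (length(g$elem) == 0L) 0L else max(.componentsOf(g))
  nrow(g$bonds) - length(g$elem) + comp
}

## logical per bond: part of a ring (i.e. not a bridge)
.ringBonds <- function(g) {
  if (nrow(g$bonds) == 0L) return(logical(0))
  ig <- .asIgraph(g)
  br <- igraph::bridges(ig)
  inring <- rep(TRUE, nrow(g$bonds))
  inring[as.integer(br)] <- FALSE
  inring
}

.ringAtoms <- function(g) {
  rb <- .ringBonds(g)
  atoms <- rep(FALSE, length(g$elem))
  if (any(rb)) {
    atoms[unique(c(g$bonds$a[rb], g$bonds$b[rb]))] <- TRUE
  }
  atoms
}

## implicit hydrogen count per atom under standard valence rules;
## negative values signal an impossible valence
.implicitH <- function(g) {
  n <- length(g$elem)
  bsum <- numeric(n)
  if (nrow(g$bonds) > 0L) {
    for (i in seq_len(nrow(g$bonds))) {
      o <- g$bonds$order[i]
      bsum[g$bonds$a[i]] <- bsum[g$bonds$a[i]] + o
      bsum[g$bonds$b[i]] <- bsum[g$bonds$b[i]] + o
    }
  }
  h <- integer(n)
  for (i in seq_len(n)) {
    el <- g$elem[i]
    if (el %in% .METALS) { h[i] <- 0L; next }
    base <- .STD_VALENCE[[el]]
    if (is.null(base) || is.na(base)) { h[i] <- 0L; next }
    cands <- if (!is.null(.ALT_VALENCE[[el]])) .ALT_VALENCE[[el]] else base
    target <- NA_integer_
    for (v in cands) {
      t <- v + g$charge[i]
      if (el %in% c("O", "S") && g$charge[i] > 0L) t <- v + g$charge[i]
      if (bsum[i] <= t) { target <- t; break }
    }
    if (is.na(target)) target <- max(cands) + g$charge[i]
    h[i] <- as.integer(target - bsum[i])
  }
  h
}

## chemically sensible: all implicit H counts non-negative
.valenceOk <- function(g) all(.implicitH(g) >= 0L)

## split graph into connected-component subgraphs
.fragments <- function(g) {
  memb <- .componentsOf(g)
  lapply(seq_len(max(memb)), function(k) {
    .dropAtoms(g, which(memb != k))
  })
}
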