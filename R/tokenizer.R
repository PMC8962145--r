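## SMILES tokenization, vocabularies, and model sequence assembly.

.SPECIAL_TOKENS <- c("<pad>", "<start>", "<end>", "<unk>")

#' Tokenize a SMILES string
#'
#' Splits into single characters, with three exceptions kept as single
#' tokens: the two-character element symbols `Cl` and `Br`, bracketed
#' atoms `[...]`, and two-digit ring closures `%nn`. Concatenating the
#' tokens reconstructs the input exactly.
#'
#' @param s a syntactically valid SMILES string.
#' @return character vector of tokens.
#' @export
tokenizeSmiles <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  ok <- .smilesSyntaxOk(s)
  if (!isTRUE(ok)) stop("tokenization error: ", attr(ok, "reason"),
                        " in '", s, "'")
  toks <- regmatches(s, gregexpr(.SMILES_TOKEN_RE, s, perl = TRUE))[[1]]
  stopifnot(identical(paste(toks, collapse = ""), s))
  toks
}

#' Reassemble a SMILES from its tokens
#'
#' @param tokens character vector as produced by [tokenizeSmiles()].
#' @return the SMILES string.
#' @export
detokenizeSmiles <- function(tokens) paste(tokens, collapse = "")

#' Build a vocabulary from a pair dataset
#'
#' The vocabulary is the union of every SMILES token and every
#' property-change token observed across all splits of the dataset, plus
#' the four special tokens. Each dataset gets its own vocabulary.
#'
#' @param dataset a [PairDataset-class] (or a data.frame with the same
#'   pair columns).
#' @param includePropertyTokens set `FALSE` for the unconditional model
#'   variant whose inputs carry no property tokens.
#' @return a [SmilesVocabulary-class].
#' @export
buildVocabulary <- function(dataset, includePropertyTokens = TRUE) {
  pairs <- if (is(dataset, "PairDataset")) dataset@pairs else dataset
  if (is.null(pairs) || nrow(pairs) == 0L) stop("empty dataset")
  smi <- unique(c(pairs$source_smiles, pairs$target_smiles))
  toks <- unique(unlist(lapply(smi, tokenizeSmiles), use.names = FALSE))
  if (includePropertyTokens) {
    toks <- c(toks, unique(pairs$logd_change_token),
              unique(pairs$solubility_token), unique(pairs$clearance_token))
  }
  ## radix sort: byte order, independent of the session's collation
  ## locale, so vocabularies (and hence parameter layouts) are identical
  ## across environments
  new("SmilesVocabulary",
      tokens = c(.SPECIAL_TOKENS, sort(unique(toks), method = "radix")))
}

#' Map tokens to indices and back
#'
#' Unknown tokens map to `<unk>` with a warning.
#'
#' @param vocab a [SmilesVocabulary-class].
#' @param tokens character vector of tokens.
#' @return integer indices (1-based).
#' @export
tokensToIds <- function(vocab, tokens) {
  idx <- match(tokens, vocab@tokens)
  if (anyNA(idx)) {
    warning("out-of-vocabulary tokens replaced by <unk>: ",
            paste(unique(tokens[is.na(idx)]), collapse = " "))
    idx[is.na(idx)] <- match("<unk>", vocab@tokens)
  }
  idx
}

#' @rdname tokensToIds
#' @param ids integer indices.
#' @export
idsToTokens <- function(vocab, ids) vocab@tokens[ids]

#' Assemble the model source sequence
#'
#' `[<start>] + [logD, solubility, clearance tokens] + SMILES tokens +
#' [<end>]` for the conditional model; the property tokens are omitted
#' when `change` is `NULL` (unconditional variant).
#'
#' @param change a [PropertyChange-class] or `NULL`.
#' @param startSmiles SMILES of the starting molecule.
#' @return character vector of tokens.
#' @export
assembleSource <- function(change, startSmiles) {
  prop <- if (is.null(change)) character(0) else propertyTokens(change)
  c("<start>", prop, tokenizeSmiles(startSmiles), "<end>")
}

#' Assemble the model target sequence
#'
#' @param targetSmiles SMILES of the target molecule.
#' @return character vector `[<start>] + tokens + [<end>]`.
#' @export
assembleTarget <- function(targetSmiles) {
  c("<start>", tokenizeSmiles(targetSmiles), "<end>")
}

#' Serialize / restore a vocabulary
#'
#' Plain-text format: one token per line, index = line number.
#'
#' @param vocab a [SmilesVocabulary-class].
#' @param path file path.
#' @export
writeVocabulary <- function(vocab, path) {
  writeLines(vocab@tokens, path)
  invisible(path)
}

#' @rdname writeVocabulary
#' @return [SmilesVocabulary-class] for `readVocabulary`.
#' @export
readVocabulary <- function(path) {
  new("SmilesVocabulary", tokens = readLines(path))
}
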