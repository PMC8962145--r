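#' @import methods
#' @importFrom stats sd setNames runif
#' @importFrom utils head read.delim write.table
#' @useDynLib MolPairGen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' A standardized molecule
#'
#' Value class holding the canonical SMILES of a standardized molecule
#' together with the cheap structural summaries the pair-mining filters
#' depend on. Create with [standardizeMolecule()].
#'
#' @slot smiles canonical SMILES string (re-canonicalization is idempotent).
#' @slot heavyAtomCount number of non-hydrogen atoms (>= 1).
#' @slot ringCount number of rings (cyclomatic number, >= 0).
#' @slot graph internal molecular-graph representation (list).
#' @exportClass CanonicalMolecule
setClass("CanonicalMolecule",
         representation(smiles = "character",
                        heavyAtomCount = "integer",
                        ringCount = "integer",
                        graph = "list"))

setValidity("CanonicalMolecule", function(object) {
  msg <- character(0)
  if (length(object@smiles) != 1L || !nzchar(object@smiles))
    msg <- c(msg, "smiles must be a single non-empty string")
  if (object@heavyAtomCount < 1L) msg <- c(msg, "heavyAtomCount must be >= 1")
  if (object@ringCount < 0L) msg <- c(msg, "ringCount must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CanonicalMolecule", function(object) {
  cat("CanonicalMolecule:", object@smiles,
      sprintf("(%d heavy atoms, %d rings)\n",
              object@heavyAtomCount, object@ringCount))
})

#' A requested property change (conditioning triple)
#'
#' The three discrete tokens describing the desired shift between a
#' starting and a generated molecule: a binned logD change plus
#' categorical solubility and clearance moves.
#'
#' @slot logd logD-change interval token, e.g. `"LogD_change_(-0.1, 0.1]"`.
#' @slot solubility one of `"Solubility_low->high"`, `"Solubility_high->low"`,
#'   `"Solubility_no_change"`.
#' @slot clearance the analogous clearance token.
#' @exportClass PropertyChange
setClass("PropertyChange",
         representation(logd = "character",
                        solubility = "character",
                        clearance = "character"))

setValidity("PropertyChange", function(object) {
  msg <- character(0)
  if (!grepl("^LogD_change_\\(", object@logd))
    msg <- c(msg, "malformed logd token")
  if (!object@solubility %in% paste0("Solubility_",
                                     c("low->high", "high->low", "no_change")))
    msg <- c(msg, "malformed solubility token")
  if (!object@clearance %in% paste0("Clearance_",
                                    c("low->high", "high->low", "no_change")))
    msg <- c(msg, "malformed clearance token")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PropertyChange", function(object) {
  cat("PropertyChange:", object@logd, "|", object@solubility, "|",
      object@clearance, "\n")
})

#' A mined molecular-pair dataset with year-based splits
#'
#' Ordered (source, target) molecule pairs mined under one pairing
#' criterion, annotated with property-change tokens and split by
#' publication year into training (2000-2017), validation (2018) and
#' test (2019-2020) sets. Build with [extractPairs()].
#'
#' @slot criterion one of `pairCriteria()`.
#' @slot pairs data.frame with columns `source_smiles`, `target_smiles`,
#'   `logd_change_token`, `solubility_token`, `clearance_token`,
#'   `criterion`, `year`, `split`.
#' @exportClass PairDataset
setClass("PairDataset",
         representation(criterion = "character", pairs = "data.frame"))

setValidity("PairDataset", function(object) {
  msg <- character(0)
  need <- c("source_smiles", "target_smiles", "logd_change_token",
            "solubility_token", "clearance_token", "criterion", "year",
            "split")
  if (!all(need %in% names(object@pairs)))
    msg <- c(msg, "pairs is missing required columns")
  if (!object@criterion %in% pairCriteria())
    msg <- c(msg, "unknown criterion")
  if (nrow(object@pairs) > 0L) {
    if (!all(object@pairs$split %in% c("train", "valid", "test")))
      msg <- c(msg, "split must be train/valid/test")
    yr <- object@pairs$year
    sp <- object@pairs$split
    if (any(sp == "train" & (yr < 2000 | yr > 2017)) ||
        any(sp == "valid" & yr != 2018) ||
        any(sp == "test" & (yr < 2019 | yr > 2020)))
      msg <- c(msg, "split years violate the 2000-2017/2018/2019-2020 scheme")
    if (any(object@pairs$source_smiles == object@pairs$target_smiles))
      msg <- c(msg, "source and target must differ")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairDataset", function(object) {
  tab <- table(factor(object@pairs$split,
                      levels = c("train", "valid", "test")))
  cat(sprintf("PairDataset [%s]: %d pairs (train %d / valid %d / test %d)\n",
              object@criterion, nrow(object@pairs),
              tab[["train"]], tab[["valid"]], tab[["test"]]))
})

#' Token vocabulary for the sequence model
#'
#' Bijective token-to-index map over all SMILES and property-change tokens
#' observed in one pair dataset, plus the four special tokens
#' (`<pad>`, `<start>`, `<end>`, `<unk>` at indices 1-4).
#'
#' @slot tokens character vector; index of a token is its position.
#' @exportClass SmilesVocabulary
setClass("SmilesVocabulary", representation(tokens = "character"))

setValidity("SmilesVocabulary", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@tokens)) msg <- c(msg, "duplicate tokens")
  if (!identical(object@tokens[1:4], c("<pad>", "<start>", "<end>", "<unk>")))
    msg <- c(msg, "special tokens must occupy indices 1-4")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SmilesVocabulary", function(object) {
  cat(sprintf("SmilesVocabulary: %d tokens (incl. 4 specials)\n",
              length(object@tokens)))
})

#' A trained sequence-to-sequence transformer
#'
#' Encoder-decoder transformer over SMILES token sequences, optionally
#' conditioned on property-change tokens prepended to the source sequence.
#' Train with [trainTransformer()].
#'
#' @slot config model/training configuration list from [modelConfig()].
#' @slot vocab the [SmilesVocabulary-class] the model was trained with.
#' @slot conditional logical; `FALSE` for the unconditional variant that
#'   omits the property tokens from its inputs.
#' @slot params flat list of parameter matrices (best validation
#'   checkpoint).
#' @slot lossTrace data.frame of training/validation losses by step.
#' @slot criterion pairing criterion of the training dataset.
#' @slot ptr external pointer to the native model (rebuilt on demand).
#' @exportClass MolTransformer
setClass("MolTransformer",
         representation(config = "list", vocab = "SmilesVocabulary",
                        conditional = "logical", params = "list",
                        lossTrace = "data.frame", criterion = "character",
                        ptr = "ANY"))

setMethod("show", "MolTransformer", function(object) {
  cat(sprintf(paste0("MolTransformer (%s): %d layers, width %d, %d heads,",
                     " vocab %d\n"),
              if (object@conditional) "conditional" else "unconditional",
              object@config$numLayers, object@config$modelWidth,
              object@config$numHeads, length(object@vocab@tokens)))
  if (nrow(object@lossTrace) > 0L) {
    best <- min(object@lossTrace$valid_loss, na.rm = TRUE)
    cat(sprintf("  best validation loss: %.4f over %d steps\n", best,
                max(object@lossTrace$step)))
  }
})

#' Sampled molecules for one (start, constraint) input
#'
#' @slot start starting molecule SMILES (canonical).
#' @slot constraint the [PropertyChange-class] used as conditioning input.
#' @slot samples data.frame with columns `smiles` (raw sampled string),
#'   `canonical`, `valid` (parses and passes valence checks), `kept`
#'   (unique, valid and different from start).
#' @slot attempts number of sequences sampled.
#' @exportClass GenerationResult
setClass("GenerationResult",
         representation(start = "character", constraint = "PropertyChange",
                        samples = "data.frame", attempts = "integer"))

setMethod("show", "GenerationResult", function(object) {
  cat(sprintf("GenerationResult: %d kept / %d attempts for %s\n",
              sum(object@samples$kept), object@attempts, object@start))
})

#' Accessor: unique valid generated molecules
#'
#' @param result a [GenerationResult-class].
#' @return character vector of canonical SMILES, unique, valid and
#'   different from the starting molecule.
#' @export
uniqueValid <- function(result) {
  stopifnot(is(result, "GenerationResult"))
  result@samples$canonical[result@samples$kept]
}

#' Accessors for pair datasets
#'
#' @param dataset a [PairDataset-class].
#' @return data.frame of pairs in the requested split.
#' @export
trainPairs <- function(dataset) dataset@pairs[dataset@pairs$split == "train", , drop = FALSE]

#' @rdname trainPairs
#' @export
validPairs <- function(dataset) dataset@pairs[dataset@pairs$split == "valid", , drop = FALSE]

#' @rdname trainPairs
#' @export
testPairs <- function(dataset) dataset@pairs[dataset@pairs$split == "test", , drop = FALSE]

#' @rdname trainPairs
#' @export
pairCriterion <- function(dataset) dataset@criterion

#' The six supported pairing criteria
#'
#' `mmp` (single-transformation matched molecular pairs), `sim05`
#' (Tanimoto >= 0.5), `sim0507` (Tanimoto in [0.5, 0.7)), `sim07`
#' (Tanimoto >= 0.7), `scaffold` (identical Murcko scaffold) and
#' `scaffold_generic` (identical generic scaffold).
#'
#' @return character vector of criterion identifiers.
#' @export
pairCriteria <- function() {
  c("mmp", "sim05", "sim0507", "sim07", "scaffold", "scaffold_generic")
}
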