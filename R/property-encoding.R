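## Property-change token encoding and the synthetic property oracle.
##
## Three ADMET properties condition the generator: logD (octanol/water
## distribution coefficient at pH 7.4), aqueous solubility (log10 uM) and
## human liver microsome intrinsic clearance (log10 uL/min/mg). The logD
## change is binned into half-open intervals of width 0.2; solubility and
## clearance changes are encoded as categorical moves across fixed
## low/high thresholds (1.7 and 1.3 on the log10 scale).

.LOGD_EDGE <- 6.9
.LOGD_WIDTH <- 0.2
.SOL_THRESHOLD <- 1.7
.CLR_THRESHOLD <- 1.3

.fmtEdge <- function(v) {
  s <- sprintf("%.1f", v)
  if (s == "-0.0") s <- "0.0"
  s
}

#' Encode a logD change as an interval token
#'
#' The real line is tiled by left-open/right-closed bins of width 0.2
#' covering (-6.9, 6.9], with two open end bins `(-inf, -6.9]` and
#' `(6.9, inf]`; 71 tokens in total. A delta exactly on an edge belongs
#' to the bin whose right edge it is.
#'
#' @param delta finite numeric logD change (target minus source).
#' @return token string, e.g. `"LogD_change_(-0.1, 0.1]"`.
#' @export
encodeLogDChange <- function(delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L)
  if (!is.finite(delta)) stop("non-finite logD change")
  nb <- as.integer(round(2 * .LOGD_EDGE / .LOGD_WIDTH))  # bounded bins
  ## bin k (1..nb) covers (-edge + (k-1)*w, -edge + k*w]; epsilon absorbs
  ## float error so exact edges land in the lower-labelled bin
  k <- ceiling((delta + .LOGD_EDGE) / .LOGD_WIDTH - 1e-9)
  if (k <= 0L) return(sprintf("LogD_change_(-inf, -%s]", .fmtEdge(.LOGD_EDGE)))
  if (k > nb) return(sprintf("LogD_change_(%s, inf]", .fmtEdge(.LOGD_EDGE)))
  lo <- -.LOGD_EDGE + (k - 1) * .LOGD_WIDTH
  hi <- lo + .LOGD_WIDTH
  sprintf("LogD_change_(%s, %s]", .fmtEdge(lo), .fmtEdge(hi))
}

#' All logD-change tokens the encoder can emit
#'
#' @return character vector of the 71 tokens, ordered from the low open
#'   bin to the high open bin.
#' @export
logDChangeTokens <- function() {
  nb <- as.integer(round(2 * .LOGD_EDGE / .LOGD_WIDTH))
  mids <- -.LOGD_EDGE + (seq_len(nb) - 0.5) * .LOGD_WIDTH
  c(sprintf("LogD_change_(-inf, -%s]", .fmtEdge(.LOGD_EDGE)),
    vapply(mids, encodeLogDChange, character(1)),
    sprintf("LogD_change_(%s, inf]", .fmtEdge(.LOGD_EDGE)))
}

## midpoint of a logD-change token's bin; open bins use edge +/- 0.1
.logDBinMidpoint <- function(token) {
  body <- sub("^LogD_change_\\(", "", sub("\\]$", "", token))
  parts <- strsplit(body, ", ", fixed = TRUE)[[1]]
  if (parts[1] == "-inf") return(-(.LOGD_EDGE + 0.1))
  if (parts[2] == "inf") return(.LOGD_EDGE + 0.1)
  (as.numeric(parts[1]) + as.numeric(parts[2])) / 2
}

#' Categorize a solubility or clearance value
#'
#' `"low"` when the value is at or below the threshold (1.7 for
#' solubility, 1.3 for clearance, both log10 scale), `"high"` otherwise.
#'
#' @param propertyName `"solubility"` or `"clearance"`.
#' @param value numeric value on the log10 scale.
#' @return `"low"` or `"high"`.
#' @export
categorizeProperty <- function(propertyName, value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  thr <- switch(propertyName,
                solubility = .SOL_THRESHOLD,
                clearance = .CLR_THRESHOLD,
                stop("unknown property: ", propertyName))
  if (value <= thr) "low" else "high"
}

#' Encode a categorical property change
#'
#' @param propertyName `"solubility"` or `"clearance"`.
#' @param src,tgt numeric source/target values (log10 scale).
#' @return token, e.g. `"Solubility_low->high"` or `"Clearance_no_change"`.
#' @export
encodeCategoryChange <- function(propertyName, src, tgt) {
  cs <- categorizeProperty(propertyName, src)
  ct <- categorizeProperty(propertyName, tgt)
  prefix <- switch(propertyName, solubility = "Solubility",
                   clearance = "Clearance")
  if (cs == ct) return(paste0(prefix, "_no_change"))
  paste0(prefix, "_", cs, "->", ct)
}

#' Assemble the conditioning triple between two property profiles
#'
#' @param src,tgt named lists or vectors with elements `logd`,
#'   `solubility`, `clearance` (log10 scale where applicable).
#' @return a [PropertyChange-class].
#' @export
propertyChange <- function(src, tgt) {
  src <- as.list(src); tgt <- as.list(tgt)
  new("PropertyChange",
      logd = encodeLogDChange(tgt$logd - src$logd),
      solubility = encodeCategoryChange("solubility", src$solubility,
                                        tgt$solubility),
      clearance = encodeCategoryChange("clearance", src$clearance,
                                       tgt$clearance))
}

#' Invert a property change
#'
#' Maps the change (X -> Y) to the change (Y -> X): the logD bin of
#' delta becomes the bin of -delta, `low->high` becomes `high->low`
#' and `no_change` stays.
#'
#' @param change a [PropertyChange-class].
#' @return a [PropertyChange-class].
#' @export
invertPropertyChange <- function(change) {
  stopifnot(is(change, "PropertyChange"))
  new("PropertyChange",
      logd = .invertLogDToken(change@logd),
      solubility = .invertCategoryToken(change@solubility),
      clearance = .invertCategoryToken(change@clearance))
}

.invertLogDToken <- function(token) {
  body <- sub("^LogD_change_\\(", "", sub("\\]$", "", token))
  parts <- strsplit(body, ", ", fixed = TRUE)[[1]]
  if (parts[1] == "-inf")
    return(sprintf("LogD_change_(%s, inf]", .fmtEdge(.LOGD_EDGE)))
  if (parts[2] == "inf")
    return(sprintf("LogD_change_(-inf, -%s]", .fmtEdge(.LOGD_EDGE)))
  lo <- as.numeric(parts[1]); hi <- as.numeric(parts[2])
  ## mirrored bin keeps closed-right convention: -(a,b] = [-b,-a) -> the
  ## bin labelled (-b-w, -a+...]; with symmetric tiling this is (-hi, -lo]
  sprintf("LogD_change_(%s, %s]", .fmtEdge(-hi), .fmtEdge(-lo))
}

.invertCategoryToken <- function(token) {
  if (grepl("_no_change$", token)) return(token)
  prefix <- sub("_(low|high)->.*$", "", token)
  if (grepl("low->high", token, fixed = TRUE))
    paste0(prefix, "_high->low") else paste0(prefix, "_low->high")
}

#' Property tokens in model-input order
#'
#' @param change a [PropertyChange-class].
#' @return character vector (logD, solubility, clearance).
#' @export
propertyTokens <- function(change) {
  c(change@logd, change@solubility, change@clearance)
}

# ---------------------------------------------------------------------------
# synthetic property oracle

## descriptor weights of the deterministic oracle (see the methods
## vignette for rationale); exposed via syntheticOracleWeights()
.ORACLE_W <- list(
  logd = c(intercept = -1.6, carbon = 0.32, halogen = 0.70,
           nitrogen = -0.85, oxygen = -0.95, ring = 0.25),
  solubility = c(intercept = 3.05, logd = -0.82, oxygen = 0.10),
  clearance = c(intercept = -0.15, carbon = 0.11, halogen = 0.38,
                nitrogen = -0.42, oxygen = -0.12, ring = 0.22))

#' Weights of the synthetic property oracle
#' @return named list of per-property descriptor weights.
#' @export
syntheticOracleWeights <- function() .ORACLE_W

#' Deterministic synthetic property oracle
#'
#' Pseudo-properties computed from cheap structural descriptors: the
#' pseudo-logD increases with carbon and halogen counts and decreases
#' with polar-atom (N, O) counts; pseudo-solubility is anti-correlated
#' with pseudo-logD; pseudo-clearance is driven by a distinct descriptor
#' combination. Scaled so that synthetic corpora populate both sides of
#' the 1.7 (solubility) and 1.3 (clearance) category thresholds. The
#' oracle is a stand-in for a trained property predictor; any function
#' mapping a molecule to such a profile can replace it throughout the
#' package.
#'
#' @param x a SMILES string or [CanonicalMolecule-class].
#' @return named list with `logd`, `solubility`, `clearance`.
#' @export
syntheticOracle <- function(x) {
  mol <- .asMolecule(x)
  g <- mol@graph
  d <- c(carbon = sum(g$elem == "C"),
         halogen = sum(g$elem %in% c("F", "Cl", "Br", "I")),
         nitrogen = sum(g$elem == "N"),
         oxygen = sum(g$elem == "O"),
         ring = as.numeric(mol@ringCount))
  w <- .ORACLE_W
  logd <- w$logd[["intercept"]] +
    sum(w$logd[names(d)] * d)
  sol <- w$solubility[["intercept"]] + w$solubility[["logd"]] * logd +
    w$solubility[["oxygen"]] * d[["oxygen"]]
  clr <- w$clearance[["intercept"]] +
    sum(w$clearance[c("carbon", "halogen", "nitrogen", "oxygen", "ring")] *
          d[c("carbon", "halogen", "nitrogen", "oxygen", "ring")])
  list(logd = unname(logd), solubility = unname(sol), clearance = unname(clr))
}

## profile of a corpus row (list with logd/solubility/clearance columns)
.profileOfRow <- function(df, i) {
  list(logd = df$logd[i], solubility = df$solubility[i],
       clearance = df$clearance[i])
}
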