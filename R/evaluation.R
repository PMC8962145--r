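## Evaluation framework: error-adjusted property-constraint success,
## criterion-specific structure-constraint success, combined metrics,
## the random baseline, cross-constraint analytics and similarity
## distributions.

#' Error-adjusted acceptance bands for property success
#'
#' The property-success classifier widens each categorical threshold by
#' the property predictor's error: a generated molecule passes a "low"
#' solubility target up to `solubilityThreshold + solubilityError`
#' (default 1.7 + 0.6 = 2.3) and a "high" target down to 1.7 - 0.6 =
#' 1.1; clearance analogously with 1.3 +/- 0.35. The logD target is
#' passed within an absolute tolerance (default 0.4).
#'
#' @param logdTolerance absolute logD tolerance.
#' @param solubilityThreshold,solubilityError solubility low/high
#'   threshold and error margin (log10 uM).
#' @param clearanceThreshold,clearanceError clearance analogues
#'   (log10 uL/min/mg).
#' @return list of bands used by [propertySuccess()].
#' @export
errorBands <- function(logdTolerance = 0.4, solubilityThreshold = 1.7,
                       solubilityError = 0.6, clearanceThreshold = 1.3,
                       clearanceError = 0.35) {
  ## rounded to well below the assay scale so the printed boundaries
  ## (2.3, 1.1, 1.65, 0.95) hold exactly despite binary float error
  list(logd_tolerance = logdTolerance,
       solubility = round(c(low_max = solubilityThreshold + solubilityError,
                            high_min = solubilityThreshold - solubilityError),
                          10),
       clearance = round(c(low_max = clearanceThreshold + clearanceError,
                           high_min = clearanceThreshold - clearanceError),
                         10))
}

#' Point target spec implied by a start profile and a requested change
#'
#' The logD target is the start value plus the midpoint of the requested
#' logD-change bin (open bins use their finite edge +/- 0.1); the
#' solubility/clearance targets are the categories after applying the
#' requested categorical move to the start categories.
#'
#' @param startProfile list with `logd`, `solubility`, `clearance`.
#' @param change a [PropertyChange-class].
#' @return list with `logd` (numeric target), `solubility`, `clearance`
#'   (target categories `"low"`/`"high"`).
#' @export
targetSpecFromChange <- function(startProfile, change) {
  stopifnot(is(change, "PropertyChange"))
  applyMove <- function(token, startCat) {
    if (grepl("no_change", token)) startCat
    else if (grepl("low->high", token, fixed = TRUE)) "high"
    else "low"
  }
  list(logd = startProfile$logd + .logDBinMidpoint(change@logd),
       solubility = applyMove(change@solubility,
                              categorizeProperty("solubility",
                                                 startProfile$solubility)),
       clearance = applyMove(change@clearance,
                             categorizeProperty("clearance",
                                                startProfile$clearance)))
}

#' Does a generated molecule satisfy the property constraints?
#'
#' logD passes iff `|generated - target| <= logd_tolerance`; a "low"
#' solubility target passes iff the value is at most `low_max` and a
#' "high" target iff at least `high_min`; clearance analogously.
#' Overall success requires all three simultaneously.
#'
#' @param generatedProfile list with `logd`, `solubility`, `clearance`.
#' @param targetSpec from [targetSpecFromChange()].
#' @param bands from [errorBands()].
#' @return list with `overall` and per-property logical flags.
#' @export
propertySuccess <- function(generatedProfile, targetSpec,
                            bands = errorBands()) {
  for (p in c("logd", "solubility", "clearance"))
    if (is.null(generatedProfile[[p]]) || !is.finite(generatedProfile[[p]]))
      stop("missing property in generated profile: ", p)
  logdOk <- abs(generatedProfile$logd - targetSpec$logd) <=
    bands$logd_tolerance
  catOk <- function(value, target, band) {
    if (target == "low") value <= band[["low_max"]]
    else value >= band[["high_min"]]
  }
  solOk <- catOk(generatedProfile$solubility, targetSpec$solubility,
                 bands$solubility)
  clrOk <- catOk(generatedProfile$clearance, targetSpec$clearance,
                 bands$clearance)
  list(overall = logdOk && solOk && clrOk, logd = logdOk,
       solubility = solOk, clearance = clrOk)
}

#' Does a generated molecule satisfy the structure constraint?
#'
#' `mmp`: matched molecular pair with the start; `sim05`: Tanimoto in
#' [0.5, 1.0); `sim0507`: [0.5, 0.7); `sim07`: [0.7, 1.0); `scaffold` /
#' `scaffold_generic`: identical (generic) scaffold string. Similarity
#' 1.0 is excluded since generated molecules must differ from the start.
#' An invalid generated molecule returns FALSE rather than an error.
#'
#' @param start starting molecule SMILES.
#' @param generated generated molecule SMILES.
#' @param criterion one of [pairCriteria()].
#' @return logical.
#' @export
structureSuccess <- function(start, generated, criterion) {
  criterion <- .normalizeCriterion(criterion)
  ok <- tryCatch({
    if (!validSmiles(generated)) return(FALSE)
    switch(criterion,
           mmp = isMmp(start, generated),
           sim05 = {
             t <- tanimotoSimilarity(start, generated)
             t >= 0.5 && t < 1.0
           },
           sim0507 = {
             t <- tanimotoSimilarity(start, generated)
             t >= 0.5 && t < 0.7
           },
           sim07 = {
             t <- tanimotoSimilarity(start, generated)
             t >= 0.7 && t < 1.0
           },
           scaffold = {
             .asMolecule(generated)@ringCount > 0L &&
               murckoScaffold(start) == murckoScaffold(generated)
           },
           scaffold_generic = {
             .asMolecule(generated)@ringCount > 0L &&
               genericScaffold(start) == genericScaffold(generated)
           })
  }, error = function(e) FALSE)
  isTRUE(ok)
}

#' Evaluate a set of generation results
#'
#' Percentages of generated molecules fulfilling the property
#' constraints, the structure constraint, and both simultaneously, over
#' all kept molecules of all results, plus a per-molecule breakdown.
#'
#' @param results list of [GenerationResult-class].
#' @param criterion structure criterion of the training dataset.
#' @param bands from [errorBands()].
#' @param oracle property oracle for generated molecules.
#' @return list with `property_pct`, `structure_pct`, `combined_pct`,
#'   `n_generated` and `breakdown` (data.frame).
#' @export
evaluateRun <- function(results, criterion, bands = errorBands(),
                        oracle = syntheticOracle) {
  criterion <- .normalizeCriterion(criterion)
  rows <- list()
  for (res in results) {
    gen <- uniqueValid(res)
    if (length(gen) == 0L) next
    startProf <- oracle(res@start)
    spec <- targetSpecFromChange(startProf, res@constraint)
    for (g in gen) {
      ps <- propertySuccess(oracle(g), spec, bands)
      ss <- structureSuccess(res@start, g, criterion)
      rows[[length(rows) + 1]] <- data.frame(
        start = res@start, generated = g, property = ps$overall,
        structure = ss, combined = ps$overall && ss,
        logd_ok = ps$logd, solubility_ok = ps$solubility,
        clearance_ok = ps$clearance, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no generated molecules to evaluate")
  bd <- do.call(rbind, rows)
  list(property_pct = 100 * mean(bd$property),
       structure_pct = 100 * mean(bd$structure),
       combined_pct = 100 * mean(bd$combined),
       n_generated = nrow(bd), breakdown = bd)
}

#' Random baseline over the test split
#'
#' For a random fraction of test inputs, draws `n` molecules from the
#' unique test-set pool restricted to those satisfying the structure
#' constraint with the start (so structure success is 100% by
#' construction) and measures property success; repeated with different
#' sampling seeds and averaged.
#'
#' @param dataset a [PairDataset-class].
#' @param bands from [errorBands()].
#' @param oracle property oracle.
#' @param fraction fraction of test inputs evaluated per repeat.
#' @param repeats number of repeats.
#' @param n molecules drawn per input.
#' @param seed base seed; repeat r uses `seed + r`.
#' @return list with `property_pct` (mean), `property_sd`,
#'   `structure_pct` (always 100), `per_repeat`, and `short_records`
#'   (inputs with fewer than `n` structure-satisfying pool molecules).
#' @export
randomBaseline <- function(dataset, bands = errorBands(),
                           oracle = syntheticOracle, fraction = 0.01,
                           repeats = 5L, n = 10L, seed = 1L) {
  test <- testPairs(dataset)
  if (nrow(test) == 0L) stop("dataset has no test split")
  criterion <- dataset@criterion
  pool <- unique(c(test$source_smiles, test$target_smiles))
  .precacheMolecules(pool)
  ## precomputed scaffold strings make the structure screen a vector
  ## comparison for the scaffold criteria (same candidate sets as the
  ## generic per-molecule path)
  poolScaf <- if (criterion %in% c("scaffold", "scaffold_generic")) {
    fn <- if (criterion == "scaffold") murckoScaffold else genericScaffold
    vapply(pool, function(s) tryCatch(fn(s), error = function(e)
      NA_character_), character(1), USE.NAMES = FALSE)
  } else NULL
  candidatesFor <- function(start) {
    if (!is.null(poolScaf)) {
      fn <- if (criterion == "scaffold") murckoScaffold else genericScaffold
      ss <- tryCatch(fn(start), error = function(e) NA_character_)
      keep <- !is.na(poolScaf) & poolScaf == ss & pool != start
      pool[keep]
    } else {
      cand <- pool[pool != start]
      cand[vapply(cand, function(m)
        structureSuccess(start, m, criterion), logical(1))]
    }
  }
  perRepeat <- numeric(repeats)
  short <- 0L
  for (r in seq_len(repeats)) {
    flags <- logical(0)
    .withSeed(seed + r, {
      nPick <- max(1L, round(fraction * nrow(test)))
      picks <- sample.int(nrow(test), nPick)
      for (i in picks) {
        start <- test$source_smiles[i]
        change <- .changeFromRow(test, i)
        spec <- targetSpecFromChange(oracle(start), change)
        cand <- candidatesFor(start)
        if (length(cand) == 0L) { short <- short + 1L; next }
        if (length(cand) < n) short <- short + 1L
        draw <- if (length(cand) <= n) cand else sample(cand, n)
        flags <- c(flags, vapply(draw, function(m)
          propertySuccess(oracle(m), spec, bands)$overall, logical(1)))
      }
    })
    perRepeat[r] <- if (length(flags) > 0L) 100 * mean(flags) else NA_real_
  }
  list(property_pct = mean(perRepeat, na.rm = TRUE),
       property_sd = sd(perRepeat, na.rm = TRUE),
       structure_pct = 100, per_repeat = perRepeat,
       short_records = short)
}

#' Cross-constraint heatmap
#'
#' Given, per training criterion, the (start, generated) pairs that
#' fulfilled both the property and the structure constraints of that
#' criterion, computes for every column criterion the fraction that
#' also satisfies the column's structure constraint. The diagonal is 1
#' by construction; containment relations (e.g. every shared-scaffold
#' pair also shares the generic scaffold) force further columns to 1.
#'
#' @param resultsByCriterion named list (names from [pairCriteria()]) of
#'   data.frames with columns `start` and `generated`.
#' @return numeric matrix of fractions in [0, 1] (rows = training
#'   criterion, columns = structure constraint); rows with no results
#'   are `NA`.
#' @export
crossConstraintHeatmap <- function(resultsByCriterion) {
  rowsCr <- names(resultsByCriterion)
  stopifnot(!is.null(rowsCr), all(rowsCr %in% pairCriteria()))
  cols <- pairCriteria()
  out <- matrix(NA_real_, nrow = length(rowsCr), ncol = length(cols),
                dimnames = list(rowsCr, cols))
  for (r in rowsCr) {
    df <- resultsByCriterion[[r]]
    if (is.null(df) || nrow(df) == 0L) next
    for (cc in cols) {
      ok <- vapply(seq_len(nrow(df)), function(i)
        structureSuccess(df$start[i], df$generated[i], cc), logical(1))
      out[r, cc] <- mean(ok)
    }
  }
  out
}

#' Tanimoto similarity distribution
#'
#' Normalized histogram of Tanimoto similarities for one or more series
#' of molecule pairs (e.g. training pairs vs generated pairs split by
#' success category).
#'
#' @param pairsBySeries named list of data.frames with columns `a`, `b`
#'   (SMILES).
#' @param breaks histogram break points over [0, 1].
#' @return data.frame with columns `series`, `bin_low`, `bin_high`,
#'   `mass` (masses sum to 1 per series), plus the raw similarities as
#'   attribute `similarities`.
#' @export
similarityDistribution <- function(pairsBySeries,
                                   breaks = seq(0, 1, by = 0.05)) {
  stopifnot(is.list(pairsBySeries), !is.null(names(pairsBySeries)))
  out <- list()
  sims <- list()
  for (s in names(pairsBySeries)) {
    df <- pairsBySeries[[s]]
    if (nrow(df) == 0L) next
    t <- vapply(seq_len(nrow(df)), function(i)
      tanimotoSimilarity(df$a[i], df$b[i]), numeric(1))
    sims[[s]] <- t
    h <- hist(pmin(t, max(breaks) - 1e-9), breaks = breaks, plot = FALSE)
    out[[s]] <- data.frame(series = s, bin_low = head(breaks, -1),
                           bin_high = breaks[-1],
                           mass = h$counts / sum(h$counts))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "similarities") <- sims
  res
}

#' Pairs of a dataset split as a similarity series
#'
#' @param dataset a [PairDataset-class].
#' @param split `"train"`, `"valid"` or `"test"`.
#' @return data.frame with columns `a`, `b` for [similarityDistribution()].
#' @export
pairSeries <- function(dataset, split = "train") {
  df <- dataset@pairs[dataset@pairs$split == split, , drop = FALSE]
  data.frame(a = df$source_smiles, b = df$target_smiles,
             stringsAsFactors = FALSE)
}

#' @importFrom graphics hist lines legend
#' @param distribution output of [similarityDistribution()].
#' @param main plot title.
#' @rdname similarityDistribution
#' @export
plotSimilarityDistribution <- function(distribution,
                                       main = "Tanimoto similarity") {
  series <- unique(distribution$series)
  cols <- seq_along(series)
  plot(NULL, xlim = c(0, 1), ylim = c(0, max(distribution$mass)),
       xlab = "Tanimoto similarity", ylab = "mass", main = main)
  for (k in seq_along(series)) {
    d <- distribution[distribution$series == series[k], ]
    lines((d$bin_low + d$bin_high) / 2, d$mass, type = "b", col = cols[k],
          pch = 16)
  }
  legend("topleft", legend = series, col = cols, lty = 1, pch = 16,
         bty = "n")
  invisible(NULL)
}

#' Restrict test inputs to large requested property changes
#'
#' Keeps test pairs whose requested logD change exceeds 1 in magnitude
#' or whose solubility or clearance token is a category flip.
#'
#' @param dataset a [PairDataset-class].
#' @return a [PairDataset-class] with the filtered test split (train and
#'   validation splits unchanged).
#' @export
largeChangeSubset <- function(dataset) {
  p <- dataset@pairs
  isTest <- p$split == "test"
  mid <- vapply(p$logd_change_token, .logDBinMidpoint, numeric(1))
  big <- abs(mid) > 1 |
    grepl("->", p$solubility_token, fixed = TRUE) |
    grepl("->", p$clearance_token, fixed = TRUE)
  new("PairDataset", criterion = dataset@criterion,
      pairs = p[!isTest | big, , drop = FALSE])
}
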