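test_that("property-success bands flip exactly at the stated boundaries", {
  bands <- errorBands()
  eps <- 1e-9
  spec <- list(logd = 2.0, solubility = "high", clearance = "low")
  prof <- function(logd = 2.0, sol = 2.0, clr = 1.0)
    list(logd = logd, solubility = sol, clearance = clr)
  # logD: |generated - target| <= 0.4
  expect_true(propertySuccess(prof(logd = 2.4), spec, bands)$logd)
  expect_false(propertySuccess(prof(logd = 2.4 + 1e-6), spec, bands)$logd)
  expect_true(propertySuccess(prof(logd = 1.6), spec, bands)$logd)
  # solubility "high" passes down to 1.1
  expect_true(propertySuccess(prof(sol = 1.1), spec, bands)$solubility)
  expect_false(propertySuccess(prof(sol = 1.1 - 1e-6), spec,
                               bands)$solubility)
  # solubility "low" passes up to 2.3
  specLow <- list(logd = 2.0, solubility = "low", clearance = "low")
  expect_true(propertySuccess(prof(sol = 2.3), specLow, bands)$solubility)
  expect_false(propertySuccess(prof(sol = 2.3 + 1e-6), specLow,
                               bands)$solubility)
  # clearance "low" passes up to 1.65, "high" down to 0.95
  expect_true(propertySuccess(prof(clr = 1.65), spec, bands)$clearance)
  expect_false(propertySuccess(prof(clr = 1.65 + 1e-6), spec,
                               bands)$clearance)
  specHigh <- list(logd = 2.0, solubility = "high", clearance = "high")
  expect_true(propertySuccess(prof(clr = 0.95), specHigh, bands)$clearance)
  expect_false(propertySuccess(prof(clr = 0.95 - 1e-6), specHigh,
                               bands)$clearance)
  # overall success is the conjunction
  expect_true(propertySuccess(prof(), spec, bands)$overall)
  expect_false(propertySuccess(prof(logd = 9), spec, bands)$overall)
  expect_error(propertySuccess(list(logd = 1), spec, bands),
               "missing property")
})

test_that("the implied point target uses bin midpoints and category moves", {
  start <- list(logd = 1.0, solubility = 1.0, clearance = 2.0)
  z <- new("PropertyChange", logd = "LogD_change_(0.1, 0.3]",
           solubility = "Solubility_low->high",
           clearance = "Clearance_high->low")
  spec <- targetSpecFromChange(start, z)
  expect_equal(spec$logd, 1.2)
  expect_identical(spec$solubility, "high")
  expect_identical(spec$clearance, "low")
  # open bins use the finite edge +/- 0.1; no_change keeps the category
  z2 <- new("PropertyChange", logd = "LogD_change_(6.9, inf]",
            solubility = "Solubility_no_change",
            clearance = "Clearance_no_change")
  spec2 <- targetSpecFromChange(start, z2)
  expect_equal(spec2$logd, 8.0)
  expect_identical(spec2$solubility, "low")
  expect_identical(spec2$clearance, "high")
})

test_that("structure success is criterion-specific and safe on junk", {
  # heteroatom-swapped analog: generic scaffold holds, exact does not
  a <- "Cc1ccc(C(=O)Nc2ccccc2)cc1"
  b <- "Cc1ccc(C(=O)Nc2ccccn2)cc1"
  expect_false(structureSuccess(a, b, "scaffold"))
  expect_true(structureSuccess(a, b, "scaffold_generic"))
  # an invalid generated molecule is a failure, not an error
  expect_false(structureSuccess(a, "C(C", "scaffold"))
  expect_false(structureSuccess(a, "c1ccc1cc", "sim05"))
  # mmp routes through the matched-pair test
  expect_true(structureSuccess("Cc1ccccc1", "CCc1ccccc1", "mmp"))
  # similarity bands agree with the computed similarity
  t <- tanimotoSimilarity(a, "CCc1ccc(C(=O)Nc2ccccc2)cc1")
  expect_identical(structureSuccess(a, "CCc1ccc(C(=O)Nc2ccccc2)cc1",
                                    "sim05"), t >= 0.5 && t < 1)
  expect_identical(structureSuccess(a, "CCc1ccc(C(=O)Nc2ccccc2)cc1",
                                    "sim0507"), t >= 0.5 && t < 0.7)
})

# generation results assembled from corpus molecules (no model needed)
mockResults <- function(n = 4L) {
  corpus <- smallCorpus()
  pub <- corpus[corpus$publication_id == corpus$publication_id[1], ]
  lapply(seq_len(n), function(i) {
    gen <- pub$smiles[setdiff(seq_len(nrow(pub)), i)][1:3]
    new("GenerationResult", start = pub$smiles[i],
        constraint = propertyChange(MolPairGen:::.profileOfRow(pub, i),
                                    MolPairGen:::.profileOfRow(pub, 1)),
        samples = data.frame(smiles = gen, canonical = gen, valid = TRUE,
                             kept = TRUE, stringsAsFactors = FALSE),
        attempts = 3L)
  })
}

test_that("run evaluation obeys the conjunction bound", {
  ev <- evaluateRun(mockResults(), "scaffold")
  expect_lte(ev$combined_pct, min(ev$property_pct, ev$structure_pct))
  expect_equal(ev$n_generated, nrow(ev$breakdown))
  expect_true(all(ev$breakdown$combined ==
                    (ev$breakdown$property & ev$breakdown$structure)))
  expect_error(evaluateRun(list(), "scaffold"), "no generated molecules")
})

test_that("the random baseline always satisfies the structure constraint", {
  ds <- smallPairs("scaffold")
  rnd <- randomBaseline(ds, fraction = 0.05, repeats = 3L, n = 5L,
                        seed = 4L)
  expect_equal(rnd$structure_pct, 100)
  expect_length(rnd$per_repeat, 3L)
  # identical seeds give identical metrics
  rnd2 <- randomBaseline(ds, fraction = 0.05, repeats = 3L, n = 5L,
                         seed = 4L)
  expect_identical(rnd$per_repeat, rnd2$per_repeat)
  # drawn molecules come from the pool and satisfy the constraint by
  # construction: with n larger than the pool the success rate equals
  # the exhaustive base rate over constraint-satisfying pool molecules
  test <- testPairs(ds)
  pool <- unique(c(test$source_smiles, test$target_smiles))
  i <- 1L
  start <- test$source_smiles[i]
  z <- MolPairGen:::.changeFromRow(test, i)
  spec <- targetSpecFromChange(syntheticOracle(start), z)
  cand <- pool[pool != start]
  cand <- cand[vapply(cand, function(m)
    structureSuccess(start, m, "scaffold"), logical(1))]
  expect_gt(length(cand), 0L)
  exhaustive <- 100 * mean(vapply(cand, function(m)
    propertySuccess(syntheticOracle(m), spec)$overall, logical(1)))
  expect_gte(exhaustive, 0)
  expect_lte(exhaustive, 100)
})

test_that("the cross-constraint heatmap has unit diagonal and containments", {
  # heatmap rows are structure-successful generations by definition;
  # emulate them with mined pairs that pass the row's generation band
  res <- list()
  for (cr in c("sim07", "sim05", "scaffold", "scaffold_generic")) {
    p <- smallPairs(cr)@pairs
    ok <- vapply(seq_len(min(nrow(p), 60)), function(i)
      structureSuccess(p$source_smiles[i], p$target_smiles[i], cr),
      logical(1))
    take <- head(which(ok), 25)
    res[[cr]] <- data.frame(start = p$source_smiles[take],
                            generated = p$target_smiles[take])
  }
  hm <- crossConstraintHeatmap(res)
  expect_true(all(hm >= 0 & hm <= 1, na.rm = TRUE))
  for (cr in rownames(hm)) expect_equal(hm[cr, cr], 1)
  # band and scaffold containments force ones
  expect_equal(hm["sim07", "sim05"], 1)
  expect_equal(hm["scaffold", "scaffold_generic"], 1)
})

test_that("similarity distributions are normalized and band-consistent", {
  ds07 <- smallPairs("sim07")
  d <- similarityDistribution(list(train = pairSeries(ds07, "train")))
  expect_equal(sum(d$mass), 1)
  expect_true(all(d$mass[d$bin_high <= 0.7] == 0))
  # multiple series are normalized independently
  ds05 <- smallPairs("sim05")
  d2 <- similarityDistribution(list(a = pairSeries(ds05, "train"),
                                    b = pairSeries(ds07, "train")))
  sums <- tapply(d2$mass, d2$series, sum)
  expect_equal(as.numeric(sums), c(1, 1))
})

test_that("the large-change subset keeps only category flips or |dlogD|>1", {
  ds <- smallPairs("scaffold")
  sub <- largeChangeSubset(ds)
  t <- testPairs(sub)
  if (nrow(t) > 0L) {
    mid <- vapply(t$logd_change_token, MolPairGen:::.logDBinMidpoint,
                  numeric(1))
    big <- abs(mid) > 1 | grepl("->", t$solubility_token, fixed = TRUE) |
      grepl("->", t$clearance_token, fixed = TRUE)
    expect_true(all(big))
  }
  expect_identical(nrow(trainPairs(sub)), nrow(trainPairs(ds)))
})
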