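# A tiny dataset for fast training tests: one publication of close
# analogs, pairs under the scaffold criterion.
tinyDataset <- function() {
  if (is.null(.testCache$tinyDs)) {
    corpus <- smallCorpus()
    pubs <- unique(corpus$publication_id)[1:3]
    .testCache$tinyDs <- extractPairs(
      corpus[corpus$publication_id %in% pubs, ], "scaffold")
  }
  .testCache$tinyDs
}

tinyConfig <- function(seed = 1L) {
  modelConfig(numLayers = 1L, modelWidth = 32L, feedforwardWidth = 64L,
              numHeads = 2L, dropout = 0.1, maxSequenceLength = 64L,
              batchSize = 16L, warmupSteps = 100L, seed = seed)
}

test_that("analytic gradients match finite differences", {
  p <- MolPairGen:::.tfCreate(10L, 12L, 2L, 1L, 24L, 16L, 0.0, 3L)
  src <- rbind(c(1L, 4L, 5L, 6L, 2L), c(1L, 7L, 8L, 2L, 0L))
  tin <- rbind(c(1L, 5L, 6L, 2L, 0L), c(1L, 8L, 9L, 2L, 0L))
  tou <- rbind(c(5L, 6L, 2L, 0L, 0L), c(8L, 9L, 2L, 0L, 0L))
  g <- MolPairGen:::.tfGradients(p, src, tin, tou)
  set.seed(4)
  npar <- MolPairGen:::.tfParamCount(p)
  eps <- 1e-5
  for (k in 1:40) {
    pi <- sample(npar, 1) - 1L
    gm <- g[[pi + 1]]
    ei <- sample(length(gm), 1) - 1L
    MolPairGen:::.tfNudgeParam(p, pi, ei, eps)
    lp <- MolPairGen:::.tfEvalLoss(p, src, tin, tou)
    MolPairGen:::.tfNudgeParam(p, pi, ei, -2 * eps)
    lm <- MolPairGen:::.tfEvalLoss(p, src, tin, tou)
    MolPairGen:::.tfNudgeParam(p, pi, ei, eps)
    num <- (lp - lm) / (2 * eps)
    ana <- gm[ei + 1]
    if (abs(num) + abs(ana) < 1e-10) next
    expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-4)
  }
})

test_that("the learning-rate schedule warms up linearly then decays", {
  w <- 400L; d <- 64L
  lrs <- noamLearningRate(1:2000, d, w)
  expect_equal(which.max(lrs), w)
  # linear before warmup
  expect_equal(lrs[100] / lrs[50], 2, tolerance = 1e-9)
  # inverse-square-root after
  expect_equal(lrs[1600] / lrs[400], (1600 / 400)^-0.5, tolerance = 1e-9)
})

test_that("a model learns to copy sequences almost perfectly", {
  set.seed(8)
  V <- 12L
  m <- MolPairGen:::.tfCreate(V, 32L, 4L, 2L, 64L, 16L, 0.0, 11L)
  mk <- function(n, len = 6) t(vapply(seq_len(n), function(i)
    sample(5:11, len, replace = TRUE), integer(len)))
  for (step in 1:300) {
    s <- mk(16)
    lr <- noamLearningRate(step, 32L, 100L)
    MolPairGen:::.tfTrainStep(m, cbind(1L, s, 2L), cbind(1L, s, 0L),
                              cbind(s, 2L, 0L), lr)
  }
  s <- mk(8)
  out <- MolPairGen:::.tfSample(m, cbind(1L, s, 2L), 10L, 1L, 2L, 5L, TRUE)
  acc <- mean(out[, 1:6] == s)
  expect_gte(acc, 0.95)
  # decoding terminates with <end> and emits nothing afterwards
  expect_true(all(out[, 7] == 2L))
  expect_true(all(out[, 8:10] == 0L))
})

test_that("training is reproducible under a fixed seed", {
  ds <- tinyDataset()
  m1 <- trainTransformer(ds, tinyConfig(5L), steps = 12L, evalEvery = 6L)
  m2 <- trainTransformer(ds, tinyConfig(5L), steps = 12L, evalEvery = 6L)
  expect_identical(m1@lossTrace$train_loss, m2@lossTrace$train_loss)
  m3 <- trainTransformer(ds, tinyConfig(6L), steps = 12L, evalEvery = 6L)
  expect_false(identical(m1@lossTrace$train_loss, m3@lossTrace$train_loss))
})

test_that("training rejects invalid configurations and inputs", {
  expect_error(modelConfig(modelWidth = 30L, numHeads = 4L))
  ds <- tinyDataset()
  cfg <- tinyConfig()
  cfg$maxSequenceLength <- 5L
  expect_error(trainTransformer(ds, cfg, steps = 2L), "truncation error")
})

sampModel <- function() {
  if (is.null(.testCache$sampModel)) {
    .testCache$sampModel <- trainTransformer(tinyDataset(), tinyConfig(),
                                             steps = 150L, evalEvery = 50L)
  }
  .testCache$sampModel
}

test_that("sampling returns unique valid molecules different from the start", {
  ds <- tinyDataset()
  model <- sampModel()
  tp <- trainPairs(ds)
  z <- MolPairGen:::.changeFromRow(tp, 1)
  r <- sampleMolecules(model, tp$source_smiles[1], z, nUnique = 5L,
                       maxAttempts = 40L, seed = 2L)
  kept <- uniqueValid(r)
  expect_lte(length(kept), 5L)
  expect_false(anyDuplicated(kept) > 0)
  startCan <- canonicalSmiles(tp$source_smiles[1])
  for (g in kept) {
    expect_true(validSmiles(g))
    expect_false(identical(g, startCan))
  }
  expect_lte(r@attempts, 40L)
  # same seed, same draw
  r2 <- sampleMolecules(model, tp$source_smiles[1], z, nUnique = 5L,
                        maxAttempts = 40L, seed = 2L)
  expect_identical(r2@samples$smiles, r@samples$smiles)
  # different seed, different draw (with overwhelming probability)
  r3 <- sampleMolecules(model, tp$source_smiles[1], z, nUnique = 5L,
                        maxAttempts = 40L, seed = 3L)
  expect_false(identical(r3@samples$smiles, r@samples$smiles))
})

test_that("the unconditional variant drops the property tokens", {
  ds <- tinyDataset()
  mu <- trainTransformer(ds, tinyConfig(), conditional = FALSE,
                         steps = 5L, evalEvery = 5L)
  expect_false(any(grepl("^LogD_change|^Solubility|^Clearance",
                         mu@vocab@tokens)))
  p <- trainPairs(ds)[1, ]
  z <- MolPairGen:::.changeFromRow(trainPairs(ds), 1)
  condLen <- length(assembleSource(z, p$source_smiles))
  uncondLen <- length(assembleSource(NULL, p$source_smiles))
  expect_equal(condLen - uncondLen, 3L)
})

test_that("models survive a save/load round trip", {
  model <- sampModel()
  path <- tempfile(fileext = ".rds")
  saveTransformer(model, path)
  m2 <- loadTransformer(path)
  tp <- trainPairs(tinyDataset())
  z <- MolPairGen:::.changeFromRow(tp, 1)
  r1 <- sampleMolecules(model, tp$source_smiles[1], z, nUnique = 3L,
                        maxAttempts = 16L, seed = 9L)
  r2 <- sampleMolecules(m2, tp$source_smiles[1], z, nUnique = 3L,
                        maxAttempts = 16L, seed = 9L)
  expect_identical(r1@samples$smiles, r2@samples$smiles)
})
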