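## Desk-scale benchmark: mine a synthetic-grammar pair dataset, train the
## conditional transformer and its unconditional counterpart, and compare
## them with the random baseline on held-out test inputs. Shared by the
## acceptance machinery and the vignette.

#' Configuration of the desk-scale benchmark
#'
#' Problem sizes chosen so the whole study (corpus, mining, two model
#' trainings, sampling, baseline) runs on a single CPU in minutes; see
#' the methods vignette for the reasoning behind each number.
#'
#' @param seed master seed; all stages derive their seeds from it.
#' @param criterion pairing criterion of the benchmark dataset.
#' @param nPublications synthetic corpus size.
#' @param steps training steps per model.
#' @param nTestInputs number of held-out test inputs evaluated.
#' @param nUnique unique valid molecules requested per input.
#' @param sampleSeeds sampling seeds averaged over.
#' @return list of benchmark settings.
#' @export
benchmarkConfig <- function(seed = 1L, criterion = "scaffold",
                            nPublications = 500L, steps = 1500L,
                            nTestInputs = 20L, nUnique = 10L,
                            sampleSeeds = c(1L, 2L, 3L)) {
  list(seed = as.integer(seed),
       criterion = .normalizeCriterion(criterion),
       fixture = fixtureConfig(nPublications = nPublications,
                               seed = as.integer(seed)),
       model = modelConfig(numLayers = 2L, modelWidth = 64L,
                           feedforwardWidth = 128L, numHeads = 4L,
                           dropout = 0.1, maxSequenceLength = 64L,
                           batchSize = 64L, warmupSteps = 400L,
                           seed = as.integer(seed)),
       steps = as.integer(steps), nTestInputs = as.integer(nTestInputs),
       nUnique = as.integer(nUnique),
       sampleSeeds = as.integer(sampleSeeds))
}

#' Build the benchmark pair dataset
#'
#' Corpus generation, molecule and publication filtering, pair mining.
#'
#' @param bench a [benchmarkConfig()].
#' @return list with `corpus` (filtered) and `dataset`
#'   ([PairDataset-class]).
#' @export
benchmarkDataset <- function(bench = benchmarkConfig()) {
  corpus <- generateCorpus(bench$fixture)
  corpus <- filterPublications(filterMolecules(corpus))
  list(corpus = corpus,
       dataset = extractPairs(corpus, bench$criterion))
}

#' Run the full benchmark
#'
#' Trains the conditional transformer and the unconditional variant on
#' the benchmark dataset, samples `nUnique` molecules per test input for
#' each sampling seed, evaluates property/structure/combined success,
#' and runs the random baseline.
#'
#' @param bench a [benchmarkConfig()].
#' @param verbose print progress.
#' @return list with per-model metrics (`transformer`, `transformer_u`,
#'   `random`), the seed-level table `per_seed`, the models and the
#'   dataset.
#' @export
runBenchmark <- function(bench = benchmarkConfig(), verbose = FALSE) {
  parts <- benchmarkDataset(bench)
  ds <- parts$dataset
  if (verbose)
    message(sprintf("benchmark dataset: %d train / %d valid / %d test",
                    nrow(trainPairs(ds)), nrow(validPairs(ds)),
                    nrow(testPairs(ds))))
  model <- trainTransformer(ds, bench$model, conditional = TRUE,
                            steps = bench$steps, evalEvery = 200L,
                            verbose = verbose)
  modelU <- trainTransformer(ds, bench$model, conditional = FALSE,
                             steps = bench$steps, evalEvery = 200L,
                             verbose = verbose)
  test <- testPairs(ds)
  .withSeed(bench$seed + 101L, {
    pick <- sample.int(nrow(test), min(bench$nTestInputs, nrow(test)))
  })
  inputs <- test[pick, , drop = FALSE]
  perSeed <- list()
  evalT <- list(); evalU <- list()
  for (s in bench$sampleSeeds) {
    resT <- .sampleInputs(model, inputs, bench$nUnique, s)
    resU <- .sampleInputs(modelU, inputs, bench$nUnique, s)
    eT <- evaluateRun(resT, bench$criterion)
    eU <- evaluateRun(resU, bench$criterion)
    evalT[[length(evalT) + 1]] <- eT
    evalU[[length(evalU) + 1]] <- eU
    perSeed[[length(perSeed) + 1]] <- data.frame(
      seed = s,
      transformer_property = eT$property_pct,
      transformer_structure = eT$structure_pct,
      transformer_combined = eT$combined_pct,
      transformer_u_property = eU$property_pct,
      transformer_u_structure = eU$structure_pct,
      transformer_u_combined = eU$combined_pct)
    if (verbose)
      message(sprintf("seed %d: T prop %.1f / TU prop %.1f", s,
                      eT$property_pct, eU$property_pct))
  }
  perSeed <- do.call(rbind, perSeed)
  rnd <- randomBaseline(ds, fraction = max(0.01, bench$nTestInputs /
                                             max(nrow(test), 1)),
                        repeats = 5L, n = bench$nUnique,
                        seed = bench$seed)
  list(transformer = list(property_pct = mean(perSeed$transformer_property),
                          structure_pct = mean(perSeed$transformer_structure),
                          combined_pct = mean(perSeed$transformer_combined)),
       transformer_u = list(
         property_pct = mean(perSeed$transformer_u_property),
         structure_pct = mean(perSeed$transformer_u_structure),
         combined_pct = mean(perSeed$transformer_u_combined)),
       random = rnd, per_seed = perSeed, inputs = inputs,
       models = list(conditional = model, unconditional = modelU),
       dataset = ds, corpus = parts$corpus,
       evaluations = list(transformer = evalT, transformer_u = evalU))
}

## sample every input row with one seed; returns list of GenerationResult
.sampleInputs <- function(model, inputs, nUnique, seed) {
  lapply(seq_len(nrow(inputs)), function(i) {
    sampleMolecules(model, inputs$source_smiles[i],
                    .changeFromRow(inputs, i), nUnique = nUnique,
                    seed = seed * 100000L + i)
  })
}
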