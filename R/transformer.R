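## Training and sampling wrappers around the native transformer.

#' Model and training configuration
#'
#' @param numLayers encoder and decoder layer count.
#' @param modelWidth embedding/attention width (divisible by `numHeads`).
#' @param feedforwardWidth inner width of the position-wise feed-forward
#'   sublayers.
#' @param numHeads attention heads.
#' @param dropout dropout probability on embeddings and sublayer outputs.
#' @param maxSequenceLength hard cap on token-sequence length.
#' @param batchSize training batch size.
#' @param warmupSteps linear warmup length of the learning-rate schedule.
#' @param seed integer seed fixing initialization, dropout and batch
#'   order.
#' @return validated configuration list.
#' @export
modelConfig <- function(numLayers = 3L, modelWidth = 256L,
                        feedforwardWidth = 512L, numHeads = 8L,
                        dropout = 0.1, maxSequenceLength = 128L,
                        batchSize = 128L, warmupSteps = 4000L, seed = 1L) {
  cfg <- list(numLayers = as.integer(numLayers),
              modelWidth = as.integer(modelWidth),
              feedforwardWidth = as.integer(feedforwardWidth),
              numHeads = as.integer(numHeads), dropout = dropout,
              maxSequenceLength = as.integer(maxSequenceLength),
              batchSize = as.integer(batchSize),
              warmupSteps = as.integer(warmupSteps), seed = as.integer(seed))
  stopifnot(cfg$numLayers > 0L, cfg$modelWidth > 0L,
            cfg$feedforwardWidth > 0L, cfg$numHeads > 0L,
            cfg$modelWidth %% cfg$numHeads == 0L,
            cfg$dropout >= 0, cfg$dropout < 1,
            cfg$maxSequenceLength > 0L, cfg$batchSize > 0L,
            cfg$warmupSteps > 0L)
  cfg
}

#' Learning rate of the warmup / inverse-square-root schedule
#'
#' `lr(step) = width^-0.5 * min(step^-0.5, step * warmup^-1.5)`:
#' linear increase over the warmup steps, then decay proportional to
#' `step^-0.5`, with the maximum reached exactly at `step = warmup`.
#'
#' @param step training step (1-based).
#' @param modelWidth model width.
#' @param warmupSteps warmup length.
#' @return numeric learning rate.
#' @export
noamLearningRate <- function(step, modelWidth, warmupSteps) {
  modelWidth^-0.5 * pmin(step^-0.5, step * warmupSteps^-1.5)
}

## PropertyChange from the token columns of one pair row
.changeFromRow <- function(pairs, i) {
  new("PropertyChange", logd = pairs$logd_change_token[i],
      solubility = pairs$solubility_token[i],
      clearance = pairs$clearance_token[i])
}

## encode pairs into 0-based id sequences (list of integer vectors)
.encodePairs <- function(pairs, vocab, conditional, maxLen) {
  n <- nrow(pairs)
  src <- vector("list", n); tin <- vector("list", n); tou <- vector("list", n)
  smilesTok <- new.env(parent = emptyenv())
  tokOf <- function(s) {
    h <- smilesTok[[s]]
    if (is.null(h)) { h <- tokensToIds(vocab, tokenizeSmiles(s)); smilesTok[[s]] <- h }
    h
  }
  startId <- 2L; endId <- 3L
  for (i in seq_len(n)) {
    prop <- if (conditional) {
      tokensToIds(vocab, c(pairs$logd_change_token[i],
                           pairs$solubility_token[i],
                           pairs$clearance_token[i]))
    } else integer(0)
    s <- c(startId, prop, tokOf(pairs$source_smiles[i]), endId)
    t <- c(startId, tokOf(pairs$target_smiles[i]), endId)
    if (length(s) > maxLen || length(t) > maxLen)
      stop("truncation error: sequence exceeds maxSequenceLength")
    src[[i]] <- s - 1L
    tin[[i]] <- t[-length(t)] - 1L
    tou[[i]] <- t[-1L] - 1L
  }
  list(src = src, tgt_in = tin, tgt_out = tou)
}

## pad a list of 0-based id vectors into a matrix (pad id 0)
.padBatch <- function(seqs) {
  len <- max(lengths(seqs))
  m <- matrix(0L, nrow = length(seqs), ncol = len)
  for (i in seq_along(seqs)) m[i, seq_along(seqs[[i]])] <- seqs[[i]]
  m
}

.freshPtr <- function(config, vocabSize, params = NULL) {
  ptr <- .tfCreate(as.integer(vocabSize), config$modelWidth,
                   config$numHeads, config$numLayers,
                   config$feedforwardWidth, config$maxSequenceLength,
                   config$dropout, config$seed)
  if (!is.null(params)) .tfSetParams(ptr, params)
  ptr
}

## rebuild the native model from stored parameters when the external
## pointer is stale (e.g. after serialization)
.ensurePtr <- function(model) {
  e <- model@ptr
  if (is.environment(e) && !is.null(e$ptr) && .tfAlive(e$ptr)) return(e$ptr)
  ptr <- .freshPtr(model@config, length(model@vocab@tokens), model@params)
  if (is.environment(e)) e$ptr <- ptr
  ptr
}

#' Train the sequence-to-sequence transformer on a pair dataset
#'
#' Teacher-forced training of the encoder-decoder on (source + property
#' tokens, target) sequences with the Adam optimizer and the warmup /
#' inverse-square-root learning-rate schedule. The parameters with the
#' lowest validation loss are kept (falling back to the final step when
#' the dataset has no validation split). With a fixed seed, config and
#' data the loss trace is reproducible.
#'
#' @param dataset a [PairDataset-class].
#' @param config a [modelConfig()].
#' @param conditional `FALSE` trains the unconditional variant whose
#'   source sequences omit the three property tokens.
#' @param steps number of optimization steps.
#' @param evalEvery validation/checkpoint interval in steps.
#' @param maxValidPairs cap on validation pairs used per evaluation.
#' @param verbose print progress.
#' @return a [MolTransformer-class].
#' @export
trainTransformer <- function(dataset, config = modelConfig(),
                             conditional = TRUE, steps = 2000L,
                             evalEvery = 200L, maxValidPairs = 512L,
                             verbose = FALSE) {
  train <- trainPairs(dataset)
  if (nrow(train) == 0L) stop("dataset has no training pairs")
  vocab <- buildVocabulary(dataset, includePropertyTokens = conditional)
  enc <- .encodePairs(train, vocab, conditional, config$maxSequenceLength)
  valid <- validPairs(dataset)
  if (nrow(valid) > maxValidPairs) valid <- valid[seq_len(maxValidPairs), ]
  vEnc <- if (nrow(valid) > 0L)
    .encodePairs(valid, vocab, conditional, config$maxSequenceLength)
  else NULL
  ptr <- .freshPtr(config, length(vocab@tokens))
  n <- nrow(train)
  bs <- min(config$batchSize, n)
  trace <- list()
  bestLoss <- Inf
  bestParams <- NULL
  .withSeed(config$seed, {
    for (step in seq_len(steps)) {
      idx <- sample.int(n, bs, replace = n < bs)
      lr <- noamLearningRate(step, config$modelWidth, config$warmupSteps)
      loss <- .tfTrainStep(ptr, .padBatch(enc$src[idx]),
                           .padBatch(enc$tgt_in[idx]),
                           .padBatch(enc$tgt_out[idx]), lr)
      vloss <- NA_real_
      if (step %% evalEvery == 0L || step == steps) {
        if (!is.null(vEnc)) {
          vloss <- .evalLoss(ptr, vEnc, bs)
          if (vloss < bestLoss) {
            bestLoss <- vloss
            bestParams <- .tfGetParams(ptr)
          }
        } else {
          bestParams <- .tfGetParams(ptr)
        }
        if (verbose)
          message(sprintf("step %d: train %.4f valid %.4f lr %.2e",
                          step, loss, vloss, lr))
      }
      trace[[step]] <- c(step = step, train_loss = loss, valid_loss = vloss,
                         lr = lr)
    }
  })
  if (is.null(bestParams)) bestParams <- .tfGetParams(ptr)
  .tfSetParams(ptr, bestParams)
  env <- new.env(parent = emptyenv())
  env$ptr <- ptr
  new("MolTransformer", config = config, vocab = vocab,
      conditional = conditional, params = bestParams,
      lossTrace = as.data.frame(do.call(rbind, trace)),
      criterion = dataset@criterion, ptr = env)
}

.evalLoss <- function(ptr, enc, bs) {
  n <- length(enc$src)
  tot <- 0; cnt <- 0
  for (start in seq(1L, n, by = bs)) {
    idx <- seq(start, min(start + bs - 1L, n))
    l <- .tfEvalLoss(ptr, .padBatch(enc$src[idx]),
                     .padBatch(enc$tgt_in[idx]),
                     .padBatch(enc$tgt_out[idx]))
    tot <- tot + l * length(idx)
    cnt <- cnt + length(idx)
  }
  tot / cnt
}

#' Sample target molecules for a starting molecule and constraint
#'
#' Autoregressive multinomial decoding from the trained model: each next
#' token is drawn from the full output distribution until the end token
#' or the length cap, repeated until `nUnique` unique valid molecules
#' different from the start are collected or `maxAttempts` sequences
#' have been drawn. An empty result (no valid molecule within the
#' budget) is returned as such, not as an error.
#'
#' @param model a [MolTransformer-class].
#' @param start starting molecule SMILES (standardized).
#' @param constraint a [PropertyChange-class]; ignored (may be `NULL`)
#'   for unconditional models.
#' @param nUnique number of unique valid molecules requested.
#' @param maxLength decoding length cap (default: model maximum).
#' @param maxAttempts sampling budget (default `10 * nUnique`).
#' @param seed integer seed for the sampler.
#' @return a [GenerationResult-class].
#' @export
sampleMolecules <- function(model, start, constraint, nUnique = 10L,
                            maxLength = NULL, maxAttempts = 10L * nUnique,
                            seed = 1L) {
  stopifnot(is(model, "MolTransformer"))
  if (model@conditional && !is(constraint, "PropertyChange"))
    stop("a conditional model needs a PropertyChange constraint")
  ptr <- .ensurePtr(model)
  if (is.null(maxLength)) maxLength <- model@config$maxSequenceLength
  startCan <- .asMolecule(start)@smiles
  srcTokens <- assembleSource(if (model@conditional) constraint else NULL,
                              startCan)
  srcIds <- tokensToIds(model@vocab, srcTokens) - 1L
  kept <- character(0)
  rows <- list()
  attempts <- 0L
  batch <- 0L
  while (length(kept) < nUnique && attempts < maxAttempts) {
    bs <- min(max(2L * (nUnique - length(kept)), 8L), maxAttempts - attempts)
    srcMat <- matrix(rep(srcIds, bs), nrow = bs, byrow = TRUE)
    batch <- batch + 1L
    out <- .tfSample(ptr, srcMat, as.integer(maxLength), 1L, 2L,
                     as.integer(seed + 7919L * batch), FALSE)
    attempts <- attempts + bs
    for (b in seq_len(bs)) {
      ids <- out[b, ]
      endpos <- match(2L, ids)                    # first <end>
      if (!is.na(endpos)) ids <- ids[seq_len(endpos)]
      toks <- idsToTokens(model@vocab, ids[ids > 0L] + 1L)
      toks <- toks[!toks %in% .SPECIAL_TOKENS]
      smi <- detokenizeSmiles(toks)
      valid <- validSmiles(smi)
      can <- if (valid) canonicalSmiles(smi) else NA_character_
      valid <- valid && !is.na(can)
      keep <- valid && can != startCan && !can %in% kept
      if (keep) kept <- c(kept, can)
      rows[[length(rows) + 1]] <- data.frame(smiles = smi, canonical = can,
                                             valid = valid, kept = keep,
                                             stringsAsFactors = FALSE)
      if (length(kept) >= nUnique) break
    }
  }
  samples <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(smiles = character(0), canonical = character(0),
               valid = logical(0), kept = logical(0))
  constraint <- if (is(constraint, "PropertyChange")) constraint else
    new("PropertyChange", logd = encodeLogDChange(0),
        solubility = "Solubility_no_change",
        clearance = "Clearance_no_change")
  new("GenerationResult", start = startCan, constraint = constraint,
      samples = samples, attempts = as.integer(attempts))
}

#' Save / load a trained model
#'
#' Stores the configuration, vocabulary, parameters and loss trace; the
#' native model is rebuilt on load.
#'
#' @param model a [MolTransformer-class].
#' @param path file path (`.rds`).
#' @export
saveTransformer <- function(model, path) {
  saveRDS(list(config = model@config, tokens = model@vocab@tokens,
               conditional = model@conditional, params = model@params,
               lossTrace = model@lossTrace, criterion = model@criterion),
          path)
  invisible(path)
}

#' @rdname saveTransformer
#' @return a [MolTransformer-class] for `loadTransformer`.
#' @export
loadTransformer <- function(path) {
  x <- readRDS(path)
  new("MolTransformer", config = x$config,
      vocab = new("SmilesVocabulary", tokens = x$tokens),
      conditional = x$conditional, params = x$params,
      lossTrace = x$lossTrace, criterion = x$criterion,
      ptr = new.env(parent = emptyenv()))
}
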