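test_that("tokenization splits characters but keeps Cl/Br/brackets whole", {
  expect_identical(tokenizeSmiles("CC(Cl)c1cc[nH]c1"),
                   c("C", "C", "(", "Cl", ")", "c", "1", "c", "c", "[nH]",
                     "c", "1"))
  expect_identical(tokenizeSmiles("[O-]"), "[O-]")
  expect_identical(tokenizeSmiles("BrCCBr"), c("Br", "C", "C", "Br"))
  # two-digit ring closures stay single tokens
  expect_true("%10" %in% tokenizeSmiles("C%10CCCCC%10"))
  expect_error(tokenizeSmiles("C[nH"), "tokenization error")
})

test_that("tokenize/detokenize round-trips a large generated battery", {
  corpus <- smallCorpus()
  base <- unique(corpus$smiles)
  set.seed(21)
  battery <- c(base,
               paste0("ClC(Br)", sample(base, 300, replace = TRUE)),
               vapply(sample(base, 300, replace = TRUE), function(s)
                 paste0("[13CH3]O", s), character(1)),
               rep(c("C%12CCCCC%12", "C/C=C\\[C@@H](O)Cl"), 50))
  battery <- head(battery, 1000)
  expect_gte(length(battery), 600L)
  for (s in battery)
    expect_identical(detokenizeSmiles(tokenizeSmiles(s)), s)
  # never a split Cl: no bare "l" token can appear
  for (s in head(battery, 100))
    expect_false("l" %in% tokenizeSmiles(s))
})

test_that("vocabularies are the token union over all splits plus specials", {
  ds <- smallPairs("scaffold")
  v <- buildVocabulary(ds)
  expect_identical(v@tokens[1:4], c("<pad>", "<start>", "<end>", "<unk>"))
  all_tokens <- unique(unlist(lapply(
    unique(c(ds@pairs$source_smiles, ds@pairs$target_smiles)),
    tokenizeSmiles)))
  expect_true(all(all_tokens %in% v@tokens))
  expect_true(all(unique(ds@pairs$logd_change_token) %in% v@tokens))
  # a token only in the validation split is still covered
  splitTok <- unique(unlist(lapply(
    validPairs(ds)$source_smiles, tokenizeSmiles)))
  expect_true(all(splitTok %in% v@tokens))
  # the unconditional vocabulary carries no property tokens
  vu <- buildVocabulary(ds, includePropertyTokens = FALSE)
  expect_false(any(grepl("^LogD_change|^Solubility|^Clearance", vu@tokens)))
  expect_error(buildVocabulary(MolPairGen:::.emptyPairs()), "empty dataset")
})

test_that("source assembly prepends the property triple inside specials", {
  z <- propertyChange(list(logd = 0, solubility = 1, clearance = 1),
                      list(logd = 0.2, solubility = 1.9, clearance = 1))
  s <- assembleSource(z, "CCO")
  expect_identical(s[1], "<start>")
  expect_identical(tail(s, 1), "<end>")
  expect_identical(s[2:4], propertyTokens(z))
  expect_length(s, 2L + 3L + length(tokenizeSmiles("CCO")))
  # stripping specials and the property prefix recovers the SMILES
  expect_identical(detokenizeSmiles(s[5:(length(s) - 1)]), "CCO")
  # unconditional source is exactly 3 tokens shorter
  expect_length(assembleSource(NULL, "CCO"), length(s) - 3L)
})

test_that("vocabulary indices survive serialization", {
  v <- buildVocabulary(smallPairs("scaffold"))
  path <- tempfile(fileext = ".vocab")
  writeVocabulary(v, path)
  v2 <- readVocabulary(path)
  expect_identical(v2@tokens, v@tokens)
  toks <- c("C", "(", "<end>")
  expect_identical(tokensToIds(v2, toks), tokensToIds(v, toks))
  # out-of-vocabulary tokens fall back to <unk> with a warning
  expect_warning(ids <- tokensToIds(v, "[Xe]"), "unk")
  expect_identical(ids, 4L)
})
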