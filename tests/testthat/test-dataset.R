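mkRecords <- function(smiles, pub = "P1", year = 2010L) {
  prof <- lapply(smiles, syntheticOracle)
  data.frame(smiles = vapply(smiles, canonicalSmiles, character(1)),
             publication_id = pub, year = year,
             logd = vapply(prof, `[[`, numeric(1), "logd"),
             solubility = vapply(prof, `[[`, numeric(1), "solubility"),
             clearance = vapply(prof, `[[`, numeric(1), "clearance"),
             stringsAsFactors = FALSE)
}

test_that("molecule filters enforce size, rings and property outliers", {
  recs <- mkRecords(c("CCCCCCCCC",                 # 9 heavy atoms, no ring
                      "CCCCCCCCCC",                # 10 heavy atoms, no ring
                      "Cc1ccc(C(=O)Nc2ccccc2)cc1", # fine
                      "CCCCCCCC1CC1"))             # ring, 10 heavy
  kept <- filterMolecules(recs)
  expect_false("CCCCCCCCC" %in% kept$smiles)
  expect_false(canonicalSmiles("CCCCCCCCCC") %in% kept$smiles)  # acyclic
  expect_true(canonicalSmiles("Cc1ccc(C(=O)Nc2ccccc2)cc1") %in% kept$smiles)
  # a gross property outlier is removed by the 3-SD rule
  many <- do.call(rbind, rep(list(mkRecords(
    c("Cc1ccc(C(=O)Nc2ccccc2)cc1", "CCc1ccc(C(=O)Nc2ccccc2)cc1"))), 10))
  out <- mkRecords("Cc1ccccc1CCCCCCCCCCCCCCCCCCCCCCCC")  # huge logd
  all <- rbind(many, out)
  kept <- filterMolecules(all)
  expect_false(out$smiles %in% kept$smiles)
  # pluggable extra filters are honoured
  kept <- filterMolecules(recs, extraFilters = list(function(s) FALSE))
  expect_equal(nrow(kept), 0L)
  expect_equal(nrow(filterMolecules(recs[0, ])), 0L)
})

test_that("publication filters enforce year and size bounds", {
  a <- mkRecords(rep("Cc1ccc(C(=O)Nc2ccccc2)cc1", 12), pub = "OLD",
                 year = 1999L)
  b <- mkRecords(rep("Cc1ccc(C(=O)Nc2ccccc2)cc1", 61), pub = "BIG",
                 year = 2005L)
  c <- mkRecords(rep("Cc1ccc(C(=O)Nc2ccccc2)cc1", 10), pub = "OK",
                 year = 2000L)
  kept <- filterPublications(rbind(a, b, c))
  expect_setequal(unique(kept$publication_id), "OK")
  expect_equal(nrow(kept), 10L)
})

test_that("pair predicates implement the six criteria", {
  expect_true(pairPredicate("scaffold", "Cc1ccccc1", "CCc1ccccc1"))
  expect_false(pairPredicate("scaffold", "c1ccccc1", "c1ccncc1"))
  expect_true(pairPredicate("scaffold-generic", "c1ccccc1", "c1ccncc1"))
  expect_true(pairPredicate("mmp", "Cc1ccccc1", "CCc1ccccc1"))
  t <- tanimotoSimilarity("Cc1ccc(C(=O)Nc2ccccc2)cc1",
                          "CCc1ccc(C(=O)Nc2ccccc2)cc1")
  expect_identical(pairPredicate("sim05", "Cc1ccc(C(=O)Nc2ccccc2)cc1",
                                 "CCc1ccc(C(=O)Nc2ccccc2)cc1"), t >= 0.5)
  expect_error(pairPredicate("nope", "C", "C"), "configuration error")
})

test_that("similarity bands are half-open and partition sim05", {
  ds05 <- smallPairs("sim05")@pairs
  ds0507 <- smallPairs("sim0507")@pairs
  ds07 <- smallPairs("sim07")@pairs
  key <- function(df) paste(df$source_smiles, df$target_smiles)
  expect_true(all(key(ds0507) %in% key(ds05)))
  expect_true(all(key(ds07) %in% key(ds05)))
  expect_length(intersect(key(ds0507), key(ds07)), 0L)
  expect_setequal(key(ds05), union(key(ds0507), key(ds07)))
  # and the bands hold numerically
  t07 <- vapply(seq_len(nrow(ds07)), function(i)
    tanimotoSimilarity(ds07$source_smiles[i], ds07$target_smiles[i]),
    numeric(1))
  expect_true(all(t07 >= 0.7))
  t0507 <- vapply(seq_len(min(nrow(ds0507), 50)), function(i)
    tanimotoSimilarity(ds0507$source_smiles[i], ds0507$target_smiles[i]),
    numeric(1))
  expect_true(all(t0507 >= 0.5 & t0507 < 0.7))
})

test_that("a publication where all pairs pass yields n(n-1) directed pairs", {
  recs <- mkRecords(c("Cc1ccc(C(=O)Nc2ccccc2)cc1",
                      "CCc1ccc(C(=O)Nc2ccccc2)cc1",
                      "CCCc1ccc(C(=O)Nc2ccccc2)cc1"))
  ds <- extractPairs(recs, "scaffold")
  expect_equal(nrow(ds@pairs), 6L)
  expect_true(all(ds@pairs$split == "train"))
})

test_that("duplicate structure pairs keep the earliest year", {
  smi <- c("Cc1ccc(C(=O)Nc2ccccc2)cc1", "CCc1ccc(C(=O)Nc2ccccc2)cc1")
  recs <- rbind(mkRecords(smi, pub = "LATE", year = 2012L),
                mkRecords(smi, pub = "EARLY", year = 2005L))
  ds <- extractPairs(recs, "scaffold")
  expect_equal(nrow(ds@pairs), 2L)  # one unordered pair + its reverse
  expect_true(all(ds@pairs$year == 2005L))
})

test_that("reverse pairs are present with inverted changes in the same split", {
  for (cr in c("scaffold", "sim05", "mmp")) {
    p <- smallPairs(cr)@pairs
    if (nrow(p) == 0L) next
    key <- paste(p$source_smiles, p$target_smiles, p$split)
    for (i in seq_len(min(nrow(p), 200))) {
      z <- MolPairGen:::.changeFromRow(p, i)
      inv <- invertPropertyChange(z)
      revKey <- paste(p$target_smiles[i], p$source_smiles[i], p$split[i])
      j <- match(revKey, key)
      expect_false(is.na(j))
      expect_identical(propertyTokens(MolPairGen:::.changeFromRow(p, j)),
                       propertyTokens(inv))
    }
  }
})

test_that("year splits partition the retained pairs", {
  p <- smallPairs("scaffold")@pairs
  expect_true(all(p$split %in% c("train", "valid", "test")))
  expect_true(all(p$year[p$split == "train"] %in% 2000:2017))
  expect_true(all(p$year[p$split == "valid"] == 2018))
  expect_true(all(p$year[p$split == "test"] %in% 2019:2020))
})

test_that("every extracted pair satisfies its criterion predicate", {
  for (cr in c("scaffold", "scaffold_generic", "sim07", "mmp")) {
    p <- smallPairs(cr)@pairs
    take <- head(seq_len(nrow(p)), 40)
    for (i in take)
      expect_true(pairPredicate(cr, p$source_smiles[i], p$target_smiles[i]))
  }
})

test_that("pair datasets round-trip through TSV", {
  ds <- smallPairs("scaffold")
  path <- tempfile(fileext = ".tsv")
  writePairDataset(ds, path)
  ds2 <- readPairDataset(path)
  expect_identical(ds2@pairs$source_smiles, ds@pairs$source_smiles)
  expect_identical(ds2@criterion, ds@criterion)
})
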