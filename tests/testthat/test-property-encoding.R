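test_that("logD changes map to the designed interval tokens", {
  expect_identical(encodeLogDChange(0.0), "LogD_change_(-0.1, 0.1]")
  expect_identical(encodeLogDChange(0.25), "LogD_change_(0.1, 0.3]")
  expect_identical(encodeLogDChange(-0.2), "LogD_change_(-0.3, -0.1]")
  expect_identical(encodeLogDChange(-7.5), "LogD_change_(-inf, -6.9]")
  expect_identical(encodeLogDChange(8.0), "LogD_change_(6.9, inf]")
  expect_error(encodeLogDChange(NaN), "non-finite")
})

test_that("the encoder emits exactly 71 distinct tokens", {
  toks <- logDChangeTokens()
  expect_length(toks, 71L)
  expect_false(anyDuplicated(toks) > 0)
  # enumeration agrees with the encoder over a dense sweep
  sweep <- seq(-7.4, 7.4, by = 0.01)
  emitted <- unique(vapply(sweep, encodeLogDChange, character(1)))
  expect_setequal(emitted, toks)
})

test_that("bins are left-open right-closed and tile the line", {
  # a value exactly on an edge belongs to the lower-labelled bin
  expect_identical(encodeLogDChange(0.1), "LogD_change_(-0.1, 0.1]")
  expect_identical(encodeLogDChange(0.1000001), "LogD_change_(0.1, 0.3]")
  expect_identical(encodeLogDChange(-6.9), "LogD_change_(-inf, -6.9]")
  expect_identical(encodeLogDChange(6.9), "LogD_change_(6.7, 6.9]")
  # every finite delta maps to exactly one token
  set.seed(5)
  for (d in runif(200, -9, 9))
    expect_length(encodeLogDChange(d), 1L)
})

test_that("mirror symmetry holds off bin edges", {
  set.seed(6)
  for (d in runif(100, -8, 8)) {
    if (abs(round((d + 6.9) / 0.2) - (d + 6.9) / 0.2) < 1e-6) next
    tok <- encodeLogDChange(d)
    mir <- encodeLogDChange(-d)
    expect_identical(MolPairGen:::.invertLogDToken(tok), mir)
  }
})

test_that("solubility and clearance categorize at 1.7 and 1.3 inclusively", {
  expect_identical(categorizeProperty("solubility", 1.0), "low")
  expect_identical(categorizeProperty("solubility", 1.7), "low")
  expect_identical(categorizeProperty("solubility", 1.7000001), "high")
  expect_identical(categorizeProperty("clearance", 1.3), "low")
  expect_identical(categorizeProperty("clearance", 1.31), "high")
  expect_error(categorizeProperty("potency", 1.0), "unknown property")
})

test_that("the worked solubility example encodes low->high", {
  # input 10 uM (log10 = 1.0), target 80 uM (log10 ~ 1.9)
  expect_identical(encodeCategoryChange("solubility", log10(10), log10(80)),
                   "Solubility_low->high")
  expect_identical(encodeCategoryChange("solubility", 2.5, 1.2),
                   "Solubility_high->low")
  expect_identical(encodeCategoryChange("clearance", 0.8, 1.1),
                   "Clearance_no_change")
})

test_that("each categorical property emits exactly three distinct tokens", {
  vals <- c(0.5, 1.3, 1.7, 2.5)
  for (p in c("solubility", "clearance")) {
    toks <- unique(unlist(lapply(vals, function(a)
      lapply(vals, function(b) encodeCategoryChange(p, a, b)))))
    expect_length(toks, 3L)
  }
})

test_that("property changes compose and invert consistently", {
  a <- list(logd = 1.0, solubility = 1.0, clearance = 1.0)
  b <- list(logd = 1.2, solubility = 1.9, clearance = 1.1)
  z <- propertyChange(a, b)
  expect_identical(propertyTokens(z),
                   c("LogD_change_(0.1, 0.3]", "Solubility_low->high",
                     "Clearance_no_change"))
  expect_identical(propertyTokens(invertPropertyChange(z)),
                   propertyTokens(propertyChange(b, a)))
  same <- propertyChange(a, a)
  expect_identical(propertyTokens(same),
                   c("LogD_change_(-0.1, 0.1]", "Solubility_no_change",
                     "Clearance_no_change"))
})

test_that("the synthetic oracle is deterministic and direction-consistent", {
  p1 <- syntheticOracle("Cc1ccc(C(=O)Nc2ccccc2)cc1")
  p2 <- syntheticOracle("Cc1ccc(C(=O)Nc2ccccc2)cc1")
  expect_identical(p1, p2)
  # adding a polar substituent strictly decreases pseudo-logD
  base <- syntheticOracle("Cc1ccc(C(=O)Nc2ccccc2)cc1")
  polar <- syntheticOracle("Cc1ccc(C(=O)Nc2ccc(O)cc2)cc1")
  expect_lt(polar$logd, base$logd)
  # and solubility moves the other way
  expect_gt(polar$solubility, base$solubility)
})

test_that("the synthetic corpus populates both category sides", {
  corpus <- smallCorpus()
  expect_gt(sum(corpus$solubility <= 1.7), 0)
  expect_gt(sum(corpus$solubility > 1.7), 0)
  expect_gt(sum(corpus$clearance <= 1.3), 0)
  expect_gt(sum(corpus$clearance > 1.3), 0)
})
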