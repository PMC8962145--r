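## Molecule/publication filtering and molecular-pair mining under the six
## criteria, with deduplication (earliest year kept), reverse-pair
## closure, and year-based train/valid/test splitting.

.TRAIN_YEARS <- c(2000L, 2017L)
.VALID_YEAR <- 2018L
.TEST_YEARS <- c(2019L, 2020L)

#' Filter molecules for pair mining
#'
#' Keeps records with 10 <= heavy atoms <= 50, at least one ring, every
#' property within 3 standard deviations of the corpus mean for that
#' property, and passing all extra predicate hooks (stand-ins for
#' proprietary quality/substructure filters).
#'
#' @param records data.frame with columns `smiles` (standardized),
#'   `logd`, `solubility`, `clearance` (and any others, preserved).
#' @param extraFilters list of functions `function(smiles) -> logical`.
#' @param minHeavy,maxHeavy heavy-atom bounds (default 10, 50).
#' @param sdLimit property standard-deviation cutoff (default 3).
#' @return the kept subset of `records`.
#' @export
filterMolecules <- function(records, extraFilters = list(),
                            minHeavy = 10L, maxHeavy = 50L, sdLimit = 3) {
  if (nrow(records) == 0L) return(records)
  .precacheMolecules(unique(records$smiles))
  heavy <- vapply(records$smiles, heavyAtomCount, integer(1))
  rings <- vapply(records$smiles, ringCount, integer(1))
  keep <- heavy >= minHeavy & heavy <= maxHeavy & rings > 0L
  for (prop in c("logd", "solubility", "clearance")) {
    v <- records[[prop]]
    mu <- mean(v); s <- sd(v)
    if (is.finite(s) && s > 0) keep <- keep & abs(v - mu) <= sdLimit * s
  }
  for (f in extraFilters) {
    keep <- keep & vapply(records$smiles, function(s) isTRUE(f(s)),
                          logical(1))
  }
  records[keep, , drop = FALSE]
}

#' Filter publications
#'
#' Keeps only records whose publication has year >= 2000 and whose
#' (post-molecule-filter) size lies in [10, 60].
#'
#' @param records data.frame with columns `publication_id` and `year`.
#' @param minSize,maxSize publication size bounds (default 10, 60).
#' @return the kept subset of `records`.
#' @export
filterPublications <- function(records, minSize = 10L, maxSize = 60L) {
  if (nrow(records) == 0L) return(records)
  keep <- records$year >= 2000L
  sizes <- table(records$publication_id[keep])
  okPub <- names(sizes)[sizes >= minSize & sizes <= maxSize]
  records[keep & records$publication_id %in% okPub, , drop = FALSE]
}

#' Pairing predicate for one criterion
#'
#' `sim05`/`sim0507`/`sim07` test the Tanimoto similarity against
#' [0.5, 1], [0.5, 0.7) and [0.7, 1]; `scaffold` and `scaffold_generic`
#' test scaffold-string equality; `mmp` delegates to [isMmp()].
#'
#' @param criterion one of [pairCriteria()].
#' @param a,b SMILES strings or [CanonicalMolecule-class] objects.
#' @return logical.
#' @export
pairPredicate <- function(criterion, a, b) {
  criterion <- .normalizeCriterion(criterion)
  switch(criterion,
         mmp = isMmp(a, b),
         sim05 = tanimotoSimilarity(a, b) >= 0.5,
         sim0507 = {
           t <- tanimotoSimilarity(a, b); t >= 0.5 && t < 0.7
         },
         sim07 = tanimotoSimilarity(a, b) >= 0.7,
         scaffold = murckoScaffold(a) == murckoScaffold(b),
         scaffold_generic = genericScaffold(a) == genericScaffold(b))
}

## elementwise bytewise string comparison (collation-independent)
.byteGreater <- function(a, b) {
  vapply(seq_along(a), function(i) {
    if (a[i] == b[i]) return(FALSE)
    order(c(a[i], b[i]), method = "radix")[1] == 2L
  }, logical(1))
}

.normalizeCriterion <- function(criterion) {
  c <- gsub("-", "_", tolower(criterion))
  if (!c %in% pairCriteria())
    stop("configuration error: unknown criterion '", criterion, "'")
  c
}

#' Mine molecular pairs from a filtered corpus
#'
#' Enumerates all unordered within-publication molecule pairs, keeps
#' those passing the criterion predicate, removes duplicated structure
#' pairs keeping the earliest year (ties broken by publication id),
#' attaches property-change tokens, adds the reverse pair with inverted
#' change, and splits by year into train (2000-2017) / valid (2018) /
#' test (2019-2020). Pairs outside 2000-2020 are dropped.
#'
#' @param corpus filtered data.frame with columns `smiles`,
#'   `publication_id`, `year`, `logd`, `solubility`, `clearance`.
#' @param criterion one of [pairCriteria()].
#' @return a [PairDataset-class].
#' @export
extractPairs <- function(corpus, criterion) {
  criterion <- .normalizeCriterion(criterion)
  .precacheMolecules(unique(corpus$smiles))
  cand <- list()
  for (pub in unique(corpus$publication_id)) {
    sub <- corpus[corpus$publication_id == pub, , drop = FALSE]
    if (nrow(sub) < 2L) next
    hits <- .pairHits(criterion, sub$smiles)
    if (nrow(hits) == 0L) next
    cand[[length(cand) + 1]] <- data.frame(
      i = hits$i, j = hits$j, pub = pub, year = sub$year[1],
      si = sub$smiles[hits$i], sj = sub$smiles[hits$j],
      row_i = rownames(sub)[hits$i], row_j = rownames(sub)[hits$j],
      stringsAsFactors = FALSE)
  }
  if (length(cand) == 0L) {
    return(new("PairDataset", criterion = criterion, pairs = .emptyPairs()))
  }
  cand <- do.call(rbind, cand)
  ## orient: source = bytewise-smaller SMILES (deterministic and
  ## locale-independent)
  swap <- .byteGreater(cand$si, cand$sj)
  tmp <- cand$si[swap]; cand$si[swap] <- cand$sj[swap]; cand$sj[swap] <- tmp
  tmp <- cand$row_i[swap]; cand$row_i[swap] <- cand$row_j[swap]
  cand$row_j[swap] <- tmp
  ## dedup: earliest year, ties by publication id
  key <- paste(cand$si, cand$sj, sep = "\r")
  ord <- order(key, cand$year, cand$pub, method = "radix")
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(key[ord]), , drop = FALSE]
  ## property change from the two records' profiles
  prof <- function(rows) {
    idx <- match(rows, rownames(corpus))
    lapply(idx, function(k) .profileOfRow(corpus, k))
  }
  pa <- prof(cand$row_i); pb <- prof(cand$row_j)
  fwd <- lapply(seq_len(nrow(cand)), function(k) propertyChange(pa[[k]],
                                                                pb[[k]]))
  rev <- lapply(fwd, invertPropertyChange)
  mk <- function(src, tgt, chg, year) {
    data.frame(source_smiles = src, target_smiles = tgt,
               logd_change_token = vapply(chg, slot, character(1), "logd"),
               solubility_token = vapply(chg, slot, character(1),
                                         "solubility"),
               clearance_token = vapply(chg, slot, character(1), "clearance"),
               criterion = criterion, year = year, stringsAsFactors = FALSE)
  }
  pairs <- rbind(mk(cand$si, cand$sj, fwd, cand$year),
                 mk(cand$sj, cand$si, rev, cand$year))
  pairs$split <- .yearSplit(pairs$year)
  pairs <- pairs[!is.na(pairs$split), , drop = FALSE]
  rownames(pairs) <- NULL
  new("PairDataset", criterion = criterion, pairs = pairs)
}

.emptyPairs <- function() {
  data.frame(source_smiles = character(0), target_smiles = character(0),
             logd_change_token = character(0),
             solubility_token = character(0),
             clearance_token = character(0), criterion = character(0),
             year = integer(0), split = character(0))
}

.yearSplit <- function(year) {
  ifelse(year >= .TRAIN_YEARS[1] & year <= .TRAIN_YEARS[2], "train",
         ifelse(year == .VALID_YEAR, "valid",
                ifelse(year >= .TEST_YEARS[1] & year <= .TEST_YEARS[2],
                       "test", NA_character_)))
}

## indices (i < j) of pairs among `smiles` passing the criterion;
## vectorized per criterion to keep mining fast
.pairHits <- function(criterion, smiles) {
  n <- length(smiles)
  none <- data.frame(i = integer(0), j = integer(0))
  if (n < 2L) return(none)
  if (criterion %in% c("scaffold", "scaffold_generic")) {
    scaf <- vapply(smiles, function(s) {
      mol <- .asMolecule(s)
      if (mol@ringCount < 1L) return(NA_character_)
      if (criterion == "scaffold") murckoScaffold(mol) else
        genericScaffold(mol)
    }, character(1), USE.NAMES = FALSE)
    out <- list()
    for (idxs in split(seq_len(n), scaf)) {
      if (length(idxs) < 2L) next
      cmb <- t(utils::combn(idxs, 2L))
      out[[length(out) + 1]] <- cmb
    }
    if (length(out) == 0L) return(none)
    m <- do.call(rbind, out)
    ## identical SMILES cannot pair (duplicates across templates)
    keep <- smiles[m[, 1]] != smiles[m[, 2]]
    return(data.frame(i = m[keep, 1], j = m[keep, 2]))
  }
  if (criterion %in% c("sim05", "sim0507", "sim07")) {
    fps <- lapply(smiles, morganFingerprint)
    out <- list()
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (smiles[i] == smiles[j]) next
        inter <- length(intersect(fps[[i]], fps[[j]]))
        t <- inter / (length(fps[[i]]) + length(fps[[j]]) - inter)
        ok <- switch(criterion,
                     sim05 = t >= 0.5,
                     sim0507 = t >= 0.5 && t < 0.7,
                     sim07 = t >= 0.7)
        if (ok) out[[length(out) + 1]] <- c(i, j)
      }
    }
    if (length(out) == 0L) return(none)
    m <- do.call(rbind, out)
    return(data.frame(i = m[, 1], j = m[, 2]))
  }
  ## mmp: shared-core join over per-molecule fragment indexes
  idx <- lapply(smiles, function(s) {
    mol <- .asMolecule(s)
    fi <- mmpFragmentIndex(mol)
    if (nrow(fi) == 0L) return(fi)
    fi[fi$r_heavy / mol@heavyAtomCount <= 0.33 + 1e-9, , drop = FALSE]
  })
  big <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (nrow(idx[[i]]) == 0L) return(NULL)
    cbind(idx[[i]], mol = i)
  }))
  if (is.null(big) || nrow(big) == 0L) return(none)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (grp in split(big, big$core)) {
    mols <- unique(grp$mol)
    if (length(mols) < 2L) next
    for (ii in seq_len(length(mols) - 1L)) {
      for (jj in seq((ii + 1L), length(mols))) {
        a <- mols[ii]; b <- mols[jj]
        if (smiles[a] == smiles[b]) next
        kk <- paste(min(a, b), max(a, b))
        if (!is.null(seen[[kk]])) next
        ra <- grp$r[grp$mol == a]; rb <- grp$r[grp$mol == b]
        if (any(outer(ra, rb, "!="))) {
          seen[[kk]] <- TRUE
          out[[length(out) + 1]] <- c(min(a, b), max(a, b))
        }
      }
    }
  }
  if (length(out) == 0L) return(none)
  m <- unique(do.call(rbind, out))
  data.frame(i = m[, 1], j = m[, 2])
}

#' Property change of one mined pair
#'
#' Reassembles the [PropertyChange-class] of row `i` from the token
#' columns of a pair table.
#'
#' @param pairs a [PairDataset-class] or its pair data.frame.
#' @param i row index.
#' @return a [PropertyChange-class].
#' @export
pairPropertyChange <- function(pairs, i) {
  if (is(pairs, "PairDataset")) pairs <- pairs@pairs
  .changeFromRow(pairs, i)
}

# ---------------------------------------------------------------------------
# file interfaces

#' Read a molecule corpus from CSV/TSV
#'
#' Expects columns `smiles`, `publication_id`, `year`; property columns
#' (`logd`, `solubility`, `clearance`) are attached from `oracle` when
#' absent.
#'
#' @param path file path (separator inferred from the extension).
#' @param oracle property oracle, a function `smiles -> list(logd,
#'   solubility, clearance)`; default [syntheticOracle()].
#' @return data.frame corpus.
#' @export
readCorpus <- function(path, oracle = syntheticOracle) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("smiles", "publication_id", "year") %in% names(df)))
  if (!all(c("logd", "solubility", "clearance") %in% names(df))) {
    .precacheMolecules(unique(df$smiles))
    prof <- lapply(df$smiles, oracle)
    df$logd <- vapply(prof, `[[`, numeric(1), "logd")
    df$solubility <- vapply(prof, `[[`, numeric(1), "solubility")
    df$clearance <- vapply(prof, `[[`, numeric(1), "clearance")
  }
  df
}

#' Write / read a pair dataset as TSV
#'
#' @param dataset a [PairDataset-class].
#' @param path file path.
#' @export
writePairDataset <- function(dataset, path) {
  write.table(dataset@pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writePairDataset
#' @return a [PairDataset-class] for `readPairDataset`.
#' @export
readPairDataset <- function(path) {
  pairs <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  new("PairDataset", criterion = pairs$criterion[1], pairs = pairs)
}
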