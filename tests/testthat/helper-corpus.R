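# Shared fixtures, built once per test run and cached.

.testCache <- new.env(parent = emptyenv())

# small publication-structured corpus used across test files
smallCorpus <- function() {
  if (is.null(.testCache$corpus)) {
    cfg <- fixtureConfig(nPublications = 8L, seed = 424242L)
    .testCache$corpusConfig <- cfg
    corpus <- generateCorpus(cfg)
    # spread publication years over a fixed cycle so every split
    # (train/valid/test) is populated even at this small scale
    pubs <- unique(corpus$publication_id)
    years <- rep(c(2005L, 2010L, 2018L, 2019L, 2015L, 2020L, 2008L, 2012L),
                 length.out = length(pubs))
    corpus$year <- years[match(corpus$publication_id, pubs)]
    .testCache$corpus <- corpus
  }
  .testCache$corpus
}

smallCorpusConfig <- function() {
  smallCorpus()
  .testCache$corpusConfig
}

# a ~30-molecule slice (first publications) for brute-force comparisons
oracleCorpus <- function() {
  corpus <- smallCorpus()
  pubs <- unique(corpus$publication_id)
  keep <- character(0)
  for (p in pubs) {
    keep <- c(keep, p)
    if (sum(corpus$publication_id %in% keep) >= 30L) break
  }
  corpus[corpus$publication_id %in% keep, , drop = FALSE]
}

# pair datasets per criterion on the small corpus, cached
smallPairs <- function(criterion) {
  key <- paste0("pairs_", criterion)
  if (is.null(.testCache[[key]])) {
    .testCache[[key]] <- extractPairs(smallCorpus(), criterion)
  }
  .testCache[[key]]
}

# run a short python/RDKit snippet; skips nothing -- RDKit is part of the
# supported toolchain and the test should fail loudly if it breaks
runPython <- function(code) {
  out <- suppressWarnings(system2("python", c("-c", shQuote(code)),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) stop("python helper failed")
  out
}

# independent circular-environment enumerator: features as explicit
# strings (element, degree, charge, implicit H, ring flag; expanded over
# sorted neighbour (bond, feature) lists), no hashing or bit folding
enumerateCircularFeatures <- function(smiles, radius = 2L) {
  g <- MolPairGen:::.smilesToGraph(smiles)
  deg <- MolPairGen:::.degrees(g)
  impH <- MolPairGen:::.implicitH(g)
  ring <- MolPairGen:::.ringAtoms(g)
  n <- length(g$elem)
  lab <- vapply(seq_len(n), function(i) {
    paste(g$elem[i], deg[i], g$charge[i], impH[i], as.integer(ring[i]),
          sep = ",")
  }, character(1))
  nbr <- lapply(seq_len(n), function(i) {
    sel <- g$bonds$a == i | g$bonds$b == i
    data.frame(j = ifelse(g$bonds$a[sel] == i, g$bonds$b[sel],
                          g$bonds$a[sel]),
               o = g$bonds$order[sel])
  })
  feats <- unique(lab)
  cur <- lab
  for (r in seq_len(radius)) {
    nxt <- vapply(seq_len(n), function(i) {
      nb <- nbr[[i]]
      parts <- sort(paste0(nb$o, ":", cur[nb$j]))
      paste0("r", r, "{", cur[i], "|", paste(parts, collapse = ";"), "}")
    }, character(1))
    cur <- nxt
    feats <- c(feats, unique(cur))
  }
  unique(feats)
}
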