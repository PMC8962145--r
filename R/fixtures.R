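## Synthetic corpus generator: publication-structured molecule families
## built from shared scaffold templates decorated with enumerable
## substituents, plus the exhaustive structure->property grammar truth
## used to benchmark the generative model.

## run expr under a fixed seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## template families: each family is a set of scaffold templates sharing
## ring topology (heteroatom swaps), so same-family cross-template pairs
## share the generic but not the exact scaffold
.DEFAULT_TEMPLATES <- list(
  benzanilide = c(
    "O=C(Nc1ccc({R2})cc1)c1cc({R3})cc({R1})c1",
    "O=C(Nc1ccc({R2})cc1)c1cc({R3})cc({R1})n1"),
  diarylmethane = c(
    "c1cc({R1})cc({R3})c1Cc1ccc({R2})cc1",
    "c1cc({R1})cc({R3})c1Cc1ccc({R2})nc1"),
  piperidineamide = c(
    "O=C(N1CCC({R1})CC1)c1cc({R3})cc({R2})c1",
    "O=C(N1CCC({R1})CC1)c1cc({R3})cc({R2})n1"),
  diarylether = c(
    "c1cc({R1})cc({R3})c1Oc1ccc({R2})cc1",
    "c1cc({R1})cc({R3})c1Oc1ccc({R2})nc1"))

.DEFAULT_SUBSTITUENTS <- c("C", "CC", "CCC", "O", "OC", "OCC", "N", "NC",
                           "F", "Cl", "C#N", "CO")

## chemically coherent series a single project would explore at its
## varied position (homologation, ether series, amines, halogen walk)
.DEFAULT_FAMILIES <- list(alkyl = c("C", "CC", "CCC"),
                          ether = c("O", "OC", "OCC"),
                          amino = c("N", "NC", "CO"),
                          halogen = c("F", "Cl", "C#N"))

#' Configuration for the synthetic corpus generator
#'
#' @param nPublications number of publications to simulate.
#' @param moleculesPerPublication integer range `c(lo, hi)`; defaults stay
#'   within the [10, 60] publication-size filter.
#' @param scaffoldTemplates named list of template families; each template
#'   is a SMILES with substitution slots `({R1})`, `({R2})`, `({R3})`.
#' @param substituentAlphabet fragment SMILES insertable as branches; the
#'   empty substituent (hydrogen) is always included implicitly.
#' @param substituentFamilies named list of chemically coherent series
#'   (subsets of the alphabet); each publication explores one series at
#'   its varied position.
#' @param yearRange publication years, inclusive.
#' @param seed integer; fixes all randomness of the generator.
#' @return a validated configuration list.
#' @export
fixtureConfig <- function(nPublications = 40L,
                          moleculesPerPublication = c(10L, 12L),
                          scaffoldTemplates = .DEFAULT_TEMPLATES,
                          substituentAlphabet = .DEFAULT_SUBSTITUENTS,
                          substituentFamilies = .DEFAULT_FAMILIES,
                          yearRange = c(2000L, 2020L),
                          seed = 1L) {
  stopifnot(nPublications >= 1L,
            length(moleculesPerPublication) == 2L,
            moleculesPerPublication[1] <= moleculesPerPublication[2],
            length(scaffoldTemplates) >= 1L,
            length(substituentAlphabet) >= 1L,
            yearRange[1] <= yearRange[2])
  for (fam in scaffoldTemplates) {
    for (tpl in fam) {
      if (!grepl("\\{R1\\}", tpl))
        stop("template without attachment points: ", tpl)
    }
  }
  stopifnot(all(unlist(substituentFamilies) %in% substituentAlphabet))
  structure(list(nPublications = as.integer(nPublications),
                 moleculesPerPublication = as.integer(moleculesPerPublication),
                 scaffoldTemplates = scaffoldTemplates,
                 substituentAlphabet = substituentAlphabet,
                 substituentFamilies = substituentFamilies,
                 yearRange = as.integer(yearRange),
                 seed = as.integer(seed)),
            class = "FixtureConfig")
}

## slots present in a template
.templateSlots <- function(tpl) {
  m <- regmatches(tpl, gregexpr("\\{R[0-9]\\}", tpl))[[1]]
  sort(unique(m), method = "radix")
}

## instantiate a template with substituents (named by slot; "" = hydrogen)
.instantiateTemplate <- function(tpl, subs) {
  out <- tpl
  for (slot in names(subs)) {
    pat <- paste0("(", slot, ")")
    rep <- if (nzchar(subs[[slot]])) paste0("(", subs[[slot]], ")") else ""
    out <- sub(pat, rep, out, fixed = TRUE)
  }
  out
}

#' Generate a publication-structured synthetic corpus
#'
#' Each simulated publication draws one template family and decorates its
#' template(s) with sampled substituent combinations, guaranteeing by
#' construction: within-publication matched pairs (single-substituent
#' edits), multi-edit similar pairs, shared-scaffold pairs, and
#' heteroatom-swapped generic-scaffold pairs. Properties come from
#' [syntheticOracle()]. Deterministic under the config seed.
#'
#' @param config a [fixtureConfig()].
#' @return data.frame with columns `smiles` (canonical), `publication_id`,
#'   `year`, `logd`, `solubility`, `clearance`, plus grammar metadata
#'   columns `family`, `template`, `r1`, `r2`, `r3`.
#' @export
generateCorpus <- function(config = fixtureConfig()) {
  stopifnot(inherits(config, "FixtureConfig"))
  .withSeed(config$seed, {
    rows <- list()
    for (p in seq_len(config$nPublications)) {
      famIdx <- sample(length(config$scaffoldTemplates), 1L)
      fam <- config$scaffoldTemplates[[famIdx]]
      famName <- names(config$scaffoldTemplates)[famIdx]
      ## a publication is one project: it anchors most substitution
      ## positions to project-specific decorations and explores a
      ## focused palette at the remaining position(s). This is what
      ## makes within-publication analogs property-coherent while
      ## same-scaffold molecules from other publications sit in
      ## different property regions
      allSlots <- .templateSlots(fam[1])
      varySlot <- sample(allSlots, 1L)
      series <- config$substituentFamilies[[
        sample(length(config$substituentFamilies), 1L)]]
      n <- sample(seq(config$moleculesPerPublication[1],
                      config$moleculesPerPublication[2]), 1L)
      ## all templates of the family are in play, so heteroatom-swapped
      ## generic-scaffold analogs exist in every publication
      tpls <- fam
      slotPalette <- list()
      for (sl in allSlots) {
        full <- c("", config$substituentAlphabet)
        if (sl == varySlot) {
          ## the project's systematic series at the varied position,
          ## padded only as far as the molecule count requires
          pal <- c("", series)
          extra <- setdiff(full, pal)
          while (length(pal) * length(tpls) < n && length(extra) > 0L) {
            pick <- sample(length(extra), 1L)
            pal <- c(pal, extra[pick]); extra <- extra[-pick]
          }
          slotPalette[[sl]] <- pal
        } else {
          ## project-specific fixed decoration
          slotPalette[[sl]] <- sample(full, 1L)
        }
      }
      capacity <- length(tpls) *
        prod(vapply(slotPalette[allSlots], length, integer(1)))
      n <- min(n, capacity)
      year <- sample(seq(config$yearRange[1], config$yearRange[2]), 1L)
      seen <- character(0)
      tries <- 0L
      while (length(seen) < n && tries < 40L * n) {
        tries <- tries + 1L
        tpl <- tpls[sample(length(tpls), 1L)]
        slots <- .templateSlots(tpl)
        subs <- setNames(vapply(slots, function(sl) {
          pal <- slotPalette[[sl]]
          pal[sample.int(length(pal), 1L)]
        }, character(1)), slots)
        raw <- .instantiateTemplate(tpl, subs)
        key <- paste(match(tpl, fam), paste(subs, collapse = "|"))
        if (key %in% seen) next
        seen <- c(seen, key)
        rows[[length(rows) + 1]] <- data.frame(
          raw = raw, publication_id = sprintf("PUB%04d", p),
          year = year, family = famName, template = tpl,
          r1 = if ("{R1}" %in% slots) subs[["{R1}"]] else NA_character_,
          r2 = if ("{R2}" %in% slots) subs[["{R2}"]] else NA_character_,
          r3 = if ("{R3}" %in% slots) subs[["{R3}"]] else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    df$smiles <- .obCanonical(df$raw)
    bad <- !nzchar(df$smiles)
    if (any(bad)) df <- df[!bad, , drop = FALSE]
    ## drop duplicate structures within a publication (heteroatom swap plus
    ## substituent choice can collide)
    df <- df[!duplicated(df[, c("publication_id", "smiles")]), , drop = FALSE]
    .precacheMolecules(unique(df$smiles))
    prof <- lapply(df$smiles, syntheticOracle)
    df$logd <- vapply(prof, `[[`, numeric(1), "logd")
    df$solubility <- vapply(prof, `[[`, numeric(1), "solubility")
    df$clearance <- vapply(prof, `[[`, numeric(1), "clearance")
    rownames(df) <- NULL
    df[, c("smiles", "publication_id", "year", "logd", "solubility",
           "clearance", "family", "template", "r1", "r2", "r3")]
  })
}

## parse many SMILES through one OpenBabel batch call and fill the
## molecule cache
.precacheMolecules <- function(smiles) {
  todo <- smiles[!vapply(smiles, function(s) !is.null(.molCache[[s]]),
                         logical(1))]
  todo <- unique(todo)
  if (length(todo) == 0L) return(invisible(NULL))
  sdf <- .obConvert("SMI", "SDF", paste0(paste(todo, collapse = "\n"), "\n"))
  recs <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  if (length(recs) != length(todo)) return(invisible(NULL))  # fall back lazy
  for (i in seq_along(todo)) {
    g <- tryCatch(.parseMolfile(recs[i]), error = function(e) NULL)
    if (is.null(g)) next
    obj <- new("CanonicalMolecule", smiles = todo[i],
               heavyAtomCount = length(g$elem),
               ringCount = as.integer(.ringCount(g)), graph = g)
    .molCache[[todo[i]]] <- obj
  }
  invisible(NULL)
}

## enumerate the full substituent space of one template, with oracle
## profiles; cached per (template, alphabet)
.templateSpace <- function(tpl, alphabet) {
  key <- paste0("space:", tpl, ":", paste(alphabet, collapse = ","))
  hit <- .molCache[[key]]
  if (!is.null(hit)) return(hit)
  slots <- .templateSlots(tpl)
  alphabet <- c("", alphabet)
  combos <- expand.grid(rep(list(alphabet), length(slots)),
                        stringsAsFactors = FALSE)
  names(combos) <- slots
  raw <- vapply(seq_len(nrow(combos)), function(i) {
    .instantiateTemplate(tpl, as.list(combos[i, , drop = FALSE]))
  }, character(1))
  can <- .obCanonical(raw)
  keep <- nzchar(can) & !duplicated(can)
  can <- can[keep]
  .precacheMolecules(can)
  prof <- lapply(can, syntheticOracle)
  space <- data.frame(smiles = can,
                      logd = vapply(prof, `[[`, numeric(1), "logd"),
                      solubility = vapply(prof, `[[`, numeric(1),
                                          "solubility"),
                      clearance = vapply(prof, `[[`, numeric(1),
                                         "clearance"))
  .molCache[[key]] <- space
  space
}

#' Exhaustive grammar truth for a starting molecule
#'
#' Enumerates every molecule expressible in the starting molecule's
#' template (all substituent combinations over the alphabet, hydrogen
#' included) and returns those whose oracle property deltas relative to
#' the start encode exactly to the requested property-change tokens.
#' This is the ground truth the trained generator is benchmarked
#' against.
#'
#' @param start starting molecule SMILES (must originate from `corpus`).
#' @param change a [PropertyChange-class].
#' @param corpus a corpus from [generateCorpus()] (carries the template
#'   metadata).
#' @param config the [fixtureConfig()] used to build the corpus.
#' @return character vector of reachable target SMILES (start excluded).
#' @export
grammarTruth <- function(start, change, corpus, config = fixtureConfig()) {
  stopifnot(is(change, "PropertyChange"))
  i <- match(start, corpus$smiles)
  if (is.na(i)) stop("start molecule is not part of the corpus grammar")
  tpl <- corpus$template[i]
  space <- .templateSpace(tpl, config$substituentAlphabet)
  src <- .profileOfRow(corpus, i)
  want <- propertyTokens(change)
  hits <- vapply(seq_len(nrow(space)), function(k) {
    if (space$smiles[k] == start) return(FALSE)
    got <- propertyTokens(propertyChange(src, .profileOfRow(space, k)))
    identical(got, want)
  }, logical(1))
  space$smiles[hits]
}
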