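test_that("building-block generator is deterministic, valid, and role-complete", {
  lib <- generateBuildingBlocks(100, seed = 4)
  expect_equal(length(lib), 100)
  smis <- blockSmiles(lib)
  expect_false(anyDuplicated(smis) > 0)
  expect_true(all(!is.na(canonicalSmiles(smis))))
  expect_true(all(blockTable(lib)$heavyAtoms <= 12))
  lib2 <- generateBuildingBlocks(100, seed = 4)
  expect_identical(blockTable(lib), blockTable(lib2))
  ## role-coverage census: >= 5 compatible blocks per reactant role
  roles <- unique(unlist(lapply(defaultReactions(), templateRoles)))
  for (r in roles) expect_gte(sum(matchesRole(smis, r)), 5)
  expect_error(generateBuildingBlocks(10), ">= 20")
})

test_that("the reaction repertoire parses and each template couples a worked pair", {
  tmpl <- defaultReactions()
  expect_length(tmpl, 4)
  for (tm in tmpl) expect_equal(templateArity(tm), 2L)
  pairs <- list(
    amide_coupling = c("CCC(=O)O", "NCc1ccccc1"),
    sulfonamide = c("c1ccccc1S(=O)(=O)Cl", "CCN"),
    reductive_amination = c("c1ccccc1C=O", "CCN"),
    suzuki_coupling = c("Clc1ccncc1", "OB(O)c1ccccc1")
  )
  for (tm in tmpl) {
    p <- applyTemplate(tm, pairs[[templateId(tm)]])
    expect_gte(length(p), 1)
  }
})

test_that("hits are distinct fragment-sized compounds with replayable routes", {
  fx <- sharedFixture()
  expect_length(fx$hits, 5)
  keys <- vapply(fx$hits, `[[`, character(1), "smiles")
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(descriptorTable(keys)$heavyAtoms <= 20))
  for (h in fx$hits)
    expect_equal(replayRoute(h$route, fx$templates), h$smiles)
  ## the fragment screen returns weak actives above the landscape floor
  v <- oracleValues(fx$oracles$affinity, keys)
  expect_true(all(v > fx$landscape@baseLevel))
  expect_true(all(v < 6))
})

test_that("the landscape peaks exactly at its optimum structure", {
  fx <- sharedFixture()
  land <- fx$landscape
  v <- oracleValues(fx$oracles$affinity, land@optimumSmiles)
  ## the optimum is cliff-free, so its value is exactly base + amplitude
  expect_equal(v, min(land@baseLevel + land@amplitude, land@dynamicRange[2]))
  expect_identical(designLandscape(fx$library, fx$templates, seed = 1)@optimumSmiles,
                   land@optimumSmiles)
})

## parent -> analog pairs within analog series of the hits and the landscape
## optimum: where structure-activity relationships live. Pairs that cross an
## activity-cliff motif are flagged (cliffs are the second, separately tested
## landscape property).
analogSeries <- function(nPerParent = 100) {
  if (!is.null(.testEnv$series)) return(.testEnv$series)
  fx <- sharedFixture()
  land <- fx$landscape
  cfgs <- list(ideationConfig(temperature = 0.25, nReplace = 1),
               ideationConfig(temperature = 0.6, nReplace = 1))
  st <- rngStreams(59)
  parents <- c(fx$hits,
               list(list(smiles = land@optimumSmiles, route = land@optimumRoute,
                         parents = character(0))))
  isCliff <- function(s) {
    out <- rep(FALSE, length(s))
    for (cl in land@cliffs) {
      cnt <- dmtaSim:::.motifCount(s, cl$smarts)
      out <- out | (!is.na(cnt) & cnt > 0)
    }
    out
  }
  aff <- fx$oracles$affinity
  rows <- data.frame()
  pools <- list()
  pi <- 0
  while (pi < length(parents)) {
    pi <- pi + 1
    h <- parents[[pi]]
    analogs <- list()
    for (cfg in cfgs) {
      drawn <- 0
      while (drawn < nPerParent) {
        more <- replaceReactants(h, fx$library, cfg, fx$templates, st, nAnalogs = 8)
        if (!length(more)) break
        analogs <- c(analogs, more)
        drawn <- drawn + length(more)
      }
    }
    analogs <- Filter(function(a) !identical(a$smiles, h$smiles), analogs)
    analogs <- analogs[!duplicated(vapply(analogs, `[[`, character(1), "smiles"))]
    ks <- vapply(analogs, `[[`, character(1), "smiles")
    vp <- oracleValues(aff, h$smiles)
    va <- oracleValues(aff, ks)
    pfp <- morganBits(h$smiles)
    ok <- !is.na(va)
    rows <- rbind(rows, data.frame(
      fam = pi,
      dfp = vapply(ks[ok], function(s) 1 - tanimoto(morganBits(s), pfp),
                   numeric(1), USE.NAMES = FALSE),
      da = abs(va[ok] - vp),
      cliffCross = xor(isCliff(ks[ok]), isCliff(h$smiles))))
    pools[[pi]] <- c(h$smiles, ks)
    ## grow the audit with a second generation: the best analog of each of
    ## the first two hit series becomes a parent series of its own
    if (pi <= 2 && length(parents) < length(fx$hits) + 3) {
      best <- ks[ok][which.max(va[ok])]
      rec <- Filter(function(a) identical(a$smiles, best), analogs)[[1]]
      parents[[length(parents) + 1]] <- list(smiles = best, route = rec$route,
                                             parents = character(0))
    }
  }
  .testEnv$series <- list(pairs = rows, pools = pools)
  .testEnv$series
}

test_that("the landscape exhibits structure-activity relationships", {
  d <- analogSeries()$pairs
  d <- d[!d$cliffCross, ]
  expect_gte(nrow(d), 300)
  ## within-series rank association (parents differ in baseline potency)
  rdfp <- ave(d$dfp, d$fam, FUN = rank)
  rda <- ave(d$da, d$fam, FUN = rank)
  expect_gt(stats::cor(rdfp, rda, method = "spearman"), 0.3)
})

test_that("the landscape contains activity cliffs", {
  fx <- sharedFixture()
  aff <- fx$oracles$affinity
  ## among a few hundred related analogs, a near-identical pair (Tanimoto
  ## > 0.85) with a potency gap >= 1.5 log units must exist
  pool <- unique(unlist(analogSeries()$pools))
  expect_gte(length(pool), 100)
  v <- oracleValues(aff, pool)
  fps <- lapply(pool, morganBits)
  found <- FALSE
  for (i in seq_along(pool)) {
    if (found) break
    for (j in seq_len(i - 1L)) {
      if (is.na(v[i]) || is.na(v[j])) next
      if (abs(v[i] - v[j]) >= 1.5 && tanimoto(fps[[i]], fps[[j]]) > 0.85) {
        found <- TRUE; break
      }
    }
  }
  expect_true(found)
})

test_that("fixture files round-trip through the standard input formats", {
  fx <- sharedFixture()
  dir <- tempfile()
  writeFixture(fx, dir)
  lib <- loadCatalog(file.path(dir, "catalog.csv"))
  expect_equal(blockSmiles(lib), blockSmiles(fx$library))
  tmpl <- readReactionTemplates(file.path(dir, "reactions.txt"))
  expect_length(tmpl, 4)
  hits <- readHitsFile(file.path(dir, "hits.smi"))
  expect_equal(hits, vapply(fx$hits, `[[`, character(1), "smiles"))
  land <- jsonlite::read_json(file.path(dir, "landscape.json"))
  expect_equal(land$baseLevel, fx$landscape@baseLevel)
})
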