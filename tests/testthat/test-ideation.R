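test_that("similarity ranking matches a brute-force Tanimoto sort", {
  fx <- sharedFixture()
  lib <- fx$library
  sub <- blockTable(lib)[1:20, ]
  small <- buildLibrary(sub$blockId, sub$smiles)
  ref <- sub$smiles[7]
  ranked <- similarityRank(ref, small)
  ## brute force: pairwise Tanimoto, sort desc with id tie-break
  rfp <- morganBits(ref)
  sims <- vapply(blockSmiles(small), function(s) tanimoto(morganBits(s), rfp),
                 numeric(1), USE.NAMES = FALSE)
  ord <- order(-sims, blockIds(small))
  expect_equal(ranked$blockId, blockIds(small)[ord])
  expect_equal(ranked$similarity, sims[ord])
  ## reference present in the library ranks first at similarity 1
  expect_equal(ranked$smiles[1], ref)
  expect_equal(ranked$similarity[1], 1)
})

test_that("fingerprints: self-similarity 1, disjoint 0, bitwise determinism", {
  a <- morganBits("CCO")
  expect_equal(tanimoto(a, morganBits("CCO")), 1)
  expect_equal(tanimoto(morganBits("C"), morganBits("O")), 0)
  clearChemCache()
  expect_identical(a, morganBits("CCO"))
})

test_that("Boltzmann limits: T = 0 is exact top-k; huge T is uniform", {
  ranked <- data.frame(blockId = sprintf("b%02d", 1:10),
                       smiles = rep("C", 10),
                       similarity = seq(1, 0.1, by = -0.1), idx = 1:10)
  top <- boltzmannSample(ranked, 0, 2)
  expect_equal(top$blockId, c("b01", "b02"))
  ## equal-similarity groups at huge T: frequencies within 3 sigma multinomial
  eq <- data.frame(blockId = c("a", "b", "c", "d"), smiles = "C",
                   similarity = 0.5, idx = 1:4)
  set.seed(42)
  draws <- replicate(10000, boltzmannSample(eq, Inf, 1)$blockId[1])
  tab <- table(factor(draws, levels = eq$blockId))
  expect_true(all(abs(tab - 2500) <= 3 * sqrt(10000 * 0.25 * 0.75)))
  ## seeded determinism
  s1 <- rngStreams(7); s2 <- rngStreams(7)
  expect_identical(boltzmannSample(ranked, 0.1, 3, s1),
                   boltzmannSample(ranked, 0.1, 3, s2))
  expect_error(boltzmannSample(ranked, 0.1, 11), "k must be")
})

test_that("identity replacement emerges at T = 0 when the original block is in the library", {
  fx <- sharedFixture()
  hit <- fx$hits[[1]]
  cfg <- ideationConfig(temperature = 0, nReplace = 1)
  out <- replaceReactants(hit, fx$library, cfg, fx$templates,
                          streams = rngStreams(3), nAnalogs = 2)
  ## the most similar replacement for some position is the original block
  ## itself, so the parent structure is among the top analogs
  expect_true(hit$smiles %in% vapply(out, `[[`, character(1), "smiles"))
})

test_that("all-replacement swaps every block position", {
  fx <- sharedFixture()
  hit <- fx$hits[[1]]
  pos <- nrow(dmtaSim:::.routeBlockPositions(hit$route))
  expect_gte(pos, 2)
  cfg <- ideationConfig(temperature = 0.5, nReplace = Inf)
  out <- replaceReactants(hit, fx$library, cfg, fx$templates,
                          streams = rngStreams(11), nAnalogs = 3)
  for (an in out) expect_length(an$blocks, pos)
})

test_that("emitted analog routes replay to the emitted structure", {
  fx <- sharedFixture()
  cfg <- ideationConfig(temperature = 0.3)
  cache <- new.env(parent = emptyenv())
  out <- ideateBatch(fx$hits, fx$library, fx$templates, cfg, cache,
                     streams = rngStreams(5))
  expect_gt(length(out), 0)
  for (an in out) expect_equal(replayRoute(an$route, fx$templates), an$smiles)
})

test_that("the ideation cache prevents re-emitting known structures", {
  fx <- sharedFixture()
  cfg <- ideationConfig(temperature = 0.2)
  cache <- new.env(parent = emptyenv())
  first <- ideateBatch(fx$hits, fx$library, fx$templates, cfg, cache,
                       streams = rngStreams(9))
  second <- ideateBatch(fx$hits, fx$library, fx$templates, cfg, cache,
                        streams = rngStreams(9))
  k1 <- vapply(first, `[[`, character(1), "smiles")
  k2 <- vapply(second, `[[`, character(1), "smiles")
  expect_false(any(k2 %in% k1))
  expect_false(anyDuplicated(k1) > 0)
  ## lineage bookkeeping: every record names its parent
  hitKeys <- vapply(fx$hits, `[[`, character(1), "smiles")
  for (an in first) expect_true(an$parents %in% hitKeys)
})

test_that("growth adds atoms and respects the block size cap", {
  fx <- sharedFixture()
  ## a parent with a free primary amine: couple an acid to a diamine
  tab <- blockTable(fx$library)
  amide <- Filter(function(t) templateId(t) == "amide_coupling", fx$templates)[[1]]
  p <- applyTemplate(amide, c("CC(=O)O", "NCCCN"))[1]
  expect_true(matchesRole(p, "amine"))
  hit <- list(smiles = p,
              route = syntheticRoute(list(list(
                template = "amide_coupling",
                reactants = list(blockRef("x1", "CC(=O)O"), blockRef("x2", "NCCCN")),
                product = p))),
              parents = character(0))
  cfg <- ideationConfig(growthMaxHeavyAtoms = 10)
  out <- growCompound(hit, fx$library, cfg, fx$templates,
                      streams = rngStreams(13), nAnalogs = 5)
  expect_gt(length(out), 0)
  ha <- function(s) descriptorTable(s)$heavyAtoms
  for (an in out) expect_gt(ha(an$smiles), ha(hit$smiles))
  ## a cap below every block size yields nothing
  cfg0 <- ideationConfig(growthMaxHeavyAtoms = 0)
  expect_length(growCompound(hit, fx$library, cfg0, fx$templates,
                             streams = rngStreams(13), nAnalogs = 3), 0)
})

test_that("analog similarity to the parent decreases with temperature", {
  fx <- sharedFixture()
  hit <- fx$hits[[2]]
  pfp <- morganBits(hit$smiles)
  meanSim <- function(Tv, n = 200) {
    cfg <- ideationConfig(temperature = Tv, nReplace = 1)
    sims <- c()
    st <- rngStreams(101)
    while (length(sims) < n) {
      out <- replaceReactants(hit, fx$library, cfg, fx$templates, st,
                              nAnalogs = 8)
      sims <- c(sims, vapply(out, function(an)
        tanimoto(morganBits(an$smiles), pfp), numeric(1)))
    }
    mean(sims[seq_len(n)])
  }
  ms <- vapply(c(0, 0.04, 0.16, 0.64, Inf), meanSim, numeric(1))
  ## non-increasing within sampling tolerance
  expect_true(all(diff(ms) <= 0.03))
  expect_lt(ms[5], ms[1])
})

test_that("more replaced reactants give more dissimilar analogs", {
  fx <- sharedFixture()
  hit <- fx$hits[[2]]
  pfp <- morganBits(hit$smiles)
  meanDis <- function(nr, n = 200) {
    cfg <- ideationConfig(temperature = 0.16, nReplace = nr)
    dis <- c()
    st <- rngStreams(103)
    while (length(dis) < n) {
      out <- replaceReactants(hit, fx$library, cfg, fx$templates, st,
                              nAnalogs = 8)
      dis <- c(dis, vapply(out, function(an)
        1 - tanimoto(morganBits(an$smiles), pfp), numeric(1)))
    }
    mean(dis[seq_len(n)])
  }
  expect_gte(meanDis(Inf), meanDis(1) - 0.03)
})
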