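test_that("reset makes and tests the hits against the budget", {
  fx <- sharedFixture()
  cfg <- testConfig(budget = 100, seed = 2)
  st <- campaignReset(cfg, fx$hits)
  expect_equal(st$made, 5L)
  expect_true(all(st$status == "tested"))
  expect_true(all(st$cycleTested == 0L))
  expect_true(all(is.finite(st$measured)))
  expect_false(st$terminated)
})

test_that("a hit already satisfying the TCP succeeds at cycle 0", {
  fx <- sharedFixture()
  easy <- tcp(list(
    objectiveSpec("affinity", "pIC50", c(0, Inf), c(0, Inf), c(3, 11)),
    objectiveSpec("lipophilicity", "Log P", c(-20, 20), c(-20, 20), c(-1, 8)),
    objectiveSpec("solubility", "Log S", c(-20, 20), c(-20, 20), c(-8, 1))
  ))
  cfg <- campaignConfig(easy, fx$oracles, budget = 100, seed = 2)
  res <- runCampaign(cfg, fx$hits, fx$library, fx$templates)
  expect_true(res@success)
  expect_equal(res@cycles, 0)
  expect_equal(res@moleculesMade, 5)
})

test_that("budget exhausted by the hits alone is an immediate failure", {
  fx <- sharedFixture()
  cfg <- testConfig(budget = 5, batchSize = 3, seed = 2)
  res <- runCampaign(cfg, fx$hits, fx$library, fx$templates)
  expect_false(res@success)
  expect_equal(res@moleculesMade, 5)
  expect_equal(res@monetaryCost, 5 * 3000)
  expect_equal(res@cycles, 0)
})

test_that("the final batch is truncated to the remaining budget", {
  fx <- sharedFixture()
  cfg <- testConfig(budget = 12, batchSize = 8, seed = 2)
  res <- runCampaign(cfg, fx$hits, fx$library, fx$templates)
  expect_lte(res@moleculesMade, 12)
  if (!res@success) expect_equal(res@moleculesMade, 12)
  ## made in cycle 1: min(8, 12 - 5) = 7
  cyc1 <- Filter(function(e) identical(e$event, "cycle") && e$cycle == 1, res@events)[[1]]
  expect_equal(cyc1$made, 7L)
})

test_that("scoring-ratio semantics: ratio x batch candidates scored per cycle", {
  fx <- sharedFixture()
  ## scoring 20 molecules for every one tested
  cfg <- testConfig(budget = 60, batchSize = 2, scoringRatio = 20, seed = 3)
  st <- campaignReset(cfg, fx$hits)
  runCycle(st, cfg, fx$library, fx$templates)
  ev <- st$events[[length(st$events)]]
  expect_equal(ev$scored, 40L)
  expect_equal(ev$made, 2L)
  expect_equal(st$scored, 40L)
  ## the quota is an upper bound when the reachable neighborhood is smaller
  cfg2 <- testConfig(budget = 60, batchSize = 5, scoringRatio = 20, seed = 3)
  st2 <- campaignReset(cfg2, fx$hits)
  runCycle(st2, cfg2, fx$library, fx$templates)
  ev2 <- st2$events[[length(st2$events)]]
  expect_lte(ev2$scored, 100L)
  expect_equal(ev2$made, 5L)
})

test_that("campaigns are exactly reproducible for a fixed seed", {
  fx <- sharedFixture()
  cfg <- testConfig(budget = 30, seed = 19)
  r1 <- runCampaign(cfg, fx$hits, fx$library, fx$templates)
  r2 <- runCampaign(cfg, fx$hits, fx$library, fx$templates)
  expect_identical(r1@ledger, r2@ledger)
  expect_identical(r1@events, r2@events)
  expect_identical(r1@success, r2@success)
})

test_that("ledger invariants: budget conservation and status monotonicity", {
  fx <- sharedFixture()
  cfg <- testConfig(budget = 40, seed = 23)
  res <- runCampaign(cfg, fx$hits, fx$library, fx$templates)
  led <- res@ledger
  expect_equal(res@moleculesMade, sum(!is.na(led$cycleMade)))
  expect_lte(res@moleculesMade, 40)
  ## tested implies made; made implies ideated
  expect_true(all(!is.na(led$cycleMade[led$status == "tested"])))
  expect_true(all(is.na(led$measured_affinity[led$status == "ideated"])))
  expect_false(anyDuplicated(led$key) > 0)
  expect_equal(res@monetaryCost, res@moleculesMade * 3000)
})

test_that("every made molecule's route replays to its structure", {
  fx <- sharedFixture()
  cfg <- testConfig(budget = 40, seed = 29)
  res <- runCampaign(cfg, fx$hits, fx$library, fx$templates)
  led <- res@ledger
  made <- which(!is.na(led$cycleMade) & led$op != "hit")
  expect_gt(length(made), 0)
  for (i in made)
    expect_equal(replayRoute(res@routes[[i]], fx$templates), led$key[i])
})

test_that("a successful campaign's lineage connects a hit to the lead", {
  fx <- sharedFixture()
  cfg <- testConfig(budget = 80, sigmas = c(affinity = 0.5), seed = 31)
  res <- runCampaign(cfg, fx$hits, fx$library, fx$templates)
  expect_true(res@success)
  g <- lineageGraph(res)
  expect_true(igraph::is_dag(g))
  deg <- igraph::degree(g, mode = "in")
  hitKeys <- res@ledger$key[res@ledger$op == "hit"]
  expect_true(all(deg[hitKeys] == 0))
  nonhit <- setdiff(names(deg), hitKeys)
  expect_true(all(deg[nonhit] >= 1))
  up <- igraph::subcomponent(g, res@successKey, mode = "in")
  expect_true(any(hitKeys %in% names(up)))
  ## the success record re-passes the TCP on fresh ground-truth calls
  vals <- lapply(fx$oracles, function(o) oracleValues(o, res@successKey))
  expect_true(tcpSatisfied(vals, fx$tcp))
})

test_that("campaign results serialize to disk in standard formats", {
  fx <- sharedFixture()
  cfg <- testConfig(budget = 30, seed = 37)
  res <- runCampaign(cfg, fx$hits, fx$library, fx$templates)
  dir <- tempfile()
  writeCampaignResult(res, dir)
  expect_true(file.exists(file.path(dir, "summary.json")))
  s <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(s$moleculesMade, res@moleculesMade)
  led <- read.csv(file.path(dir, "ledger.csv"))
  expect_equal(nrow(led), nrow(res@ledger))
  expect_true(file.exists(file.path(dir, "lineage.csv")))
  expect_true(file.exists(file.path(dir, "events.jsonl")))
})

test_that("campaign configs round-trip through YAML", {
  fx <- sharedFixture()
  cfg <- testConfig(budget = 44, batchSize = 11, scoringRatio = 4, seed = 77,
                    sigmas = c(affinity = 1.25))
  f <- tempfile(fileext = ".yaml")
  writeCampaignConfig(cfg, f)
  back <- readCampaignConfig(f, fx$oracles)
  expect_equal(back@budget, 44)
  expect_equal(back@batchSize, 11)
  expect_equal(back@scoringRatio, 4)
  expect_equal(back@seed, 77)
  expect_equal(unname(back@sigmas["affinity"]), 1.25)
  expect_equal(back@tcp@objectives[[1]]@acceptable, cfg@tcp@objectives[[1]]@acceptable)
})
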