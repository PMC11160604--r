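## Shared test fixtures (built once per test run).

.testEnv <- new.env(parent = emptyenv())

## the package's standard desk-scale study conditions
sharedFixture <- function() {
  if (is.null(.testEnv$fx)) .testEnv$fx <- defaultFixture(seed = 1)
  .testEnv$fx
}

## a seeded sample of distinct one-step products of the fixture space
probeProducts <- function(n, seed = 99) {
  key <- paste0("probes", n, "_", seed)
  if (!is.null(.testEnv[[key]])) return(.testEnv[[key]])
  fx <- sharedFixture()
  tab <- blockTable(fx$library)
  set.seed(seed)
  ps <- character(0)
  tries <- 0
  while (length(ps) < n && tries < n * 30) {
    tries <- tries + 1
    tm <- fx$templates[[sample.int(length(fx$templates), 1)]]
    a <- which(matchesRole(tab$smiles, tm@roles[1]))
    b <- which(matchesRole(tab$smiles, tm@roles[2]))
    pr <- applyTemplate(tm, c(tab$smiles[sample(a, 1)], tab$smiles[sample(b, 1)]))
    if (length(pr)) ps <- unique(c(ps, pr[1]))
  }
  .testEnv[[key]] <- ps
  ps
}

## a small campaign config over the shared fixture
testConfig <- function(..., sigmas = c(affinity = 1)) {
  fx <- sharedFixture()
  campaignConfig(fx$tcp, fx$oracles, sigmas = sigmas, ...)
}

## a minimal CampaignResult for econometrics unit tests
fakeResult <- function(success, made, cycles = made / 8, scored = 0) {
  fx <- sharedFixture()
  cfg <- testConfig(budget = 1000)
  new("CampaignResult", success = success, successKey = NA_character_,
      moleculesMade = made, moleculesScored = scored, cycles = cycles,
      monetaryCost = made * 3000,
      ledger = data.frame(key = character(0)), routes = list(),
      lineage = data.frame(parent = character(0), child = character(0)),
      events = list(), config = cfg)
}

## monotonicity check with binomial sampling tolerance: rates must follow
## `direction` ("dec" or "inc"), allowing at most one adjacent inversion whose
## size is within the 95% interval of the difference of two proportions
expect_monotone_rates <- function(rates, n, direction = c("dec", "inc")) {
  direction <- match.arg(direction)
  d <- diff(rates)
  viol <- if (direction == "dec") which(d > 0) else which(d < 0)
  expect_lte(length(viol), 1)
  for (v in viol) {
    p1 <- rates[v]; p2 <- rates[v + 1]
    se <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
    expect_lte(abs(d[v]), 1.96 * se + 1e-9)
  }
  invisible(rates)
}

## brute-force domination oracle, independent of the implementation
bruteFronts <- function(u) {
  n <- nrow(u)
  front <- rep(NA_integer_, n)
  left <- seq_len(n); k <- 0L
  while (length(left)) {
    keep <- c()
    for (i in left) {
      dominated <- FALSE
      for (j in left) {
        if (i == j) next
        if (all(u[j, ] >= u[i, ]) && any(u[j, ] > u[i, ])) { dominated <- TRUE; break }
      }
      if (!dominated) keep <- c(keep, i)
    }
    front[keep] <- k
    left <- setdiff(left, keep)
    k <- k + 1L
  }
  front
}
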