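## Ensemble runner and cross-trial statistics: success CDFs, success rate at
## budget, expected costs with bootstrap intervals, the exponential
## cost-versus-model-error fit, breakeven model value, and progress-normalized
## property trajectories.

#' Run an ensemble of independent campaigns
#'
#' Trial `i` runs with a seed derived from `(baseSeed, i)`; results are
#' independent of execution order. A trial that errors is recorded as `NULL`
#' with a warning and excluded from statistics.
#'
#' @param config a [CampaignConfig-class] (its `seed` is overridden per trial).
#' @param hits starting hits.
#' @param library a [BlockLibrary-class].
#' @param nTrials number of trials (>= 1).
#' @param baseSeed base seed.
#' @param templates reaction repertoire.
#' @return list of [CampaignResult-class] (errored trials dropped).
#' @export
runEnsemble <- function(config, hits, library, nTrials, baseSeed = 1,
                        templates = defaultReactions()) {
  stopifnot(nTrials >= 1)
  out <- vector("list", nTrials)
  for (i in seq_len(nTrials)) {
    cfg <- config
    cfg@seed <- .mixSeed(baseSeed, 1000 + i)
    out[[i]] <- tryCatch(runCampaign(cfg, hits, library, templates),
                         error = function(e) {
                           warning("trial ", i, " errored: ", conditionMessage(e))
                           NULL
                         })
  }
  Filter(Negate(is.null), out)
}

#' Success CDF over a resource axis
#'
#' `CDF(b)` = fraction of all trials that succeeded at a resource cost
#' `<= b`. Failed trials are right-censored: they never count at any budget,
#' so the CDF plateaus at the overall success fraction.
#'
#' @param results list of [CampaignResult-class].
#' @param axis `"moleculesMade"` (default) or `"cycles"`.
#' @return a function `f(b)`; attribute `"table"` holds the step points.
#' @export
successCDF <- function(results, axis = c("moleculesMade", "cycles")) {
  axis <- match.arg(axis)
  stopifnot(length(results) >= 1)
  n <- length(results)
  cost <- vapply(results, function(r)
    if (r@success) methods::slot(r, axis) else Inf, numeric(1))
  xs <- sort(unique(cost[is.finite(cost)]))
  ys <- vapply(xs, function(b) sum(cost <= b) / n, numeric(1))
  f <- function(b) vapply(b, function(bb) sum(cost <= bb) / n, numeric(1))
  attr(f, "table") <- data.frame(cost = xs, cdf = ys)
  attr(f, "n") <- n
  f
}

#' Success rate at a budget
#'
#' @param results list of [CampaignResult-class].
#' @param budget resource bound.
#' @param axis resource axis (see [successCDF()]).
#' @return fraction of trials succeeding within `budget`.
#' @export
successRateAtBudget <- function(results, budget, axis = "moleculesMade") {
  successCDF(results, axis)(budget)
}

#' Expected cost to reach a target success rate
#'
#' The smallest resource level `b` with `CDF(b) >= targetRate`, with a seeded
#' bootstrap percentile interval over trials. Unattainable rates (above the
#' CDF plateau) return `NA` cost with `attainable = FALSE` -- never an
#' extrapolation.
#'
#' @param results list of [CampaignResult-class].
#' @param targetRate required success rate in (0, 1].
#' @param axis resource axis.
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return list: `cost`, `attainable`, `ci` (95% percentile interval).
#' @export
expectedCostAtRate <- function(results, targetRate, axis = "moleculesMade",
                               nBoot = 1000, seed = 1) {
  n <- length(results)
  cost <- vapply(results, function(r)
    if (r@success) methods::slot(r, axis) else Inf, numeric(1))
  pointCost <- function(cc) {
    cands <- sort(cc[is.finite(cc)])
    for (b in cands) if (sum(cc <= b) / length(cc) >= targetRate) return(b)
    NA_real_
  }
  pt <- pointCost(cost)
  if (is.na(pt))
    return(list(cost = NA_real_, attainable = FALSE, ci = c(NA_real_, NA_real_)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.mixSeed(seed, 7), kind = "Mersenne-Twister")
  bs <- vapply(seq_len(nBoot), function(b)
    pointCost(cost[sample.int(n, n, replace = TRUE)]), numeric(1))
  ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(cost = pt, attainable = TRUE, ci = ci)
}

#' Median molecules made among successful trials
#'
#' The 50th percentile of the resource cost over successful trials, the cost
#' summary used for breakeven-value arithmetic.
#'
#' @param results list of [CampaignResult-class].
#' @param axis resource axis.
#' @return numeric (NA when no trial succeeded).
#' @export
medianSuccessCost <- function(results, axis = "moleculesMade") {
  cost <- vapply(results, function(r)
    if (r@success) methods::slot(r, axis) else NA_real_, numeric(1))
  if (!any(is.finite(cost))) return(NA_real_)
  stats::median(cost, na.rm = TRUE)
}

#' Fit the exponential cost-versus-model-error model
#'
#' Least squares of `log(cost) = log(a) + k * sigma`, i.e.
#' `cost(sigma) = a * exp(k * sigma)`. Goodness of fit (R-squared and MAE) is
#' reported on the natural (molecules) scale. Non-positive costs are excluded
#' with a warning; at least 3 usable points are required.
#'
#' @param sigma numeric vector of model-error levels.
#' @param cost numeric vector of costs (molecules made) at a fixed success
#'   rate.
#' @return list: `a`, `k`, `r2`, `mae`, `fitted`, `points`.
#' @export
fitCostModel <- function(sigma, cost) {
  stopifnot(length(sigma) == length(cost))
  ok <- is.finite(sigma) & is.finite(cost) & cost > 0
  if (any(!ok)) warning("excluded ", sum(!ok), " non-positive/missing point(s)")
  sigma <- sigma[ok]; cost <- cost[ok]
  if (length(sigma) < 3) stop("need at least 3 usable (sigma, cost) points")
  fit <- stats::lm(log(cost) ~ sigma)
  a <- exp(unname(stats::coef(fit)[1]))
  k <- unname(stats::coef(fit)[2])
  fitted <- a * exp(k * sigma)
  ss <- sum((cost - fitted)^2)
  tot <- sum((cost - mean(cost))^2)
  r2 <- if (tot > 0) 1 - ss / tot else 1
  list(a = a, k = k, r2 = r2, mae = mean(abs(cost - fitted)),
       fitted = fitted, points = data.frame(sigma = sigma, cost = cost))
}

#' Breakeven value of a scoring model, per calculation
#'
#' `(costNoModel - costWithModel) * costPerCompound / nScored`: the monetary
#' savings a model delivers per scoring calculation, which is also the
#' breakeven price of one calculation. Inputs are 50th-percentile
#' molecules-made counts; the value may be negative (a harmful model).
#'
#' @param costNoModel median molecules made without the scoring model.
#' @param costWithModel median molecules made with it.
#' @param costPerCompound dollars to make and test one molecule.
#' @param nScored number of scoring calculations performed.
#' @return dollars per calculation.
#' @export
breakevenValue <- function(costNoModel, costWithModel, costPerCompound, nScored) {
  if (is.na(nScored) || nScored <= 0) stop("nScored must be > 0")
  (costNoModel - costWithModel) * costPerCompound / nScored
}

#' Progress-normalized make order
#'
#' The m-th molecule made of M total sits at progress `100 * m / M` percent,
#' making campaigns of different lengths comparable.
#'
#' @param result a [CampaignResult-class].
#' @return data.frame `key`, `makeOrder`, `progress` over made molecules.
#' @export
progressNormalize <- function(result) {
  led <- result@ledger
  made <- led[!is.na(led$cycleMade), , drop = FALSE]
  ## make order: by cycle made, then ledger (selection) order within a cycle
  ord <- order(made$cycleMade, seq_len(nrow(made)))
  made <- made[ord, , drop = FALSE]
  M <- nrow(made)
  data.frame(key = made$key, makeOrder = seq_len(M),
             progress = 100 * seq_len(M) / M, stringsAsFactors = FALSE)
}

#' Property trajectories over campaign progress
#'
#' Bins made molecules by progress percentage (pooled across trials) and
#' reports per-bin means of the TCP objectives and standard drug-likeness
#' descriptors: pIC50, Log P, Log S, heavy atoms, rings, rings per 1000
#' atoms, fraction Csp3, QED, ligand efficiency (LE = pIC50 / heavy atoms)
#' and lipophilic efficiency (LipE = pIC50 - Log P).
#'
#' @param results list of [CampaignResult-class].
#' @param bins number of progress bins (default 10).
#' @return data.frame, one row per bin with descriptor means; empty bins give
#'   `NA`.
#' @export
propertyTrajectories <- function(results, bins = 10) {
  rows <- do.call(rbind, lapply(results, function(r) {
    pn <- progressNormalize(r)
    led <- r@ledger
    m <- led[match(pn$key, led$key), , drop = FALSE]
    data.frame(progress = pn$progress, key = pn$key,
               pIC50 = m$measured_affinity,
               logP = m$measured_lipophilicity,
               logS = m$measured_solubility, stringsAsFactors = FALSE)
  }))
  d <- descriptorTable(rows$key)
  rows$heavyAtoms <- d$heavyAtoms
  rows$rings <- d$ringCount
  rows$ringsPer1000 <- 1000 * d$ringCount / d$heavyAtoms
  rows$fracCsp3 <- d$fracCsp3
  rows$qed <- d$qed
  rows$LE <- rows$pIC50 / d$heavyAtoms
  rows$LipE <- rows$pIC50 - rows$logP
  edges <- seq(0, 100, length.out = bins + 1)
  rows$bin <- cut(rows$progress, edges, include.lowest = TRUE, labels = FALSE)
  metrics <- c("pIC50", "logP", "logS", "heavyAtoms", "rings", "ringsPer1000",
               "fracCsp3", "qed", "LE", "LipE")
  out <- data.frame(bin = seq_len(bins),
                    progressLo = edges[-length(edges)], progressHi = edges[-1])
  for (mcol in metrics) {
    out[[mcol]] <- vapply(seq_len(bins), function(b) {
      v <- rows[[mcol]][rows$bin == b]
      if (!length(v)) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  out$n <- vapply(seq_len(bins), function(b) sum(rows$bin == b), numeric(1))
  out
}
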