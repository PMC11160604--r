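## The DMTA loop: Design -> Make -> Test -> Analyze, with the budget race.
##
## Design ideates scoring_ratio x batch_size candidates from the current
## top-utility tested molecules, scores them with noisy oracles,
## bias-corrects, and selects a batch by Pareto-front scalarization with
## epsilon-greedy exploration. Make marks the batch synthesized (depleting
## the budget), Test measures it with noiseless oracles, and Analyze lets
## measurements supplant predictions, refits the bias model, and checks the
## TCP. A campaign succeeds when a tested molecule satisfies the TCP before
## the budget is exhausted.

#' Campaign configuration
#'
#' @slot tcp the [TCP-class] objectives.
#' @slot ideation an [IdeationConfig-class].
#' @slot policy a [SelectionPolicy-class].
#' @slot oracles named list of ground-truth [Oracle-class], one per TCP
#'   objective.
#' @slot sigmas named numeric, Gaussian model error per objective.
#' @slot scoringRatio molecules scored per molecule tested (>= 1).
#' @slot batchSize molecules made per cycle.
#' @slot budget maximum molecules made.
#' @slot costPerCompound monetary cost to make and test one molecule.
#' @slot maxCycles safety cap on DMTA cycles.
#' @slot parentPool number of top-utility tested molecules used as parents.
#' @slot stallLimit consecutive empty ideations before failure.
#' @slot useModel score-and-select with the predictive model (FALSE = the
#'   no-scoring-model baseline: random selection among ideated candidates).
#' @slot frozenNoise freeze one noise draw per molecule.
#' @slot seed master RNG seed.
#' @export
setClass("CampaignConfig",
  representation(tcp = "TCP", ideation = "IdeationConfig",
                 policy = "SelectionPolicy", oracles = "list",
                 sigmas = "numeric", scoringRatio = "numeric",
                 batchSize = "numeric", budget = "numeric",
                 costPerCompound = "numeric", maxCycles = "numeric",
                 parentPool = "numeric", stallLimit = "numeric",
                 useModel = "logical", frozenNoise = "logical",
                 seed = "numeric"))

setValidity("CampaignConfig", function(object) {
  if (object@batchSize < 1) return("batchSize must be >= 1")
  if (object@budget < object@batchSize) return("budget must be >= batchSize")
  if (object@scoringRatio < 1) return("scoringRatio must be >= 1")
  obj <- objectiveNames(object@tcp)
  if (!all(obj %in% names(object@oracles)))
    return(paste("missing oracle(s) for objective(s):",
                 paste(setdiff(obj, names(object@oracles)), collapse = ", ")))
  TRUE
})

setMethod("show", "CampaignConfig", function(object) {
  cat(sprintf("CampaignConfig: budget %g made (batch %g, scoring ratio %g), seed %g\n",
              object@budget, object@batchSize, object@scoringRatio, object@seed))
  cat(sprintf("  sigmas: %s; epsilon %g; %s\n",
              paste(sprintf("%s=%g", names(object@sigmas), object@sigmas), collapse = ", "),
              object@policy@epsilon,
              if (object@useModel) "model-guided selection" else "no scoring model"))
})

#' Create a campaign configuration
#'
#' @param tcp a [TCP-class].
#' @param oracles named list of ground-truth [Oracle-class] covering the
#'   TCP's objectives.
#' @param sigmas named numeric of per-objective model error SDs (missing
#'   objectives default to 0).
#' @param ideation an [IdeationConfig-class].
#' @param policy a [SelectionPolicy-class].
#' @param scoringRatio molecules scored per molecule tested (default 5).
#' @param batchSize molecules made per cycle (default 8).
#' @param budget maximum molecules made (default 120).
#' @param costPerCompound dollars to make and test one molecule
#'   (default 3000).
#' @param maxCycles cycle cap (default 200).
#' @param parentPool parents per Design step (default 5).
#' @param stallLimit consecutive stalled cycles before failure (default 3).
#' @param useModel FALSE for the no-scoring-model baseline.
#' @param frozenNoise freeze noise per molecule (default FALSE).
#' @param seed master seed.
#' @return a [CampaignConfig-class].
#' @export
campaignConfig <- function(tcp, oracles, sigmas = numeric(0),
                           ideation = ideationConfig(),
                           policy = selectionPolicy(),
                           scoringRatio = 5, batchSize = 8, budget = 120,
                           costPerCompound = 3000, maxCycles = 200,
                           parentPool = 5, stallLimit = 3, useModel = TRUE,
                           frozenNoise = FALSE, seed = 1) {
  obj <- objectiveNames(tcp)
  s <- stats::setNames(rep(0, length(obj)), obj)
  s[names(sigmas)] <- sigmas
  new("CampaignConfig", tcp = tcp, ideation = ideation, policy = policy,
      oracles = oracles, sigmas = s, scoringRatio = scoringRatio,
      batchSize = batchSize, budget = budget,
      costPerCompound = costPerCompound, maxCycles = maxCycles,
      parentPool = parentPool, stallLimit = stallLimit, useModel = useModel,
      frozenNoise = frozenNoise, seed = seed)
}

## ---- campaign state --------------------------------------------------------

.newState <- function(config) {
  st <- new.env(parent = emptyenv())
  obj <- objectiveNames(config@tcp)
  st$objectives <- obj
  st$keys <- character(0)
  st$index <- new.env(parent = emptyenv())
  st$routes <- list()
  st$parents <- list()
  st$ops <- character(0)
  st$status <- character(0)
  st$cycleIdeated <- integer(0)
  st$cycleMade <- integer(0)
  st$cycleTested <- integer(0)
  st$predicted <- matrix(NA_real_, 0, length(obj), dimnames = list(NULL, obj))
  st$measured <- matrix(NA_real_, 0, length(obj), dimnames = list(NULL, obj))
  st$cycle <- 0L
  st$made <- 0L
  st$scored <- 0L
  st$stalls <- 0L
  st$success <- FALSE
  st$successKey <- NA_character_
  st$terminated <- FALSE
  st$cache <- new.env(parent = emptyenv())
  st$streams <- rngStreams(config@seed)
  st$frozenStore <- new.env(parent = emptyenv())
  st$bias <- NULL
  st$utilComposite <- numeric(0)
  st$events <- list()
  st
}

.addRecord <- function(st, smiles, route, parents, op, cycle) {
  i <- length(st$keys) + 1L
  st$keys[i] <- smiles
  st$index[[smiles]] <- i
  st$routes[[i]] <- route
  st$parents[[i]] <- parents
  st$ops[i] <- op
  st$status[i] <- "ideated"
  st$cycleIdeated[i] <- cycle
  st$cycleMade[i] <- NA_integer_
  st$cycleTested[i] <- NA_integer_
  st$predicted <- rbind(st$predicted, rep(NA_real_, ncol(st$predicted)))
  st$measured <- rbind(st$measured, rep(NA_real_, ncol(st$measured)))
  st$utilComposite[i] <- NA_real_
  i
}

.measureRows <- function(st, config, rows) {
  smis <- st$keys[rows]
  for (obj in st$objectives) {
    st$measured[rows, obj] <- oracleValues(config@oracles[[obj]], smis)
  }
  st$utilComposite[rows] <- .measuredUtility(st, config, rows)
}

.checkSuccess <- function(st, config, rows) {
  for (i in rows) {
    vals <- stats::setNames(as.numeric(st$measured[i, ]), st$objectives)
    if (tcpSatisfied(as.list(vals), config@tcp)) {
      st$success <- TRUE
      st$successKey <- st$keys[i]
      st$terminated <- TRUE
      return(TRUE)
    }
  }
  FALSE
}

#' Initialize a campaign from starting hits
#'
#' Hits are made and tested immediately (noiseless oracles), counted against
#' the budget, and seed the dedup cache. A hit already satisfying the TCP
#' succeeds at cycle 0.
#'
#' @param config a [CampaignConfig-class].
#' @param hits list of compound records (`list(smiles, route, ...)`), e.g.
#'   from [generateHits()], or a character vector of SMILES (trivial
#'   single-block routes are recorded as NULL routes).
#' @return a campaign state environment.
#' @export
campaignReset <- function(config, hits) {
  if (is.character(hits))
    hits <- lapply(hits, function(s) list(smiles = s, route = NULL,
                                          parents = character(0)))
  if (length(hits) == 0) stop("no valid hits")
  smis <- canonicalSmiles(vapply(hits, `[[`, character(1), "smiles"))
  ok <- !is.na(smis)
  if (!any(ok)) stop("no valid hits")
  hits <- hits[ok]; smis <- smis[ok]
  st <- .newState(config)
  rows <- integer(0)
  for (i in seq_along(hits)) {
    if (!is.null(st$index[[smis[i]]])) next
    r <- .addRecord(st, smis[i], hits[[i]]$route, character(0), "hit", 0L)
    st$cache[[smis[i]]] <- TRUE
    rows <- c(rows, r)
  }
  if (!length(rows)) stop("no valid hits")
  st$status[rows] <- "tested"
  st$cycleMade[rows] <- 0L
  st$cycleTested[rows] <- 0L
  st$made <- length(rows)
  .measureRows(st, config, rows)
  .checkSuccess(st, config, rows)
  if (st$made >= config@budget) st$terminated <- TRUE
  st$events[[length(st$events) + 1]] <-
    list(cycle = 0L, event = "reset", nHits = length(rows),
         made = st$made, success = st$success)
  st
}

## composite utility of measured values for tested rows
.measuredUtility <- function(st, config, rows) {
  vapply(rows, function(i) {
    vals <- stats::setNames(as.numeric(st$measured[i, ]), st$objectives)
    compositeUtility(as.list(vals), config@tcp)
  }, numeric(1))
}

## tested records ordered by composite measured utility (best first)
.parentOrder <- function(st, config) {
  tested <- which(st$status == "tested")
  if (!length(tested)) return(integer(0))
  tested[order(-st$utilComposite[tested], st$keys[tested])]
}

.recordsAt <- function(st, idx) {
  lapply(idx, function(i)
    list(key = st$keys[i], smiles = st$keys[i], route = st$routes[[i]]))
}

#' Run one DMTA cycle
#'
#' @param st campaign state from [campaignReset()] (modified in place).
#' @param config the [CampaignConfig-class].
#' @param library a [BlockLibrary-class].
#' @param templates reaction repertoire.
#' @return the state, invisibly; `st$terminated` signals completion.
#' @export
runCycle <- function(st, config, library, templates = defaultReactions()) {
  if (st$terminated) return(invisible(st))
  st$cycle <- st$cycle + 1L
  cyc <- st$cycle

  ## ---- Design: ideate ----
  ## top-utility tested molecules are the parents; when their neighborhoods
  ## are exhausted (everything new is already cached), ideation escalates to
  ## the next tier of tested molecules
  target <- ceiling(config@scoringRatio * config@batchSize)
  ord <- .parentOrder(st, config)
  tierSize <- max(1L, as.integer(config@parentPool))
  newRows <- integer(0)
  tier <- 0L
  while (length(newRows) < target && tier * tierSize < length(ord)) {
    idx <- ord[(tier * tierSize + 1):min((tier + 1L) * tierSize, length(ord))]
    parents <- .recordsAt(st, idx)
    for (attempt in 1:25) {   # keep drawing until this tier yields nothing new
      batch <- ideateBatch(parents, library, templates, config@ideation,
                           st$cache, st$streams,
                           maxNew = target - length(newRows))
      if (!length(batch)) break
      for (an in batch)
        newRows <- c(newRows, .addRecord(st, an$smiles, an$route, an$parents,
                                         an$op, cyc))
      if (length(newRows) >= target) break
    }
    tier <- tier + 1L
  }
  if (!length(newRows)) {
    st$stalls <- st$stalls + 1L
    st$events[[length(st$events) + 1]] <-
      list(cycle = cyc, event = "stall", stalls = st$stalls)
    if (st$stalls >= config@stallLimit) st$terminated <- TRUE
    return(invisible(st))
  }
  st$stalls <- 0L

  ## ---- Design: score (noisy oracles), bias-correct, rank ----
  if (config@useModel) {
    smis <- st$keys[newRows]
    for (obj in st$objectives) {
      no <- noisyOracle(config@oracles[[obj]], config@sigmas[[obj]],
                        frozen = config@frozenNoise)
      st$predicted[newRows, obj] <- noisyValues(no, smis, st$streams,
                                                st$frozenStore)
    }
    st$scored <- st$scored + length(newRows)
  }

  pool <- which(st$status == "ideated")
  nMake <- min(config@batchSize, config@budget - st$made)
  if (nMake <= 0) { st$terminated <- TRUE; return(invisible(st)) }

  if (config@useModel) {
    vals <- st$predicted[pool, , drop = FALSE]
    for (obj in st$objectives)
      vals[, obj] <- correctScores(vals[, obj], st$bias[[obj]])
    um <- utilityMatrix(vals, config@tcp)
    w <- if (length(config@policy@weights)) config@policy@weights
         else config@tcp@weights
    so <- .selectionOrdering(um, st$keys[pool], w, need = 2L * nMake)
    sel <- epsilonGreedySelect(so$ordering, nMake, config@policy@epsilon, st$streams)
    chosen <- pool[sel$selected]
    slotType <- sel$slotType
    fronts0 <- so$front[sel$selected]
  } else {
    perm <- withStream(st$streams, "selection", sample.int(length(pool)))
    chosen <- pool[perm[seq_len(min(nMake, length(pool)))]]
    slotType <- rep("random", length(chosen))
    fronts0 <- rep(NA_integer_, length(chosen))
  }

  ## ---- Make ----
  st$status[chosen] <- "made"
  st$cycleMade[chosen] <- cyc
  st$made <- st$made + length(chosen)

  ## ---- Test (all made molecules are tested) ----
  .measureRows(st, config, chosen)
  st$status[chosen] <- "tested"
  st$cycleTested[chosen] <- cyc

  ## ---- Analyze: refit bias, check TCP, termination ----
  if (config@useModel) {
    tested <- which(st$status == "tested" & !is.na(st$cycleTested))
    pairs <- lapply(stats::setNames(st$objectives, st$objectives), function(obj) {
      has <- tested[is.finite(st$predicted[tested, obj]) &
                    is.finite(st$measured[tested, obj])]
      list(predicted = st$predicted[has, obj], measured = st$measured[has, obj])
    })
    st$bias <- fitBias(pairs)
  }
  .checkSuccess(st, config, chosen)
  if (st$made >= config@budget) st$terminated <- TRUE
  st$events[[length(st$events) + 1]] <-
    list(cycle = cyc, event = "cycle", ideated = length(newRows),
         scored = if (config@useModel) length(newRows) else 0L,
         made = length(chosen), madeKeys = st$keys[chosen],
         slotType = slotType, fronts = fronts0,
         totalMade = st$made, success = st$success)
  invisible(st)
}

## ---- results ---------------------------------------------------------------

#' Campaign result
#'
#' @slot success logical; was the TCP satisfied before budget exhaustion.
#' @slot successKey dedup key of the first TCP-satisfying molecule (or NA).
#' @slot moleculesMade total molecules made (including hits).
#' @slot moleculesScored total molecules scored by the noisy oracles.
#' @slot cycles DMTA cycles run.
#' @slot monetaryCost `moleculesMade * costPerCompound`.
#' @slot ledger data.frame, one row per compound touched by the campaign.
#' @slot routes list of synthetic routes, parallel to the ledger.
#' @slot lineage data.frame of `parent`/`child` dedup-key edges.
#' @slot events per-cycle event log (list).
#' @slot config the [CampaignConfig-class] used.
#' @export
setClass("CampaignResult",
  representation(success = "logical", successKey = "character",
                 moleculesMade = "numeric", moleculesScored = "numeric",
                 cycles = "numeric", monetaryCost = "numeric",
                 ledger = "data.frame", routes = "list", lineage = "data.frame",
                 events = "list", config = "CampaignConfig"))

setMethod("show", "CampaignResult", function(object) {
  cat(sprintf("CampaignResult: %s in %g cycles; %g made (budget %g), %g scored, cost $%s\n",
              if (object@success) "SUCCESS" else "failure",
              object@cycles, object@moleculesMade, object@config@budget,
              object@moleculesScored,
              format(object@monetaryCost, big.mark = ",", scientific = FALSE)))
})

.stateToResult <- function(st, config) {
  n <- length(st$keys)
  led <- data.frame(
    key = st$keys, smiles = st$keys, status = st$status, op = st$ops,
    cycleIdeated = st$cycleIdeated, cycleMade = st$cycleMade,
    cycleTested = st$cycleTested, stringsAsFactors = FALSE
  )
  for (obj in st$objectives) {
    led[[paste0("predicted_", obj)]] <- st$predicted[, obj]
    led[[paste0("measured_", obj)]] <- st$measured[, obj]
  }
  led$utility <- vapply(seq_len(n), function(i) {
    if (st$status[i] != "tested") return(NA_real_)
    vals <- stats::setNames(as.numeric(st$measured[i, ]), st$objectives)
    compositeUtility(as.list(vals), config@tcp)
  }, numeric(1))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    ps <- st$parents[[i]]
    if (!length(ps)) return(NULL)
    data.frame(parent = ps, child = st$keys[i], stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(parent = character(0), child = character(0))
  new("CampaignResult", success = st$success, successKey = st$successKey,
      moleculesMade = as.numeric(st$made), moleculesScored = as.numeric(st$scored),
      cycles = as.numeric(st$cycle),
      monetaryCost = as.numeric(st$made) * config@costPerCompound,
      ledger = led, routes = st$routes, lineage = edges, events = st$events,
      config = config)
}

#' Run a full campaign
#'
#' Loops DMTA cycles until the TCP is satisfied, the budget is exhausted,
#' ideation stalls repeatedly, or `maxCycles` is hit. Deterministic given
#' (config, hits, seed).
#'
#' @param config a [CampaignConfig-class].
#' @param hits starting hits (see [campaignReset()]).
#' @param library a [BlockLibrary-class].
#' @param templates reaction repertoire.
#' @return a [CampaignResult-class].
#' @export
runCampaign <- function(config, hits, library, templates = defaultReactions()) {
  st <- campaignReset(config, hits)
  while (!st$terminated && st$cycle < config@maxCycles)
    runCycle(st, config, library, templates)
  .stateToResult(st, config)
}

#' Lineage graph of a campaign
#'
#' Directed acyclic graph over made molecules: an edge `parent -> child`
#' records that the parent inspired the child's ideation. Nodes carry the
#' cycle made and composite utility.
#'
#' @param result a [CampaignResult-class].
#' @return an [igraph::igraph] object.
#' @export
lineageGraph <- function(result) {
  led <- result@ledger
  made <- led[!is.na(led$cycleMade), , drop = FALSE]
  edges <- result@lineage
  edges <- edges[edges$parent %in% made$key & edges$child %in% made$key, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = made$key, cycleMade = made$cycleMade,
                          utility = made$utility, stringsAsFactors = FALSE))
  g
}
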