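## Ideation: the Design-step analog generator.
##
## Two moves, mirroring how a med-chem team expands a hit series:
##  * replacement -- a building block in the parent's synthetic route is
##    swapped for a library block drawn by Boltzmann-weighted fingerprint
##    similarity (temperature = creativity; n-replacement = how many blocks
##    are swapped at once);
##  * growth -- the parent product joins a random size-admissible block in a
##    compatible reaction, appending one step to the route.
## A campaign-level cache of canonical SMILES keys keeps ideation from
## retreading old chemical space.

#' Ideation configuration
#'
#' @slot temperature Boltzmann temperature, >= 0; `Inf` is random search.
#' @slot nReplace number of route blocks replaced per analog (`Inf` = all).
#' @slot analogsPerParent analogs attempted per parent per cycle.
#' @slot replaceFraction share of analogs from replacement (rest grow).
#' @slot growthMaxHeavyAtoms cap on the size of added blocks.
#' @slot withReplacement logical; Boltzmann draws with replacement.
#' @export
setClass("IdeationConfig",
  representation(temperature = "numeric", nReplace = "numeric",
                 analogsPerParent = "numeric", replaceFraction = "numeric",
                 growthMaxHeavyAtoms = "numeric", withReplacement = "logical"))

setValidity("IdeationConfig", function(object) {
  if (object@temperature < 0) return("temperature must be >= 0")
  if (object@analogsPerParent < 1) return("analogsPerParent must be >= 1")
  if (object@nReplace < 1) return("nReplace must be >= 1 (use Inf for all)")
  if (object@replaceFraction < 0 || object@replaceFraction > 1)
    return("replaceFraction must be in [0, 1]")
  TRUE
})

setMethod("show", "IdeationConfig", function(object) {
  cat(sprintf("IdeationConfig: T = %g, n-replace = %s, %g analogs/parent (%.0f%% replacement)\n",
              object@temperature,
              if (is.infinite(object@nReplace)) "ALL" else object@nReplace,
              object@analogsPerParent, 100 * object@replaceFraction))
})

#' Create an ideation configuration
#'
#' @param temperature Boltzmann temperature (default 0.08; 0 is maximally
#'   conservative, `Inf` is random search).
#' @param nReplace blocks replaced per analog (default 1; `Inf` for all).
#' @param analogsPerParent analogs attempted per parent (default 8).
#' @param replaceFraction fraction of analogs from replacement vs growth
#'   (default 0.5).
#' @param growthMaxHeavyAtoms size cap for growth blocks (default 10).
#' @param withReplacement Boltzmann sampling with replacement (default FALSE).
#' @return an [IdeationConfig-class].
#' @export
ideationConfig <- function(temperature = 0.08, nReplace = 1,
                           analogsPerParent = 8, replaceFraction = 0.5,
                           growthMaxHeavyAtoms = 10, withReplacement = FALSE) {
  new("IdeationConfig", temperature = temperature, nReplace = nReplace,
      analogsPerParent = analogsPerParent, replaceFraction = replaceFraction,
      growthMaxHeavyAtoms = growthMaxHeavyAtoms,
      withReplacement = withReplacement)
}

#' Rank a library by fingerprint similarity to a reference
#'
#' Tanimoto similarity on circular fingerprints, descending; ties broken by
#' block id (stable).
#'
#' @param reference reference structure (SMILES) or fingerprint on-bit vector.
#' @param library a [BlockLibrary-class].
#' @return data.frame with `blockId`, `smiles`, `similarity`, plus row index
#'   `idx` into the library, ordered best-first.
#' @export
similarityRank <- function(reference, library) {
  stopifnot(length(library) > 0)
  fp <- if (is.character(reference))
    morganBits(reference, library@fpParams$radius, library@fpParams$nbits)
  else reference
  sims <- vapply(library@fp, tanimoto, numeric(1), b = fp)
  tab <- blockTable(library)
  ord <- order(-sims, tab$blockId)
  data.frame(blockId = tab$blockId[ord], smiles = tab$smiles[ord],
             similarity = sims[ord], idx = ord, stringsAsFactors = FALSE)
}

#' Boltzmann-weighted sampling from a similarity ranking
#'
#' Draws `k` blocks with probability proportional to `exp(similarity / T)`
#' (max-subtracted for stability), without replacement by default. `T = 0`
#' degenerates to the deterministic top-k in rank order; `T = Inf` to uniform
#' sampling.
#'
#' @param ranked data.frame from [similarityRank()].
#' @param temperature `T >= 0`, possibly `Inf`.
#' @param k number of draws, `<= nrow(ranked)`.
#' @param streams optional [rngStreams()] environment (stream `"ideation"`).
#' @param withReplacement draw with replacement.
#' @return the selected rows of `ranked`.
#' @export
boltzmannSample <- function(ranked, temperature, k, streams = NULL,
                            withReplacement = FALSE) {
  n <- nrow(ranked)
  if (k > n) stop("k must be <= number of ranked blocks")
  if (k == 0) return(ranked[0, ])
  if (temperature == 0) return(ranked[seq_len(k), ])
  w <- if (is.infinite(temperature)) rep(1, n)
       else exp((ranked$similarity - max(ranked$similarity)) / temperature)
  draw <- function() sample.int(n, k, replace = withReplacement, prob = w)
  idx <- if (is.null(streams)) draw() else withStream(streams, "ideation", draw())
  ranked[idx, , drop = FALSE]
}

## replacement positions and role of each block slot in a route
.routeSlotRole <- function(route, step, slot, templates) {
  tid <- route$steps[[step]]$template
  tm <- Filter(function(t) t@templateId == tid, templates)[[1]]
  tm@roles[slot]
}

## rebuild a route after swapping blocks; each step's recorded product is the
## enumerated product most similar to the old one (ties: lexicographic)
.rebuildRoute <- function(route, templates, library) {
  tmap <- stats::setNames(templates, vapply(templates, templateId, character(1)))
  steps <- route$steps
  prods <- rep(NA_character_, length(steps))
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    rsmis <- vapply(st$reactants, function(r)
      if (identical(r$kind, "block")) r$smiles else prods[r$index], character(1))
    if (anyNA(rsmis)) return(NULL)
    cand <- applyTemplate(tmap[[st$template]], rsmis)
    if (length(cand) == 0) return(NULL)
    if (length(cand) > 1 && !is.na(st$product)) {
      old <- morganBits(st$product, library@fpParams$radius, library@fpParams$nbits)
      sims <- vapply(cand, function(s)
        tanimoto(morganBits(s, library@fpParams$radius, library@fpParams$nbits), old),
        numeric(1))
      cand <- cand[order(-sims, cand)]
    } else cand <- sort(cand)
    steps[[i]]$product <- cand[1]
    prods[i] <- cand[1]
  }
  syntheticRoute(steps)
}

#' Generate analogs by building-block replacement
#'
#' Picks `nReplace` block positions of the parent's route (uniformly among
#' available positions when fewer are requested than exist), draws a
#' role-compatible replacement for each by similarity ranking + Boltzmann
#' sampling, and re-applies the route.
#'
#' @param parent compound record (`list(smiles, route, ...)`).
#' @param library a [BlockLibrary-class].
#' @param config an [IdeationConfig-class].
#' @param templates reaction repertoire.
#' @param streams [rngStreams()] environment.
#' @param nAnalogs number of analogs to attempt.
#' @return list of records `list(smiles, route, op = "replace", blocks)`.
#' @export
replaceReactants <- function(parent, library, config, templates = defaultReactions(),
                             streams = NULL, nAnalogs = 4) {
  if (is.null(parent$route)) return(list())
  pos <- .routeBlockPositions(parent$route)
  if (nrow(pos) == 0) return(list())
  tab <- blockTable(library)
  ## per-position replacement queues: one Boltzmann draw of up to nAnalogs
  ## blocks without replacement, so successive analogs receive distinct
  ## replacements (the deterministic top-k at T = 0)
  queues <- vector("list", nrow(pos))
  qptr <- integer(nrow(pos))
  nextPick <- function(p) {
    if (is.null(queues[[p]])) {
      role <- .routeSlotRole(parent$route, pos$step[p], pos$slot[p], templates)
      compat <- .roleCompatIdx(library, role)
      if (!length(compat)) {
        queues[[p]] <<- data.frame()
      } else {
        sub <- new("BlockLibrary", blocks = tab[compat, , drop = FALSE],
                   fp = library@fp[compat], fpParams = library@fpParams)
        ranked <- similarityRank(pos$smiles[p], sub)
        queues[[p]] <<- boltzmannSample(ranked, config@temperature,
                                        min(nAnalogs, nrow(ranked)), streams,
                                        config@withReplacement)
      }
    }
    q <- queues[[p]]
    if (!nrow(q)) return(NULL)     # position skipped: no compatible blocks
    qptr[p] <<- qptr[p] %% nrow(q) + 1L
    q[qptr[p], , drop = FALSE]
  }
  out <- list()
  for (a in seq_len(nAnalogs)) {
    nrep <- if (is.infinite(config@nReplace)) nrow(pos)
            else min(config@nReplace, nrow(pos))
    sel <- if (nrep >= nrow(pos)) seq_len(nrow(pos)) else {
      drawSel <- function() sample.int(nrow(pos), nrep)
      if (is.null(streams)) drawSel() else withStream(streams, "ideation", drawSel())
    }
    route <- parent$route
    blocks <- character(0)
    ok <- TRUE
    for (p in sel) {
      pick <- nextPick(p)
      if (is.null(pick)) { ok <- FALSE; break }
      route$steps[[pos$step[p]]]$reactants[[pos$slot[p]]] <-
        blockRef(pick$blockId[1], pick$smiles[1])
      blocks <- c(blocks, pick$blockId[1])
    }
    if (!ok) next
    newRoute <- .rebuildRoute(route, templates, library)
    if (is.null(newRoute)) next
    out[[length(out) + 1]] <- list(smiles = newRoute$product, route = newRoute,
                                   op = "replace", blocks = blocks)
  }
  out
}

#' Generate analogs by fragment growth
#'
#' Appends one route step: the parent product joins a uniformly random
#' size-admissible block under a uniformly random compatible template.
#'
#' @inheritParams replaceReactants
#' @return list of records `list(smiles, route, op = "grow", blocks)`;
#'   empty when no template role matches the parent product.
#' @export
growCompound <- function(parent, library, config, templates = defaultReactions(),
                         streams = NULL, nAnalogs = 4) {
  tab <- blockTable(library)
  ## compatible (template, parent-role-index) combos
  combos <- list()
  for (tm in templates) {
    for (ri in seq_along(tm@roles)) {
      if (matchesRole(parent$smiles, tm@roles[ri])) {
        other <- tm@roles[-ri]
        admissible <- intersect(.roleCompatIdx(library, other),
                                which(tab$heavyAtoms <= config@growthMaxHeavyAtoms))
        if (length(admissible))
          combos[[length(combos) + 1]] <- list(tm = tm, ri = ri, blocks = admissible)
      }
    }
  }
  if (!length(combos)) return(list())
  ## a parent without a recorded route (e.g. a screening hit supplied as bare
  ## SMILES) joins the new step as a pseudo-block
  nSteps <- if (is.null(parent$route)) 0L else length(parent$route$steps)
  parentRef <- if (nSteps == 0)
    blockRef(if (!is.null(parent$key)) parent$key else parent$smiles, parent$smiles)
  else stepRef(nSteps)
  priorSteps <- if (nSteps == 0) list() else parent$route$steps
  out <- list()
  for (a in seq_len(nAnalogs)) {
    draw2 <- function() {
      cb <- combos[[sample.int(length(combos), 1)]]
      list(cb = cb, b = cb$blocks[sample.int(length(cb$blocks), 1)])
    }
    d <- if (is.null(streams)) draw2() else withStream(streams, "ideation", draw2())
    tm <- d$cb$tm; ri <- d$cb$ri; b <- d$b
    reactants <- if (ri == 1)
      list(parentRef, blockRef(tab$blockId[b], tab$smiles[b]))
    else
      list(blockRef(tab$blockId[b], tab$smiles[b]), parentRef)
    rsmis <- if (ri == 1) c(parent$smiles, tab$smiles[b]) else c(tab$smiles[b], parent$smiles)
    prods <- applyTemplate(tm, rsmis)
    if (!length(prods)) next
    pi <- if (length(prods) == 1) 1 else {
      drawP <- function() sample.int(length(prods), 1)
      if (is.null(streams)) drawP() else withStream(streams, "ideation", drawP())
    }
    steps <- c(priorSteps,
               list(list(template = tm@templateId, reactants = reactants,
                         product = prods[pi])))
    out[[length(out) + 1]] <- list(smiles = prods[pi], route = syntheticRoute(steps),
                                   op = "grow", blocks = tab$blockId[b])
  }
  out
}

#' Ideate a batch of analogs from a set of parents
#'
#' Pools replacement and growth analogs per parent (split by
#' `replaceFraction`), discards analogs whose canonical structure is already
#' in the campaign cache, adds survivors to the cache, and records lineage.
#'
#' @param parents list of compound records; each must carry `key` (dedup key)
#'   or `smiles`.
#' @param library a [BlockLibrary-class].
#' @param templates reaction repertoire.
#' @param config an [IdeationConfig-class].
#' @param cache environment of already-seen dedup keys (modified in place).
#' @param streams [rngStreams()] environment.
#' @param maxNew stop once this many new records have been emitted; surplus
#'   analogs are left uncached so they can resurface later (default Inf).
#' @return list of new compound records
#'   `list(smiles, route, parents, op, blocks)`, all with distinct unseen
#'   keys (possibly empty).
#' @export
ideateBatch <- function(parents, library, templates = defaultReactions(),
                        config = ideationConfig(), cache = new.env(parent = emptyenv()),
                        streams = NULL, maxNew = Inf) {
  stopifnot(length(parents) > 0)
  nRep <- ceiling(config@analogsPerParent * config@replaceFraction)
  nGrow <- max(0, config@analogsPerParent - nRep)
  out <- list()
  for (parent in parents) {
    if (length(out) >= maxNew) break
    pkey <- if (!is.null(parent$key)) parent$key else parent$smiles
    analogs <- c(
      replaceReactants(parent, library, config, templates, streams, nAnalogs = nRep),
      if (nGrow > 0) growCompound(parent, library, config, templates, streams,
                                  nAnalogs = nGrow) else list()
    )
    for (an in analogs) {
      if (length(out) >= maxNew) break
      key <- an$smiles
      if (!is.null(cache[[key]])) next
      cache[[key]] <- TRUE
      an$parents <- pkey
      out[[length(out) + 1]] <- an
    }
  }
  out
}
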