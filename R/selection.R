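## Selection policy (Pareto fronts + scalarization + epsilon-greedy) and the
## Analyze-step bias correction of predictions.

#' Selection policy
#'
#' @slot epsilon exploration probability in `[0, 1]`.
#' @slot weights per-objective scalarization weights (normalized).
#' @export
setClass("SelectionPolicy",
  representation(epsilon = "numeric", weights = "numeric"))

setValidity("SelectionPolicy", function(object) {
  if (object@epsilon < 0 || object@epsilon > 1) return("epsilon must be in [0, 1]")
  if (length(object@weights) && abs(sum(object@weights) - 1) > 1e-8)
    return("weights must be normalized")
  TRUE
})

#' Create a selection policy
#'
#' @param epsilon probability a selection slot is filled at random
#'   (default 0.1).
#' @param weights scalarization weights (default: uniform over the TCP's
#'   objectives at use time).
#' @return a [SelectionPolicy-class].
#' @export
selectionPolicy <- function(epsilon = 0.1, weights = numeric(0)) {
  if (length(weights)) weights <- weights / sum(weights)
  new("SelectionPolicy", epsilon = epsilon, weights = weights)
}

#' Partition candidates into successive Pareto fronts
#'
#' Front 0 is the non-dominated set; front k the non-dominated set after
#' removing fronts `< k`. Candidate `a` dominates `b` iff `a >= b` in every
#' objective and `a > b` in at least one (utilities are maximized; `-Inf`
#' sentinels are allowed).
#'
#' @param utilities numeric matrix, rows = candidates, cols = objectives.
#' @return integer vector of front indices (0-based), one per candidate.
#' @export
paretoFronts <- function(utilities) {
  n <- nrow(utilities)
  if (n == 0) return(integer(0))
  front <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  k <- 0L
  while (length(remaining)) {
    nond <- .nonDominated(utilities[remaining, , drop = FALSE])
    front[remaining[nond]] <- k
    remaining <- remaining[!nond]
    k <- k + 1L
  }
  front
}

## vectorized non-dominated mask: each confirmed non-dominated candidate
## eliminates everything it strictly dominates
.nonDominated <- function(u) {
  n <- nrow(u); m <- ncol(u)
  nond <- rep(TRUE, n)
  rs <- rowSums(pmax(pmin(u, 1e12), -1e12))   # -Inf-safe scan order
  for (j in order(-rs)) {
    if (!nond[j]) next
    uj <- u[j, ]
    le <- rowSums(u <= matrix(uj, n, m, byrow = TRUE)) == m
    lt <- rowSums(u < matrix(uj, n, m, byrow = TRUE)) > 0
    nond[le & lt] <- FALSE
  }
  nond
}

## ordering for batch selection: exact fronts are peeled only until `need`
## candidates are covered; the tail is one residual front ordered by scalar
## score (greedy slots never reach it, and uniform random slots are
## order-insensitive)
.selectionOrdering <- function(utilities, keys, weights, need) {
  n <- nrow(utilities)
  weights <- weights / sum(weights)
  scal <- as.numeric(utilities %*% weights)
  scal[!is.finite(scal)] <- -Inf
  front <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  k <- 0L
  while (length(remaining) && (n - length(remaining)) < need) {
    nond <- .nonDominated(utilities[remaining, , drop = FALSE])
    front[remaining[nond]] <- k
    remaining <- remaining[!nond]
    k <- k + 1L
  }
  front[remaining] <- k
  list(ordering = order(front, -scal, keys), front = front)
}

#' Order candidates by front, scalarized utility, and key
#'
#' Ascending front, then descending weighted-mean utility within front, then
#' lexicographic dedup key (stable, deterministic).
#'
#' @param utilities numeric matrix (rows = candidates).
#' @param fronts integer front per candidate (from [paretoFronts()]).
#' @param keys character dedup keys, one per candidate.
#' @param weights scalarization weights (default uniform).
#' @return integer permutation ordering candidates best-first.
#' @export
rankCandidates <- function(utilities, fronts, keys,
                           weights = rep(1 / ncol(utilities), ncol(utilities))) {
  weights <- weights / sum(weights)
  scal <- as.numeric(utilities %*% weights)
  scal[!is.finite(scal)] <- -Inf
  order(fronts, -scal, keys)
}

#' Epsilon-greedy batch selection
#'
#' Fills `k` slots sequentially: with probability `epsilon` a slot is filled
#' uniformly at random from the remaining pool, otherwise by the best-ranked
#' remaining candidate. If `k` exceeds the pool, the whole pool is selected.
#'
#' @param ordering integer permutation (best-first), e.g. from
#'   [rankCandidates()].
#' @param k batch size.
#' @param epsilon exploration probability.
#' @param streams optional [rngStreams()] environment (stream `"selection"`).
#' @return list with `selected` (indices into the original candidate set, in
#'   selection order) and `slotType` (`"greedy"`/`"random"` per slot).
#' @export
epsilonGreedySelect <- function(ordering, k, epsilon, streams = NULL) {
  pool <- ordering
  k <- min(k, length(pool))
  sel <- integer(0); type <- character(0)
  for (s in seq_len(k)) {
    draw <- function() {
      if (epsilon > 0 && stats::runif(1) < epsilon)
        list(i = sample.int(length(pool), 1), t = "random")
      else list(i = 1L, t = "greedy")
    }
    d <- if (is.null(streams)) draw() else withStream(streams, "selection", draw())
    sel <- c(sel, pool[d$i]); type <- c(type, d$t)
    pool <- pool[-d$i]
  }
  list(selected = sel, slotType = type)
}

#' Fit the prediction-measurement bias model
#'
#' Ordinary least squares `measured = alpha + beta * predicted` per
#' objective, from complete prediction-measurement pairs. The model is
#' inactive (identity correction) until `minPairs` pairs exist or when the
#' predictor is degenerate.
#'
#' @param pairs named list: objective -> data.frame/list with `predicted`
#'   and `measured`.
#' @param minPairs minimum pair count to activate (default 10).
#' @return named list: objective -> `list(alpha, beta, n, active)`.
#' @export
fitBias <- function(pairs, minPairs = 10) {
  lapply(pairs, function(p) {
    pred <- as.numeric(p$predicted); meas <- as.numeric(p$measured)
    ok <- is.finite(pred) & is.finite(meas)
    pred <- pred[ok]; meas <- meas[ok]
    n <- length(pred)
    if (n < minPairs || stats::var(pred) < 1e-12)
      return(list(alpha = 0, beta = 1, n = n, active = FALSE))
    beta <- stats::cov(pred, meas) / stats::var(pred)
    alpha <- mean(meas) - beta * mean(pred)
    list(alpha = alpha, beta = beta, n = n, active = TRUE)
  })
}

#' Bias-correct predicted scores
#'
#' Active model: `alpha + beta * prediction`; inactive: identity. Measured
#' values are never altered by this function and always supersede
#' predictions in selection.
#'
#' @param predictions numeric vector of raw predictions for one objective.
#' @param bias one element of [fitBias()]'s result.
#' @return corrected predictions.
#' @export
correctScores <- function(predictions, bias) {
  if (is.null(bias) || !isTRUE(bias$active)) return(predictions)
  bias$alpha + bias$beta * predictions
}
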