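## Synthetic routes.
##
## A route is an ordered list of steps; each step applies a template from the
## repertoire to reactant references (building blocks or products of earlier
## steps) and records the product chosen among the enumerated possibilities,
## so forward replay is deterministic and verifiable.

#' Construct a route step reactant reference
#'
#' @param blockId,smiles block identifier and canonical SMILES (block ref).
#' @param index index of an earlier step (step ref).
#' @return a reactant reference list.
#' @export
blockRef <- function(blockId, smiles)
  list(kind = "block", id = blockId, smiles = smiles)

#' @rdname blockRef
#' @export
stepRef <- function(index) list(kind = "step", index = as.integer(index))

#' Construct a synthetic route
#'
#' @param steps list of steps; each step is `list(template = <templateId>,
#'   reactants = list(<ref>...), product = <canonical SMILES>)`.
#' @return a route list with `steps` and `product` (the final step product).
#' @export
syntheticRoute <- function(steps) {
  stopifnot(length(steps) >= 1)
  list(steps = steps, product = steps[[length(steps)]]$product)
}

## resolve a reactant reference to SMILES given earlier step products
.resolveRef <- function(ref, stepProducts) {
  if (identical(ref$kind, "block")) return(ref$smiles)
  if (identical(ref$kind, "step")) {
    i <- ref$index
    if (is.null(i) || is.na(i) || i < 1 || i > length(stepProducts) ||
        is.na(stepProducts[i]))
      stop("route-invalid: reactant references step ", i,
           " which is not an earlier completed step")
    return(stepProducts[i])
  }
  stop("route-invalid: unknown reactant reference kind")
}

#' Replay a synthetic route forward
#'
#' Re-applies every step's template to its reactants and checks that each
#' recorded intermediate is among the enumerated products. Errors (naming the
#' step) if any step cannot be reproduced.
#'
#' @param route a route from [syntheticRoute()].
#' @param templates list of [ReactionTemplate-class] covering the route's
#'   template ids (default: the built-in repertoire).
#' @return canonical SMILES of the final product (equals `route$product`).
#' @export
replayRoute <- function(route, templates = defaultReactions()) {
  tmap <- stats::setNames(templates, vapply(templates, templateId, character(1)))
  prods <- rep(NA_character_, length(route$steps))
  for (i in seq_along(route$steps)) {
    st <- route$steps[[i]]
    tm <- tmap[[st$template]]
    if (is.null(tm)) stop("route-invalid: unknown template in step ", i, ": ", st$template)
    if (i > 1 && any(vapply(st$reactants, function(r)
        identical(r$kind, "step") && r$index >= i, logical(1))))
      stop("route-invalid: step ", i, " references a non-earlier step")
    rsmis <- vapply(st$reactants, .resolveRef, character(1), stepProducts = prods)
    cand <- applyTemplate(tm, rsmis)
    if (length(cand) == 0)
      stop("route-invalid: step ", i, " (", st$template, ") yields no product")
    if (!(st$product %in% cand))
      stop("route-invalid: recorded product of step ", i,
           " is not reproduced by forward synthesis")
    prods[i] <- st$product
  }
  prods[length(prods)]
}

## block reactant positions in a route: data.frame(step, slot, blockId, smiles),
## ordered final step first (replacement prefers the last steps)
.routeBlockPositions <- function(route) {
  out <- list()
  for (i in rev(seq_along(route$steps))) {
    st <- route$steps[[i]]
    for (j in seq_along(st$reactants)) {
      r <- st$reactants[[j]]
      if (identical(r$kind, "block"))
        out[[length(out) + 1]] <- data.frame(step = i, slot = j, blockId = r$id,
                                             smiles = r$smiles, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(step = integer(0), slot = integer(0),
                      blockId = character(0), smiles = character(0)))
  do.call(rbind, out)
}
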