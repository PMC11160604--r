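## Oracles: ground-truth property functions, and noisy wrappers modeling
## predictive models of stated inaccuracy sigma.

#' Ground-truth oracle
#'
#' A deterministic, vectorized map from structures to property values.
#' Ground-truth oracles are pure functions: repeated calls give identical
#' values. Unevaluable structures yield `NA`, never an error.
#'
#' @slot name objective label the oracle serves.
#' @slot units units of the returned values.
#' @slot fun function(character vector of SMILES) -> numeric vector.
#' @slot costPerCall monetary units per evaluated molecule (0 for scoring).
#' @export
setClass("Oracle",
  representation(name = "character", units = "character",
                 fun = "function", costPerCall = "numeric"))

setMethod("show", "Oracle", function(object) {
  cat(sprintf("Oracle %s [%s], cost/call %.0f\n",
              object@name, object@units, object@costPerCall))
})

#' Create an oracle
#'
#' @param name,units label and units.
#' @param fun vectorized evaluator, `function(smiles) -> numeric`.
#' @param costPerCall monetary cost per molecule evaluated (default 0).
#' @return an [Oracle-class].
#' @export
oracle <- function(name, units, fun, costPerCall = 0) {
  new("Oracle", name = name, units = units, fun = fun, costPerCall = costPerCall)
}

#' Noisy oracle
#'
#' A ground-truth oracle wrapped with additive Gaussian error of spread
#' `sigma` (in the base oracle's units), modeling a predictive model of
#' stated inaccuracy. `sigma = 0` reproduces the base oracle exactly. By
#' default noise is resampled on every scoring call; `frozen = TRUE` fixes
#' one draw per molecule (keyed by structure).
#'
#' @slot base the wrapped [Oracle-class].
#' @slot sigma Gaussian error SD, >= 0.
#' @slot frozen logical; freeze noise per molecule.
#' @export
setClass("NoisyOracle",
  representation(base = "Oracle", sigma = "numeric", frozen = "logical"))

setValidity("NoisyOracle", function(object)
  if (object@sigma < 0) "sigma must be >= 0" else TRUE)

setMethod("show", "NoisyOracle", function(object) {
  cat(sprintf("NoisyOracle on %s: sigma = %g %s%s\n", object@base@name,
              object@sigma, object@base@units,
              if (object@frozen) " (frozen per molecule)" else ""))
})

#' Create a noisy oracle
#'
#' @param base an [Oracle-class].
#' @param sigma Gaussian error SD in the base oracle's units.
#' @param frozen freeze one noise draw per molecule (default FALSE:
#'   resampled per call).
#' @return a [NoisyOracle-class].
#' @export
noisyOracle <- function(base, sigma, frozen = FALSE) {
  new("NoisyOracle", base = base, sigma = sigma, frozen = frozen)
}

#' Evaluate an oracle
#'
#' @param oracle an [Oracle-class].
#' @param smiles character vector of structures.
#' @return numeric vector, one value per molecule (`NA` where unevaluable),
#'   order-preserving.
#' @export
oracleValues <- function(oracle, smiles) {
  if (length(smiles) == 0) return(numeric(0))
  v <- oracle@fun(smiles)
  if (length(v) != length(smiles))
    stop("oracle ", oracle@name, " returned wrong-length result")
  as.numeric(v)
}

#' Evaluate a noisy oracle
#'
#' Adds i.i.d. `Normal(0, sigma^2)` error to the base oracle's values, drawn
#' from the supplied RNG stream. With `frozen` oracles, a molecule keeps its
#' first draw for the life of the noise environment.
#'
#' @param noracle a [NoisyOracle-class].
#' @param smiles character vector of structures.
#' @param streams stream environment from [rngStreams()] (stream `"noise"`
#'   is used); `NULL` uses the current RNG state.
#' @param frozenStore environment used to persist frozen draws (required when
#'   `noracle@frozen`).
#' @return numeric vector of noisy values (`NA` propagates from the base).
#' @export
noisyValues <- function(noracle, smiles, streams = NULL, frozenStore = NULL) {
  base <- oracleValues(noracle@base, smiles)
  if (noracle@sigma == 0 || length(smiles) == 0) return(base)
  drawNoise <- function(n) stats::rnorm(n, 0, noracle@sigma)
  if (noracle@frozen) {
    if (is.null(frozenStore)) stop("frozen noise requires a frozenStore environment")
    eps <- numeric(length(smiles))
    for (i in seq_along(smiles)) {
      key <- paste0(noracle@base@name, "|", smiles[i])
      v <- frozenStore[[key]]
      if (is.null(v)) {
        v <- if (is.null(streams)) drawNoise(1) else withStream(streams, "noise", drawNoise(1))
        frozenStore[[key]] <- v
      }
      eps[i] <- v
    }
  } else {
    eps <- if (is.null(streams)) drawNoise(length(smiles))
           else withStream(streams, "noise", drawNoise(length(smiles)))
  }
  base + eps
}

#' Lipophilicity oracle (Log P)
#'
#' Atomic-contribution (Crippen-type) octanol-water Log P via the descriptor
#' backend. Deterministic; the dynamic range `[-1, 8]` is a reporting range,
#' values are not clipped for scoring.
#'
#' @return an [Oracle-class] named `"lipophilicity"`.
#' @export
lipophilicityOracle <- function() {
  oracle("lipophilicity", "Log P", function(smiles) {
    if (length(smiles) == 0) return(numeric(0))
    vapply(.propRows(smiles), `[[`, numeric(1), "logP")
  })
}

#' Solubility oracle (Log S)
#'
#' Wraps a pluggable regressor honoring the evaluate contract
#' (`function(smiles) -> numeric`). The synthetic surrogate from
#' [syntheticSolubility()] is the bundled choice.
#'
#' @param model the regressor function.
#' @param label model identity recorded in the oracle name metadata.
#' @return an [Oracle-class] named `"solubility"`.
#' @export
solubilityOracle <- function(model, label = "custom") {
  if (missing(model) || !is.function(model))
    stop("solubilityOracle requires a regressor function(smiles) -> numeric")
  o <- oracle("solubility", "Log S", model)
  attr(o, "modelLabel") <- label
  o
}

#' Affinity oracle (pIC50)
#'
#' Wraps a pluggable affinity backend. The bundled backend is the synthetic
#' structure-activity landscape ([syntheticAffinity()]); an external docking
#' adapter can be supplied as any function honoring the evaluate contract.
#'
#' @param backend `function(smiles) -> numeric` in pIC50 units.
#' @param label backend identity.
#' @return an [Oracle-class] named `"affinity"`.
#' @export
affinityOracle <- function(backend, label = "synthetic-landscape") {
  if (missing(backend) || !is.function(backend))
    stop("affinityOracle requires a backend function(smiles) -> numeric")
  o <- oracle("affinity", "pIC50", backend)
  attr(o, "backendLabel") <- label
  o
}
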