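## Target candidate profile (TCP) and the piecewise utility function.
##
## Per-objective utility maps an arbitrary real-valued objective into
## (-Inf, 1]: 1 inside the ideal window (anything ideal is equally prized),
## a linear 0 -> 1 ramp across each acceptable-to-ideal shoulder, and a
## quadratic penalty growing without bound outside the acceptable window.
## The penalty distance is scaled by the same-side ramp width so the function
## is continuous with slope comparable to the linear ramp.

#' Objective specification
#'
#' One TCP objective: the oracle it is measured by (via `name`), its units,
#' dynamic range, and acceptable / ideal windows. Bounds may be infinite;
#' at least one acceptable bound must be finite.
#'
#' @slot name objective label, e.g. `"affinity"`.
#' @slot units measurement units, e.g. `"pIC50"`.
#' @slot dynamicRange numeric length-2, reporting range of the oracle.
#' @slot acceptable numeric length-2 `[lo, hi]`, may be +-Inf.
#' @slot ideal numeric length-2, contained in `acceptable`.
#' @export
setClass("ObjectiveSpec",
  representation(name = "character", units = "character",
                 dynamicRange = "numeric", acceptable = "numeric",
                 ideal = "numeric"))

setValidity("ObjectiveSpec", function(object) {
  a <- object@acceptable; i <- object@ideal
  if (length(a) != 2 || length(i) != 2) return("acceptable and ideal must be [lo, hi]")
  if (a[1] > a[2] || i[1] > i[2]) return("interval bounds out of order")
  if (i[1] < a[1] || i[2] > a[2]) return("ideal must be contained in acceptable")
  if (!any(is.finite(a))) return("at least one acceptable bound must be finite")
  TRUE
})

setMethod("show", "ObjectiveSpec", function(object) {
  fmt <- function(x) paste0("[", x[1], ", ", x[2], "]")
  cat(sprintf("ObjectiveSpec %s (%s): acceptable %s, ideal %s\n",
              object@name, object@units, fmt(object@acceptable), fmt(object@ideal)))
})

#' Create an objective specification
#'
#' @param name,units objective label and units.
#' @param acceptable,ideal numeric length-2 windows, `ideal` inside
#'   `acceptable`; use `-Inf`/`Inf` for open sides.
#' @param dynamicRange numeric length-2 reporting range.
#' @return an [ObjectiveSpec-class].
#' @export
objectiveSpec <- function(name, units, acceptable, ideal,
                          dynamicRange = c(-Inf, Inf)) {
  new("ObjectiveSpec", name = name, units = units,
      dynamicRange = as.numeric(dynamicRange),
      acceptable = as.numeric(acceptable), ideal = as.numeric(ideal))
}

#' Target candidate profile
#'
#' The set of objectives a lead must satisfy, with scalarization weights and
#' the success criterion (whether a compound must reach the acceptable or the
#' ideal window of every objective).
#'
#' @slot objectives list of [ObjectiveSpec-class].
#' @slot weights non-negative, normalized to sum 1.
#' @slot successCriterion `"acceptable"` or `"ideal"`.
#' @export
setClass("TCP",
  representation(objectives = "list", weights = "numeric",
                 successCriterion = "character"))

setValidity("TCP", function(object) {
  if (length(object@objectives) == 0) return("TCP needs at least one objective")
  if (!all(vapply(object@objectives, is, logical(1), "ObjectiveSpec")))
    return("objectives must be ObjectiveSpec")
  if (length(object@weights) != length(object@objectives))
    return("one weight per objective")
  if (any(object@weights < 0)) return("weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  if (!object@successCriterion %in% c("acceptable", "ideal"))
    return("successCriterion must be 'acceptable' or 'ideal'")
  TRUE
})

setMethod("show", "TCP", function(object) {
  cat("TCP with", length(object@objectives), "objectives (success:",
      object@successCriterion, "window)\n")
  for (o in object@objectives) show(o)
})

#' Create a TCP
#'
#' @param objectives list of [ObjectiveSpec-class].
#' @param weights per-objective scalarization weights (default uniform);
#'   normalized to sum 1.
#' @param successCriterion `"acceptable"` (default) or `"ideal"`.
#' @return a [TCP-class].
#' @export
tcp <- function(objectives, weights = NULL, successCriterion = "acceptable") {
  if (is.null(weights)) weights <- rep(1, length(objectives))
  weights <- weights / sum(weights)
  new("TCP", objectives = objectives, weights = weights,
      successCriterion = successCriterion)
}

#' Objective names of a TCP
#'
#' @param x a [TCP-class].
#' @return character vector.
#' @export
objectiveNames <- function(x) vapply(x@objectives, function(o) o@name, character(1))

#' The default oral-drug TCP
#'
#' Affinity (pIC50) acceptable `[8, Inf)` / ideal `[9, Inf)`; lipophilicity
#' (Log P) acceptable `[0, 4]` / ideal `[0, 3]`; solubility (Log S)
#' acceptable `[-4, 0]` / ideal `[-3, 0]`.
#'
#' @param successCriterion `"acceptable"` (default) or `"ideal"`.
#' @return a [TCP-class].
#' @export
defaultTCP <- function(successCriterion = "acceptable") {
  tcp(list(
    objectiveSpec("affinity", "pIC50", c(8, Inf), c(9, Inf), c(3, 11)),
    objectiveSpec("lipophilicity", "Log P", c(0, 4), c(0, 3), c(-1, 8)),
    objectiveSpec("solubility", "Log S", c(-4, 0), c(-3, 0), c(-8, 1))
  ), successCriterion = successCriterion)
}

#' Per-objective utility
#'
#' Maps objective values into `(-Inf, 1]`: 1 inside the ideal window, linear
#' 0 to 1 between each finite acceptable bound and its ideal bound, and
#' `-(d / w)^2` outside the acceptable window, where `d` is the distance
#' beyond the acceptable bound and `w` the same-side ramp width (falling back
#' to 10% of the dynamic range when ideal and acceptable bounds coincide).
#' Sides with an infinite acceptable bound never penalize. `NA` values map to
#' `-Inf` (missing measurements must never win).
#'
#' @param value numeric vector of objective values.
#' @param spec an [ObjectiveSpec-class].
#' @return numeric vector of utilities.
#' @export
objectiveUtility <- function(value, spec) {
  a <- spec@acceptable; i <- spec@ideal
  wLo <- i[1] - a[1]; wHi <- a[2] - i[2]
  fallback <- 0.1 * diff(spec@dynamicRange)
  if (!is.finite(fallback) || fallback <= 0) fallback <- 1
  if (!is.finite(wLo) || wLo <= 0) wLo <- fallback
  if (!is.finite(wHi) || wHi <= 0) wHi <- fallback
  u <- numeric(length(value))
  for (k in seq_along(value)) {
    v <- value[k]
    if (is.na(v)) { u[k] <- -Inf; next }
    if (v >= i[1] && v <= i[2]) { u[k] <- 1; next }
    if (v >= a[1] && v <= a[2]) {
      ## on a shoulder between acceptable and ideal
      u[k] <- if (v < i[1]) (v - a[1]) / (i[1] - a[1]) else (a[2] - v) / (a[2] - i[2])
      next
    }
    if (v < a[1]) {
      u[k] <- if (is.finite(a[1])) -((a[1] - v) / wLo)^2 else 1
    } else {
      u[k] <- if (is.finite(a[2])) -((v - a[2]) / wHi)^2 else 1
    }
  }
  u
}

#' Composite (scalarized) utility
#'
#' Weighted arithmetic mean of per-objective utilities; saturates at 1 iff
#' every objective is in its ideal window. Missing objectives dominate with
#' `-Inf`.
#'
#' @param values named numeric vector or named list, objective -> value.
#' @param tcp a [TCP-class].
#' @return scalar utility.
#' @export
compositeUtility <- function(values, tcp) {
  u <- vapply(seq_along(tcp@objectives), function(j) {
    o <- tcp@objectives[[j]]
    v <- if (o@name %in% names(values)) values[[o@name]] else NA_real_
    objectiveUtility(v, o)
  }, numeric(1))
  if (any(!is.finite(u) & u < 0)) return(-Inf)
  sum(tcp@weights * u)
}

#' Per-objective utility matrix
#'
#' @param valueMatrix numeric matrix, rows = candidates, columns named by
#'   objective.
#' @param tcp a [TCP-class].
#' @return matrix of utilities with the TCP's objective columns.
#' @export
utilityMatrix <- function(valueMatrix, tcp) {
  obj <- objectiveNames(tcp)
  out <- matrix(-Inf, nrow = nrow(valueMatrix), ncol = length(obj),
                dimnames = list(rownames(valueMatrix), obj))
  for (j in seq_along(obj)) {
    if (obj[j] %in% colnames(valueMatrix))
      out[, j] <- objectiveUtility(valueMatrix[, obj[j]], tcp@objectives[[j]])
  }
  out
}

#' Does a set of measured values satisfy the TCP?
#'
#' Only measured (noiseless-oracle) values count; any unmeasured objective
#' fails. The window tested is the TCP's `successCriterion`.
#'
#' @param measured named numeric vector/list, objective -> measured value.
#' @param tcp a [TCP-class].
#' @return logical.
#' @export
tcpSatisfied <- function(measured, tcp) {
  for (o in tcp@objectives) {
    v <- if (o@name %in% names(measured)) measured[[o@name]] else NA_real_
    if (is.null(v) || length(v) != 1 || is.na(v)) return(FALSE)
    w <- if (tcp@successCriterion == "ideal") o@ideal else o@acceptable
    if (v < w[1] || v > w[2]) return(FALSE)
  }
  TRUE
}
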