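#' @import methods
NULL

## ---- BlockLibrary ----------------------------------------------------------

#' Building-block library
#'
#' A catalog of synthetic building blocks: identifier, canonical SMILES,
#' heavy-atom count, and a precomputed circular fingerprint per block.
#'
#' @slot blocks data.frame with columns `blockId`, `smiles`, `heavyAtoms`.
#' @slot fp list of integer on-bit vectors, parallel to `blocks`.
#' @slot fpParams list with `radius` and `nbits` used for the fingerprints.
#' @export
setClass("BlockLibrary",
  representation(blocks = "data.frame", fp = "list", fpParams = "list"))

setValidity("BlockLibrary", function(object) {
  b <- object@blocks
  if (!all(c("blockId", "smiles", "heavyAtoms") %in% names(b)))
    return("blocks must have columns blockId, smiles, heavyAtoms")
  if (anyDuplicated(b$blockId)) return("blockId must be unique within a catalog")
  if (length(object@fp) != nrow(b)) return("one fingerprint per block required")
  TRUE
})

#' @describeIn BlockLibrary number of blocks
#' @param x,object a `BlockLibrary`.
#' @export
setMethod("length", "BlockLibrary", function(x) nrow(x@blocks))

setMethod("show", "BlockLibrary", function(object) {
  cat("BlockLibrary with", nrow(object@blocks), "building blocks",
      sprintf("(fingerprint: radius %d, %d bits)\n",
              object@fpParams$radius, object@fpParams$nbits))
})

#' Accessors for BlockLibrary
#'
#' @param lib a `BlockLibrary`.
#' @return `blockIds`/`blockSmiles`: character vectors; `blockTable`: the
#'   underlying data.frame; `blockFingerprints`: list of on-bit vectors.
#' @export
blockIds <- function(lib) lib@blocks$blockId

#' @rdname blockIds
#' @export
blockSmiles <- function(lib) lib@blocks$smiles

#' @rdname blockIds
#' @export
blockTable <- function(lib) lib@blocks

#' @rdname blockIds
#' @export
blockFingerprints <- function(lib) lib@fp

## ---- ReactionTemplate ------------------------------------------------------

#' Reaction template
#'
#' A two-component coupling from the built-in repertoire, identified by a
#' reaction SMARTS string. Each reactant role names a functional-group
#' pattern the corresponding reactant must carry.
#'
#' @slot templateId short identifier, e.g. `"amide_coupling"`.
#' @slot smarts reaction SMARTS describing the transform.
#' @slot roles character vector of reactant role names (length = arity).
#' @export
setClass("ReactionTemplate",
  representation(templateId = "character", smarts = "character", roles = "character"))

setValidity("ReactionTemplate", function(object) {
  if (length(object@roles) < 1) return("arity must be >= 1")
  if (!all(object@roles %in% names(.ROLE_FINDERS)))
    return(paste("unknown reactant role(s):",
                 paste(setdiff(object@roles, names(.ROLE_FINDERS)), collapse = ", ")))
  TRUE
})

setMethod("show", "ReactionTemplate", function(object) {
  cat("ReactionTemplate", object@templateId,
      sprintf("[arity %d: %s]\n", length(object@roles),
              paste(object@roles, collapse = " + ")))
  cat(" ", object@smarts, "\n")
})

#' @rdname templateArity
#' @export
templateId <- function(template) template@templateId

#' Template accessors
#'
#' @param template a `ReactionTemplate`.
#' @return `templateArity`: integer number of reactant roles; `templateId`:
#'   its identifier; `templateRoles`: role names.
#' @export
templateArity <- function(template) length(template@roles)

#' @rdname templateArity
#' @export
templateRoles <- function(template) template@roles
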