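## Catalog and template file I/O.

#' Load a building-block catalog
#'
#' Reads a CSV catalog (columns `id` and `smiles`) or an SDF file. Rows whose
#' structures do not parse/sanitize are dropped with a message giving the
#' count; surviving structures are canonicalized and fingerprinted. File
#' order is preserved.
#'
#' @param path catalog file (`.csv` or `.sdf`).
#' @param fpRadius,fpBits circular-fingerprint parameters.
#' @return a [BlockLibrary-class].
#' @export
loadCatalog <- function(path, fpRadius = 2L, fpBits = 2048L) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdfs <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdfs)
    smis <- as.character(ChemmineR::sdf2smiles(sdfs))
    df <- data.frame(id = ids, smiles = unname(smis), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!all(c("id", "smiles") %in% names(df)))
      stop("catalog CSV must have columns 'id' and 'smiles'")
  }
  if (nrow(df) == 0) stop("catalog has no rows: ", path)
  buildLibrary(df$id, df$smiles, fpRadius = fpRadius, fpBits = fpBits)
}

#' Build a block library from ids and SMILES
#'
#' @param ids character vector of block identifiers.
#' @param smiles character vector of SMILES (same length).
#' @param fpRadius,fpBits circular-fingerprint parameters.
#' @return a [BlockLibrary-class]; unparseable entries are dropped with a
#'   message giving the count.
#' @export
buildLibrary <- function(ids, smiles, fpRadius = 2L, fpBits = 2048L) {
  can <- canonicalSmiles(smiles)
  ok <- !is.na(can)
  if (any(!ok))
    message("dropped ", sum(!ok), " unparseable building block(s)")
  if (!any(ok)) stop("no valid building blocks")
  ids <- as.character(ids[ok]); can <- can[ok]
  fps <- lapply(can, morganBits, radius = fpRadius, nbits = fpBits)
  bad <- vapply(fps, is.null, logical(1))
  if (any(bad)) { ids <- ids[!bad]; can <- can[!bad]; fps <- fps[!bad] }
  lib <- new("BlockLibrary",
      blocks = data.frame(blockId = ids, smiles = can,
                          heavyAtoms = .heavyAtoms(can), stringsAsFactors = FALSE),
      fp = fps, fpParams = list(radius = fpRadius, nbits = fpBits))
  ## unique tag for memoizing per-library derived indices
  n <- (.cacheGet("libcounter", "n") %||% 0) + 1
  .cacheSet("libcounter", "n", n)
  attr(lib, "uid") <- paste0("lib", n)
  lib
}

#' Write a block library to CSV
#'
#' @param lib a [BlockLibrary-class].
#' @param path output CSV path (`id,smiles` columns).
#' @return invisibly, `path`.
#' @export
writeCatalog <- function(lib, path) {
  utils::write.csv(data.frame(id = blockIds(lib), smiles = blockSmiles(lib)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read reaction templates from a file
#'
#' One reaction SMARTS per line; `#` starts a comment. Each SMARTS must match
#' a member of the built-in repertoire (see [defaultReactions()]): the
#' transform engine recognizes the standard couplings it implements, keyed by
#' their SMARTS string.
#'
#' @param path template file.
#' @return list of [ReactionTemplate-class].
#' @export
readReactionTemplates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no reaction templates in ", path)
  lapply(lines, function(s) {
    id <- names(.TEMPLATE_SMARTS)[match(s, .TEMPLATE_SMARTS)]
    if (is.na(id))
      stop("reaction SMARTS not in the built-in repertoire: ", s,
           "\nsupported transforms: ", paste(names(.TEMPLATE_SMARTS), collapse = ", "))
    new("ReactionTemplate", templateId = id, smarts = s, roles = .TEMPLATE_ROLES[[id]])
  })
}

#' Write reaction templates to a file
#'
#' @param templates list of [ReactionTemplate-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeReactionTemplates <- function(templates, path) {
  writeLines(c("# reaction SMARTS, one per line",
               vapply(templates, function(t) t@smarts, character(1))), path)
  invisible(path)
}
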