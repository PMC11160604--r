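## Low-level chemistry kernel.
##
## Molecules are carried as canonical SMILES strings; the working
## representation is a light molecular graph extracted from ChemmineR atom /
## bond blocks (OpenBabel does all parsing, sanitization, and SMILES
## canonicalization). Everything derived from a canonical SMILES is memoized
## in a package-level cache: the same finite enumeration space is revisited
## constantly during campaigns, so parse/descriptor work is paid once per
## distinct structure.

.chemCache <- new.env(parent = emptyenv())

.cacheGet <- function(kind, key) {
  e <- .chemCache[[kind]]
  if (is.null(e)) return(NULL)
  e[[key]]
}

.cacheSet <- function(kind, key, value) {
  e <- .chemCache[[kind]]
  if (is.null(e)) {
    e <- new.env(parent = emptyenv())
    .chemCache[[kind]] <- e
  }
  e[[key]] <- value
  value
}

#' Clear the package-level chemistry cache
#'
#' Drops memoized molecular graphs, descriptors, fingerprints, and enumerated
#' reaction products. Mainly useful in long sessions and in tests.
#'
#' @return invisibly, `NULL`.
#' @export
clearChemCache <- function() {
  rm(list = ls(.chemCache), envir = .chemCache)
  invisible(NULL)
}

## ---- canonical SMILES ------------------------------------------------------

#' Canonicalize SMILES strings
#'
#' Converts through OpenBabel's canonical SMILES writer. Unparseable inputs
#' yield `NA` (with a warning carrying the count) rather than an error, so
#' catalog loading can drop and log bad rows.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonicalSmiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  out <- rep(NA_character_, length(smiles))
  todo <- which(!is.na(smiles) & nzchar(smiles))
  hit <- vapply(smiles[todo], function(s) {
    v <- .cacheGet("canon", s)
    if (is.null(v)) NA_character_ else v
  }, character(1), USE.NAMES = FALSE)
  out[todo[!is.na(hit)]] <- hit[!is.na(hit)]
  miss <- todo[is.na(hit)]
  if (length(miss)) {
    tags <- paste0("q", seq_along(miss))
    txt <- paste(paste0(smiles[miss], "\t", tags), collapse = "\n")
    res <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", txt)),
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    got <- vapply(parts, function(p) if (length(p) >= 2) trimws(p[2]) else NA_character_, character(1))
    val <- vapply(parts, function(p) trimws(p[1]), character(1))
    ok <- !is.na(got) & got %in% tags & nzchar(val)
    map <- stats::setNames(val[ok], got[ok])
    for (j in seq_along(miss)) {
      v <- unname(map[tags[j]])
      if (!is.na(v) && length(v) == 1 && nzchar(v)) {
        out[miss[j]] <- v
        .cacheSet("canon", smiles[miss[j]], v)
        .cacheSet("canon", v, v)   # canonicalization is idempotent
      } else {
        ## an invalid line aborts OpenBabel's batch conversion; retry alone
        res1 <- tryCatch(
          suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles[miss[j]])),
          error = function(e) ""
        )
        v1 <- trimws(strsplit(res1, "[\t\n]")[[1]][1])
        if (!is.na(v1) && nzchar(v1)) {
          out[miss[j]] <- v1
          .cacheSet("canon", smiles[miss[j]], v1)
          .cacheSet("canon", v1, v1)
        }
      }
    }
  }
  out
}

## ---- molecular graph -------------------------------------------------------

.STD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
                  F = 1, Cl = 1, Br = 1, I = 1, H = 1)

## Parse one canonical SMILES into a light graph:
## elem (chr), ab/bb (ChemmineR blocks), bonds (m x 3: from,to,order),
## degree, ring flags, aromatic flags, implicit H counts.
.molGraph <- function(smiles) {
  g <- .cacheGet("mol", smiles)
  if (!is.null(g)) return(g)
  ## single-heavy-atom molecules (lone-atom SMILES) don't survive the SDF
  ## round trip; build their trivial graph directly
  lone <- regmatches(smiles, regexec("^\\[?([A-Z][a-z]?)[H0-9+\\-]*\\]?$", smiles))[[1]]
  if (length(lone) == 2 && lone[2] %in% names(.STD_VALENCE)) {
    g <- .finishGraph(list(
      smiles = smiles, elem = lone[2],
      bonds = matrix(integer(0), ncol = 3,
                     dimnames = list(NULL, c("from", "to", "order")))))
    return(.cacheSet("mol", smiles, g))
  }
  sdfs <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))),
    error = function(e) NULL
  )
  if (is.null(sdfs) || length(sdfs) != 1) return(NULL)
  sdf <- sdfs[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(ab) || nrow(ab) == 0) return(NULL)
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  if (is.null(bb) || NROW(bb) == 0 || NCOL(bb) < 3) {
    bonds <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("from", "to", "order")))
  } else {
    bonds <- cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  }
  g <- .finishGraph(list(smiles = smiles, elem = elem, bonds = bonds))
  .cacheSet("mol", smiles, g)
}

## Derived perception: degrees, bond-order sums, ring membership (igraph),
## aromatic heuristic (ring atom incident to a ring double bond -- generated
## space is written kekulized by OpenBabel), implicit hydrogens by standard
## valence.
.finishGraph <- function(g) {
  n <- length(g$elem)
  deg <- integer(n); bosum <- numeric(n)
  m <- nrow(g$bonds)
  ringBond <- logical(m)
  if (m > 0) {
    for (i in seq_len(m)) {
      f <- g$bonds[i, 1]; t <- g$bonds[i, 2]; o <- g$bonds[i, 3]
      deg[f] <- deg[f] + 1L; deg[t] <- deg[t] + 1L
      bosum[f] <- bosum[f] + o; bosum[t] <- bosum[t] + o
    }
    ig <- igraph::graph_from_edgelist(g$bonds[, 1:2, drop = FALSE], directed = FALSE)
    if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    ## a bond is in a ring iff it is not a bridge
    ringBond <- rep(TRUE, m)
    ringBond[igraph::bridges(ig)] <- FALSE
  }
  inRing <- logical(n)
  if (any(ringBond)) {
    rb <- g$bonds[ringBond, , drop = FALSE]
    inRing[unique(c(rb[, 1], rb[, 2]))] <- TRUE
  }
  aromatic <- logical(n)
  if (any(ringBond)) {
    dbl <- ringBond & g$bonds[, 3] == 2L
    if (any(dbl)) {
      da <- unique(c(g$bonds[dbl, 1], g$bonds[dbl, 2]))
      aromatic[da] <- TRUE
      ## ring neighbors of ring-double atoms in the same ring system count too
      ## (kekulized alternation): one expansion step over ring bonds
      rb <- g$bonds[ringBond, , drop = FALSE]
      for (i in seq_len(nrow(rb))) {
        if (aromatic[rb[i, 1]] || aromatic[rb[i, 2]]) {
          aromatic[rb[i, 1]] <- TRUE; aromatic[rb[i, 2]] <- TRUE
        }
      }
    }
  }
  val <- .STD_VALENCE[g$elem]
  val[is.na(val)] <- 4
  nH <- pmax(0, round(val - bosum))
  nComp <- if (m > 0) {
    ig <- igraph::graph_from_edgelist(g$bonds[, 1:2, drop = FALSE], directed = FALSE)
    if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    igraph::components(ig)$no
  } else n
  g$degree <- deg
  g$bondOrderSum <- bosum
  g$inRing <- inRing
  g$ringBond <- ringBond
  g$aromatic <- aromatic
  g$nH <- as.integer(nH)
  g$nRings <- m - n + nComp     # cyclomatic number (SSSR size)
  g
}

## Number of heavy atoms of a canonical SMILES (cached via the graph).
.heavyAtoms <- function(smiles) {
  vapply(smiles, function(s) {
    g <- .molGraph(s)
    if (is.null(g)) NA_integer_ else length(g$elem)
  }, integer(1), USE.NAMES = FALSE)
}

## ---- graph editing (reaction engine support) -------------------------------

## delete atoms by index, renumbering bonds; returns bare graph (no perception)
.graphDeleteAtoms <- function(g, idx) {
  keep <- setdiff(seq_along(g$elem), idx)
  remap <- integer(length(g$elem)); remap[keep] <- seq_along(keep)
  b <- g$bonds
  if (nrow(b) > 0) {
    ok <- !(b[, 1] %in% idx) & !(b[, 2] %in% idx)
    b <- b[ok, , drop = FALSE]
    if (nrow(b) > 0) { b[, 1] <- remap[b[, 1]]; b[, 2] <- remap[b[, 2]] }
  }
  list(elem = g$elem[keep], bonds = b, map = remap)
}

## merge two bare graphs; returns graph plus offset of g2 atom indices
.graphMerge <- function(g1, g2) {
  off <- length(g1$elem)
  b2 <- g2$bonds
  if (nrow(b2) > 0) { b2[, 1] <- b2[, 1] + off; b2[, 2] <- b2[, 2] + off }
  list(elem = c(g1$elem, g2$elem), bonds = rbind(g1$bonds, b2), offset = off)
}

.graphAddBond <- function(g, from, to, order = 1L) {
  g$bonds <- rbind(g$bonds, c(from, to, order))
  g
}

## Serialize a bare graph to canonical SMILES through an SDF round-trip.
## Returns NA if OpenBabel cannot sanitize the result.
.graphToSmiles <- function(g) {
  n <- length(g$elem)
  if (n == 0) return(NA_character_)
  m <- nrow(g$bonds)
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, g$elem)
  bondl <- if (m > 0)
    sprintf("%3d%3d%3d  0  0  0  0", g$bonds[, 1], g$bonds[, 2], g$bonds[, 3])
  else character(0)
  sdftxt <- paste(c("prod", " dmtaSim", "",
                    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
                    atoms, bondl, "M  END", "$$$$"), collapse = "\n")
  smi <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", paste0(sdftxt, "\n"))),
    error = function(e) ""
  )
  smi <- trimws(strsplit(smi, "[\t\n]")[[1]][1])
  if (is.na(smi) || !nzchar(smi)) return(NA_character_)
  ## disconnected products (fragments) are rejected as unsanitizable results
  if (grepl(".", smi, fixed = TRUE)) return(NA_character_)
  smi
}
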