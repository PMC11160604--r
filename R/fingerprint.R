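## Hashed circular (Morgan-type) fingerprints.
##
## Atom environments of radius 0..r are hashed into a fixed bit space, the
## de-facto similarity standard for building-block ranking. Implemented
## natively over the molecular graph: a polynomial hash in exact double
## arithmetic keeps bits deterministic across platforms, and the sparse
## on-bit representation makes Tanimoto comparisons against a whole catalog
## cheap. Parameters (radius, bit length) are carried in the catalog so
## similarity values are reproducible.

.FP_MOD <- 2147483647

.hmix <- function(h, v) ((h * 48271) %% .FP_MOD + v) %% .FP_MOD

.ELEM_CODE <- c(C = 1, N = 2, O = 3, S = 4, P = 5, B = 6,
                F = 7, Cl = 8, Br = 9, I = 10, H = 11)

#' Compute a hashed circular fingerprint
#'
#' @param smiles a single SMILES string (canonicalized internally).
#' @param radius neighborhood radius (default 2, i.e. ECFP4-like).
#' @param nbits folded bit-space size (default 2048).
#' @return integer vector of on-bit indices in `[0, nbits)`, sorted;
#'   `NULL` for unparseable input.
#' @export
morganBits <- function(smiles, radius = 2L, nbits = 2048L) {
  key <- paste0(smiles, "|", radius, "|", nbits)
  v <- .cacheGet("fp", key)
  if (!is.null(v)) return(v)
  g <- .molGraph(smiles)
  if (is.null(g)) return(NULL)
  n <- length(g$elem)
  code <- .ELEM_CODE[g$elem]; code[is.na(code)] <- 12
  ids <- vapply(seq_len(n), function(i) {
    h <- 7
    h <- .hmix(h, code[i])
    h <- .hmix(h, g$degree[i])
    h <- .hmix(h, g$nH[i])
    h <- .hmix(h, as.integer(g$inRing[i]))
    h <- .hmix(h, as.integer(g$aromatic[i]))
    h
  }, numeric(1))
  nbrs <- vector("list", n)
  if (nrow(g$bonds) > 0) {
    for (b in seq_len(nrow(g$bonds))) {
      f <- g$bonds[b, 1]; t <- g$bonds[b, 2]; o <- g$bonds[b, 3]
      nbrs[[f]] <- rbind(nbrs[[f]], c(t, o))
      nbrs[[t]] <- rbind(nbrs[[t]], c(f, o))
    }
  }
  all_ids <- ids
  cur <- ids
  if (radius >= 1) for (r in seq_len(radius)) {
    nxt <- numeric(n)
    for (i in seq_len(n)) {
      h <- .hmix(11, cur[i])
      nb <- nbrs[[i]]
      if (!is.null(nb)) {
        key2 <- cur[nb[, 1]] * 4 + nb[, 2]
        ord <- order(key2)
        for (j in ord) {
          h <- .hmix(h, nb[j, 2])
          h <- .hmix(h, cur[nb[j, 1]])
        }
      }
      nxt[i] <- h
    }
    cur <- nxt
    all_ids <- c(all_ids, cur)
  }
  bits <- sort(unique(as.integer(all_ids %% nbits)))
  .cacheSet("fp", key, bits)
}

#' Tanimoto similarity between two on-bit sets
#'
#' @param a,b integer vectors of on-bit indices (as from [morganBits()]).
#' @return similarity in `[0, 1]`; 0 when either set is empty.
#' @export
tanimoto <- function(a, b) {
  if (is.null(a) || is.null(b) || length(a) == 0 || length(b) == 0) return(0)
  i <- length(intersect(a, b))
  i / (length(a) + length(b) - i)
}
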