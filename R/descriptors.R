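## Physicochemical descriptors.
##
## Atomic-contribution Log P (Crippen-type), molecular weight, TPSA and
## H-bond counts come from OpenBabel via ChemmineR::propOB, batched over all
## uncached structures in one call. Graph-derived counts (heavy atoms, rings,
## fraction Csp3, rotatable bonds) come from the native molecular graph.
## Drug-likeness is the published QED desirability (Bickerton et al. 2012
## ADS parameters, weighted-mean form); the structural-alert term is fixed at
## zero alerts for this chemistry (see the methods vignette).

## fetch cached propOB rows, computing misses in one batched call
.propRows <- function(smiles) {
  out <- vector("list", length(smiles))
  miss <- integer(0)
  for (i in seq_along(smiles)) {
    v <- .cacheGet("prop", smiles[i])
    if (is.null(v)) miss <- c(miss, i) else out[[i]] <- v
  }
  if (length(miss)) {
    ms <- smiles[miss]
    sdfs <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(ms, paste0("p", seq_along(ms))))),
      error = function(e) NULL
    )
    if (!is.null(sdfs) && length(sdfs) == length(ms)) {
      p <- tryCatch(suppressWarnings(ChemmineR::propOB(sdfs)), error = function(e) NULL)
      if (!is.null(p) && nrow(p) == length(ms)) {
        for (j in seq_along(miss)) {
          row <- list(logP = as.numeric(p$logP[j]), MW = as.numeric(p$MW[j]),
                      TPSA = as.numeric(p$TPSA[j]), HBA = as.numeric(p$HBA1[j]),
                      HBD = as.numeric(p$HBD[j]), MR = as.numeric(p$MR[j]))
          out[[miss[j]]] <- row
          .cacheSet("prop", ms[j], row)
        }
      }
    }
    ## fall back to per-molecule conversion for any still missing
    for (i in seq_along(smiles)) {
      if (is.null(out[[i]])) {
        sdfs <- tryCatch(
          suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles[i], "p1"))),
          error = function(e) NULL
        )
        row <- NULL
        if (!is.null(sdfs)) {
          p <- tryCatch(suppressWarnings(ChemmineR::propOB(sdfs)), error = function(e) NULL)
          if (!is.null(p) && nrow(p) == 1)
            row <- list(logP = as.numeric(p$logP[1]), MW = as.numeric(p$MW[1]),
                        TPSA = as.numeric(p$TPSA[1]), HBA = as.numeric(p$HBA1[1]),
                        HBD = as.numeric(p$HBD[1]), MR = as.numeric(p$MR[1]))
        }
        if (is.null(row))
          row <- list(logP = NA_real_, MW = NA_real_, TPSA = NA_real_,
                      HBA = NA_real_, HBD = NA_real_, MR = NA_real_)
        out[[i]] <- row
        .cacheSet("prop", smiles[i], row)
      }
    }
  }
  out
}

## graph-derived structural descriptors for one molecule
.structRow <- function(smiles) {
  v <- .cacheGet("struct", smiles)
  if (!is.null(v)) return(v)
  g <- .molGraph(smiles)
  if (is.null(g)) {
    v <- list(heavyAtoms = NA_integer_, ringCount = NA_integer_,
              aromaticRings = NA_integer_, fracCsp3 = NA_real_, rotB = NA_integer_)
    return(.cacheSet("struct", smiles, v))
  }
  n <- length(g$elem)
  isC <- g$elem == "C"
  sp3 <- isC & !g$aromatic
  if (any(isC) && nrow(g$bonds) > 0) {
    hasMulti <- logical(n)
    mb <- g$bonds[g$bonds[, 3] > 1L, , drop = FALSE]
    if (nrow(mb) > 0) hasMulti[unique(c(mb[, 1], mb[, 2]))] <- TRUE
    sp3 <- isC & !hasMulti
  }
  arRings <- 0L
  if (any(g$ringBond)) {
    arB <- g$ringBond & g$aromatic[g$bonds[, 1]] & g$aromatic[g$bonds[, 2]]
    if (any(arB)) {
      sub <- g$bonds[arB, 1:2, drop = FALSE]
      verts <- unique(c(sub[, 1], sub[, 2]))
      ig <- igraph::graph_from_edgelist(matrix(match(sub, verts), ncol = 2), directed = FALSE)
      arRings <- nrow(sub) - length(verts) + igraph::components(ig)$no
    }
  }
  rot <- 0L
  if (nrow(g$bonds) > 0) {
    cand <- !g$ringBond & g$bonds[, 3] == 1L &
      g$degree[g$bonds[, 1]] >= 2L & g$degree[g$bonds[, 2]] >= 2L &
      g$elem[g$bonds[, 1]] != "H" & g$elem[g$bonds[, 2]] != "H"
    rot <- sum(cand)
  }
  v <- list(heavyAtoms = n, ringCount = as.integer(max(0L, g$nRings)),
            aromaticRings = as.integer(max(0L, arRings)),
            fracCsp3 = if (any(isC)) sum(sp3) / sum(isC) else 0,
            rotB = as.integer(rot))
  .cacheSet("struct", smiles, v)
}

## QED asymmetric double sigmoid parameters (published values)
.QED_ADS <- list(
  MW     = c(A = 2.817065973, B = 392.5754953, C = 290.7489764, D = 2.419764353,  E = 49.22325677, F = 65.37051707, DMAX = 104.9805561),
  ALOGP  = c(A = 3.172690585, B = 137.8624751, C = 2.534937431, D = 4.581497897,  E = 0.822739154, F = 0.576295591, DMAX = 131.3186604),
  HBA    = c(A = 2.948620388, B = 160.4605972, C = 3.615294657, D = 4.435986202,  E = 0.290141953, F = 1.300669958, DMAX = 148.7763046),
  HBD    = c(A = 1.618662227, B = 1010.051101, C = 0.985094388, D = 1e-09,        E = 0.713820843, F = 0.920922555, DMAX = 258.1632616),
  PSA    = c(A = 1.876861559, B = 125.2232657, C = 62.90773554, D = 87.83366614,  E = 12.01999824, F = 28.51324732, DMAX = 104.5686167),
  ROTB   = c(A = 0.01,        B = 272.4121427, C = 2.55837997,  D = 1.565547684,  E = 1.271567166, F = 2.758063707, DMAX = 105.4420403),
  AROM   = c(A = 3.21778897,  B = 957.7374108, C = 2.274627939, D = 1e-09,        E = 1.317690384, F = 0.375760881, DMAX = 312.337261),
  ALERTS = c(A = 0.01,        B = 1199.094025, C = -0.09002883, D = 1e-09,        E = 0.185904477, F = 0.875193782, DMAX = 417.725314)
)
.QED_W <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
            PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.ads <- function(x, p) {
  d <- p["A"] +
    p["B"] / (1 + exp(-(x - p["C"] + p["D"] / 2) / p["E"])) *
      (1 - 1 / (1 + exp(-(x - p["C"] - p["D"] / 2) / p["F"])))
  unname(pmax(d / p["DMAX"], 1e-6))
}

.qedFromProps <- function(mw, alogp, hba, hbd, psa, rotb, arom, alerts = 0) {
  vals <- c(MW = mw, ALOGP = alogp, HBA = hba, HBD = hbd,
            PSA = psa, ROTB = rotb, AROM = arom, ALERTS = alerts)
  d <- vapply(names(vals), function(k) .ads(vals[[k]], .QED_ADS[[k]]), numeric(1))
  exp(sum(.QED_W * log(d)) / sum(.QED_W))
}

#' Descriptor table for a set of molecules
#'
#' One row per input structure: Crippen-type Log P, molecular weight, TPSA,
#' H-bond acceptor/donor counts, heavy atoms, ring count, aromatic rings,
#' fraction Csp3 (sp3 carbons over all carbons), rotatable bonds, and QED
#' drug-likeness. Unparseable structures yield `NA` rows.
#'
#' @param smiles character vector of SMILES.
#' @return a `data.frame` with one row per input.
#' @export
descriptorTable <- function(smiles) {
  pr <- .propRows(smiles)
  st <- lapply(smiles, .structRow)
  qed <- vapply(seq_along(smiles), function(i) {
    p <- pr[[i]]; s <- st[[i]]
    if (is.na(p$MW) || is.na(s$heavyAtoms)) return(NA_real_)
    .qedFromProps(p$MW, p$logP, p$HBA, p$HBD, p$TPSA, s$rotB, s$aromaticRings)
  }, numeric(1))
  data.frame(
    smiles = smiles,
    logP = vapply(pr, `[[`, numeric(1), "logP"),
    MW = vapply(pr, `[[`, numeric(1), "MW"),
    TPSA = vapply(pr, `[[`, numeric(1), "TPSA"),
    HBA = vapply(pr, `[[`, numeric(1), "HBA"),
    HBD = vapply(pr, `[[`, numeric(1), "HBD"),
    heavyAtoms = vapply(st, `[[`, integer(1), "heavyAtoms"),
    ringCount = vapply(st, `[[`, integer(1), "ringCount"),
    aromaticRings = vapply(st, `[[`, integer(1), "aromaticRings"),
    fracCsp3 = vapply(st, `[[`, numeric(1), "fracCsp3"),
    rotB = vapply(st, `[[`, integer(1), "rotB"),
    qed = qed,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
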