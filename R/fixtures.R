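## Synthetic fixtures: a desk-scale stand-in for every external dependency --
## building-block catalog, reaction repertoire, fragment hits, and
## ground-truth oracles exhibiting structure-activity relationships (SAR)
## and activity cliffs.

## ---- building blocks -------------------------------------------------------

## carbon-skeleton prefixes that accept one more substituent atom
.FRAG_PREFIX <- c(
  "C", "CC", "CCC", "CCCC", "CC(C)", "CC(C)C", "CCC(C)",
  "C1CCC1", "C1CCCC1", "C1CCCCC1", "CC1CCCC1", "C1CCOC1", "C1CCNC1",
  "c1ccccc1", "Cc1ccc(cc1)", "CCc1ccc(cc1)", "COc1ccc(cc1)",
  "Fc1ccc(cc1)", "Cc1cccc(C)c1", "c1ccc2ccccc2c1", "Cc1occc1", "Cc1sccc1",
  "c1ccncc1", "Cc1ccncc1", "CCCCC", "CCOCC", "CC(C)(C)C", "CCCCCC"
)
## aromatic cores that accept a halide / boronic handle
.AROM_PREFIX <- c(
  "c1ccccc1", "Cc1ccc(cc1)", "COc1ccc(cc1)", "CCc1ccc(cc1)",
  "Fc1ccc(cc1)", "Cc1cccc(C)c1", "c1ccncc1", "Cc1ccncc1",
  "c1ccc2ccccc2c1", "Cc1occc1", "Cc1sccc1"
)

.blockGrid <- function() {
  rbind(
    data.frame(role = "carboxylic_acid", smiles = paste0(.FRAG_PREFIX, "C(=O)O")),
    data.frame(role = "amine", smiles = paste0(.FRAG_PREFIX, "N")),
    data.frame(role = "amine", smiles = paste0(.FRAG_PREFIX, "NC")),
    data.frame(role = "aldehyde", smiles = paste0(.FRAG_PREFIX, "C=O")),
    data.frame(role = "sulfonyl_chloride", smiles = paste0(.FRAG_PREFIX, "S(=O)(=O)Cl")),
    data.frame(role = "aryl_halide", smiles = paste0(.AROM_PREFIX, "Br")),
    data.frame(role = "aryl_halide", smiles = paste0(.AROM_PREFIX, "Cl")),
    data.frame(role = "aryl_boronic_acid", smiles = paste0(.AROM_PREFIX, "B(O)O"))
  )
}

#' Generate a synthetic building-block catalog
#'
#' Seeded combinatorial decoration of ring/chain carbon scaffolds with the
#' functional handles of the built-in reaction repertoire (carboxylic acid,
#' primary/secondary amine, aldehyde, sulfonyl chloride, aryl halide, aryl
#' boronic acid). Blocks are distinct canonical structures of at most
#' `maxHeavyAtoms` heavy atoms, and every reactant role is guaranteed at
#' least 5 compatible blocks.
#'
#' @param n number of blocks (>= 20).
#' @param seed RNG seed.
#' @param maxHeavyAtoms size cap per block (default 12).
#' @return a [BlockLibrary-class] with ids `BB0001`, `BB0002`, ...
#' @export
generateBuildingBlocks <- function(n = 120, seed = 1, maxHeavyAtoms = 12L) {
  if (n < 20) stop("n must be >= 20")
  grid <- .blockGrid()
  can <- canonicalSmiles(grid$smiles)
  ok <- !is.na(can)
  grid <- grid[ok, , drop = FALSE]; grid$can <- can[ok]
  dup <- duplicated(grid$can)
  grid <- grid[!dup, , drop = FALSE]
  ha <- .heavyAtoms(grid$can)
  grid <- grid[!is.na(ha) & ha <= maxHeavyAtoms, , drop = FALSE]
  ## keep only blocks whose advertised handle is actually detected
  det <- vapply(seq_len(nrow(grid)),
                function(i) matchesRole(grid$can[i], grid$role[i]), logical(1))
  grid <- grid[det, , drop = FALSE]
  if (nrow(grid) < n)
    stop("block grid too small for n = ", n, " (", nrow(grid), " candidates)")
  roles <- unique(grid$role)
  deficit <- roles[vapply(roles, function(r) sum(grid$role == r), integer(1)) < 5]
  if (length(deficit))
    stop("catalog constraint unsatisfiable: <5 blocks for role(s) ",
         paste(deficit, collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.mixSeed(seed, 97), kind = "Mersenne-Twister")
  ## guarantee >= 5 per role, fill the remainder at random
  pick <- integer(0)
  for (r in roles) {
    idx <- which(grid$role == r)
    pick <- c(pick, idx[sample.int(length(idx), min(5, length(idx)))])
  }
  rest <- setdiff(seq_len(nrow(grid)), pick)
  extra <- n - length(pick)
  if (extra > 0) pick <- c(pick, rest[sample.int(length(rest), min(extra, length(rest)))])
  pick <- sort(unique(pick))[seq_len(min(n, length(unique(pick))))]
  sel <- grid[pick, , drop = FALSE]
  buildLibrary(sprintf("BB%04d", seq_len(nrow(sel))), sel$can)
}

## ---- hits ------------------------------------------------------------------

#' Generate fragment-sized starting hits
#'
#' One-step products of random role-compatible block pairs, filtered to
#' fragment-like size, each carrying a valid replayable synthetic route.
#'
#' @param k number of hits (>= 1).
#' @param library a [BlockLibrary-class].
#' @param templates reaction repertoire (default built-in).
#' @param seed RNG seed.
#' @param maxHeavyAtoms fragment size cap (default 20).
#' @return list of compound records: `list(smiles, route, parents = character(0))`.
#' @export
generateHits <- function(k = 5, library, templates = defaultReactions(),
                         seed = 1, maxHeavyAtoms = 20L) {
  stopifnot(k >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.mixSeed(seed, 131), kind = "Mersenne-Twister")
  tab <- blockTable(library)
  hits <- list(); seen <- character(0)
  tries <- 0
  while (length(hits) < k && tries < 4000) {
    tries <- tries + 1
    tm <- templates[[sample.int(length(templates), 1)]]
    roleA <- tm@roles[1]; roleB <- tm@roles[2]
    candA <- which(matchesRole(tab$smiles, roleA))
    candB <- which(matchesRole(tab$smiles, roleB))
    if (!length(candA) || !length(candB)) next
    a <- candA[sample.int(length(candA), 1)]
    b <- candB[sample.int(length(candB), 1)]
    prods <- applyTemplate(tm, c(tab$smiles[a], tab$smiles[b]))
    if (!length(prods)) next
    p <- prods[sample.int(length(prods), 1)]
    if (p %in% seen) next
    if (is.na(.heavyAtoms(p)) || .heavyAtoms(p) > maxHeavyAtoms) next
    route <- syntheticRoute(list(list(
      template = tm@templateId,
      reactants = list(blockRef(tab$blockId[a], tab$smiles[a]),
                       blockRef(tab$blockId[b], tab$smiles[b])),
      product = p)))
    hits[[length(hits) + 1]] <- list(smiles = p, route = route, parents = character(0))
    seen <- c(seen, p)
  }
  if (length(hits) < k) stop("could not generate ", k, " distinct hits")
  hits
}

## ---- structure-activity landscape ------------------------------------------

.LANDSCAPE_DESCRIPTORS <- c("logP", "MW", "TPSA", "HBA", "HBD",
                            "ringCount", "fracCsp3", "heavyAtoms")

#' Synthetic affinity landscape specification
#'
#' A hidden optimum in a z-scored physicochemical descriptor space. Affinity
#' decays smoothly (Gaussian kernel) with descriptor distance from the
#' optimum (SAR), and substructure motifs add sharp bonuses/penalties
#' (activity cliffs). Values are clipped to the pIC50 dynamic range.
#'
#' @slot seed integer seed the landscape was built with.
#' @slot center,scale descriptor z-scoring statistics (named numeric).
#' @slot optimum hidden optimum in z-scored descriptor units.
#' @slot optimumSmiles the reachable product the optimum was placed on.
#' @slot optimumRoute a replayable one-step synthetic route for that product.
#' @slot smoothScale SAR decay length in z-scored descriptor units.
#' @slot cliffs list of `list(smarts =, delta =)` motifs.
#' @slot baseLevel,amplitude pIC50 floor and SAR peak height.
#' @slot dynamicRange pIC50 clipping range.
#' @export
setClass("LandscapeSpec",
  representation(seed = "numeric", center = "numeric", scale = "numeric",
                 optimum = "numeric", optimumSmiles = "character",
                 optimumRoute = "list",
                 smoothScale = "numeric", cliffs = "list",
                 baseLevel = "numeric", amplitude = "numeric",
                 dynamicRange = "numeric"))

setMethod("show", "LandscapeSpec", function(object) {
  cat(sprintf("LandscapeSpec: base %.1f + amplitude %.1f, decay %.2f, %d cliff motif(s)\n",
              object@baseLevel, object@amplitude, object@smoothScale,
              length(object@cliffs)))
  cat("  optimum at:", object@optimumSmiles, "\n")
})

## z-scored descriptor matrix (rows = molecules)
.descMatrix <- function(smiles, center = NULL, scale = NULL) {
  d <- descriptorTable(smiles)
  m <- as.matrix(d[, .LANDSCAPE_DESCRIPTORS])
  if (!is.null(center)) m <- sweep(m, 2, center[.LANDSCAPE_DESCRIPTORS], "-")
  if (!is.null(scale)) m <- sweep(m, 2, scale[.LANDSCAPE_DESCRIPTORS], "/")
  m
}

## count of a SMARTS motif per molecule, memoized; misses searched in batch
.motifCount <- function(smiles, smarts) {
  out <- rep(NA_real_, length(smiles))
  miss <- integer(0)
  for (i in seq_along(smiles)) {
    v <- .cacheGet("motif", paste0(smiles[i], "|", smarts))
    if (is.null(v)) miss <- c(miss, i) else out[i] <- v
  }
  if (length(miss)) {
    ms <- smiles[miss]
    sdfs <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(ms, paste0("m", seq_along(ms))))),
      error = function(e) NULL)
    cnt <- if (is.null(sdfs)) rep(NA_real_, length(ms)) else
      tryCatch(as.numeric(ChemmineR::smartsSearchOB(sdfs, smarts, uniqueMatches = FALSE)),
               error = function(e) rep(NA_real_, length(ms)))
    if (length(cnt) != length(ms)) cnt <- rep(NA_real_, length(ms))
    for (j in seq_along(miss)) {
      out[miss[j]] <- cnt[j]
      .cacheSet("motif", paste0(ms[j], "|", smarts), cnt[j])
    }
  }
  out
}

#' Design a synthetic affinity landscape over a fixture chemical space
#'
#' Probes the reachable one-step product space of the catalog, z-scores the
#' descriptor space against it, and places the hidden optimum on a probed
#' product with lead-like lipophilicity (so that the TCP is attainable from
#' the fixture space).
#'
#' @param library a [BlockLibrary-class].
#' @param templates reaction repertoire.
#' @param seed RNG seed.
#' @param nProbe number of probe products used for calibration.
#' @param smoothScale SAR decay length (z-scored descriptor units).
#' @param baseLevel,amplitude pIC50 floor and peak height.
#' @param cliffs list of `list(smarts =, delta =)` activity-cliff motifs;
#'   default: aromatic fluorine (-2.0) and an extended hexyl chain (-1.8)
#'   penalties -- rare motifs, so a one-heavy-atom change (adding an aryl F,
#'   or one CH2 that completes the chain) can break potency while the bulk of
#'   the space keeps smooth structure-activity relationships.
#' @return a [LandscapeSpec-class].
#' @export
designLandscape <- function(library, templates = defaultReactions(), seed = 1,
                            nProbe = 250, smoothScale = 2.2,
                            baseLevel = 4, amplitude = 4.5,
                            cliffs = list(list(smarts = "cF", delta = -2.0),
                                          list(smarts = "CCCCCC", delta = -1.8))) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.mixSeed(seed, 211), kind = "Mersenne-Twister")
  tab <- blockTable(library)
  probes <- character(0)
  recipes <- list()   # per probe: the (template, blocks) that produced it
  tries <- 0
  while (length(probes) < nProbe && tries < nProbe * 20) {
    tries <- tries + 1
    tm <- templates[[sample.int(length(templates), 1)]]
    candA <- which(matchesRole(tab$smiles, tm@roles[1]))
    candB <- which(matchesRole(tab$smiles, tm@roles[2]))
    if (!length(candA) || !length(candB)) next
    a <- candA[sample.int(length(candA), 1)]
    b <- candB[sample.int(length(candB), 1)]
    prods <- applyTemplate(tm, c(tab$smiles[a], tab$smiles[b]))
    if (length(prods) && !(prods[1] %in% probes)) {
      probes <- c(probes, prods[1])
      recipes[[length(recipes) + 1]] <- list(tm = tm, a = a, b = b)
    }
  }
  d <- descriptorTable(probes)
  m <- as.matrix(d[, .LANDSCAPE_DESCRIPTORS])
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]; probes <- probes[keep]
  recipes <- recipes[keep]; d <- d[keep, , drop = FALSE]
  center <- colMeans(m)
  scale <- apply(m, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-8] <- 1
  mz <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
  ## optimum: a probed product with lead-like lipophilicity (Log P in [1, 3],
  ## moderate size) placed toward the periphery of the product cloud -- the
  ## TCP stays attainable, but unguided sampling (which concentrates near the
  ## cloud's center) rarely wanders into the basin
  noCliff <- rep(TRUE, length(probes))
  for (cl in cliffs) {
    cnt <- .motifCount(probes, cl$smarts)
    noCliff <- noCliff & !is.na(cnt) & cnt == 0
  }
  pref <- which(d$logP >= 1 & d$logP <= 3 & d$MW >= 180 & d$MW <= 350 & noCliff)
  if (!length(pref)) pref <- which(noCliff)
  if (!length(pref)) pref <- seq_along(probes)
  dd <- sqrt(rowSums(mz^2))
  optIdx <- pref[order(dd[pref])][ceiling(0.95 * length(pref))]
  rec <- recipes[[optIdx]]
  optRoute <- syntheticRoute(list(list(
    template = rec$tm@templateId,
    reactants = list(blockRef(tab$blockId[rec$a], tab$smiles[rec$a]),
                     blockRef(tab$blockId[rec$b], tab$smiles[rec$b])),
    product = probes[optIdx])))
  new("LandscapeSpec", seed = as.numeric(seed), center = center, scale = scale,
      optimum = mz[optIdx, ], optimumSmiles = probes[optIdx],
      optimumRoute = optRoute,
      smoothScale = smoothScale, cliffs = cliffs,
      baseLevel = baseLevel, amplitude = amplitude, dynamicRange = c(3, 11))
}

#' Synthetic affinity oracle (pIC50)
#'
#' `pIC50(m) = base + amplitude * exp(-d(m)^2 / (2 * smoothScale^2)) +
#' sum(cliff deltas for matched motifs)`, clipped to the dynamic range, where
#' `d` is the Euclidean distance of the molecule's z-scored descriptor vector
#' from the hidden optimum. Unevaluable structures yield `NA`.
#'
#' @param spec a [LandscapeSpec-class].
#' @return an [Oracle-class] named `"affinity"` (units pIC50).
#' @export
syntheticAffinity <- function(spec) {
  force(spec)
  affinityOracle(function(smiles) {
    if (length(smiles) == 0) return(numeric(0))
    key <- paste0("aff", spec@seed)
    out <- rep(NA_real_, length(smiles))
    miss <- integer(0)
    for (i in seq_along(smiles)) {
      v <- .cacheGet(key, smiles[i])
      if (is.null(v)) miss <- c(miss, i) else out[i] <- v
    }
    if (length(miss)) {
      ms <- smiles[miss]
      mz <- .descMatrix(ms, spec@center, spec@scale)
      dist <- sqrt(rowSums(sweep(mz, 2, spec@optimum, "-")^2))
      v <- spec@baseLevel +
        spec@amplitude * exp(-dist^2 / (2 * spec@smoothScale^2))
      for (cl in spec@cliffs) {
        cnt <- .motifCount(ms, cl$smarts)
        v <- v + ifelse(!is.na(cnt) & cnt > 0, cl$delta, 0)
      }
      v <- pmin(pmax(v, spec@dynamicRange[1]), spec@dynamicRange[2])
      v[apply(mz, 1, anyNA)] <- NA_real_
      for (j in seq_along(miss)) {
        out[miss[j]] <- v[j]
        .cacheSet(key, ms[j], v[j])
      }
    }
    out
  }, label = "synthetic-landscape")
}

#' Synthetic solubility oracle (Log S)
#'
#' An ESOL-style linear surrogate: `Log S = 0.4 - 0.75 LogP - 0.005 MW +
#' jitter`, with a small deterministic structure-hashed jitter (SD 0.25)
#' seeded by `seed`, clipped to `[-8, 1]`. The strong negative coupling to
#' Log P reflects the usual lipophilicity-solubility trade-off.
#'
#' @param seed integer seed for the jitter hash.
#' @return an [Oracle-class] named `"solubility"` (units Log S).
#' @export
syntheticSolubility <- function(seed = 1) {
  force(seed)
  solubilityOracle(function(smiles) {
    if (length(smiles) == 0) return(numeric(0))
    pr <- .propRows(smiles)
    vapply(seq_along(smiles), function(i) {
      p <- pr[[i]]
      if (is.na(p$logP) || is.na(p$MW)) return(NA_real_)
      h <- 13
      for (ch in utf8ToInt(smiles[i])) h <- .hmix(h, ch)
      h <- .hmix(h, seed %% 100000)
      u <- min(max(h / .FP_MOD, 1e-6), 1 - 1e-6)
      v <- 0.4 - 0.75 * p$logP - 0.005 * p$MW + 0.25 * stats::qnorm(u)
      min(max(v, -8), 1)
    }, numeric(1))
  }, label = "synthetic-esol")
}

## ---- bundled study conditions ----------------------------------------------

#' Fixture TCP
#'
#' The oral-drug TCP with the affinity thresholds rescaled to the synthetic
#' landscape's achievable range (the docking pIC50 scale does not transfer to
#' a synthetic landscape); Log P and Log S windows are kept verbatim.
#'
#' @param spec a [LandscapeSpec-class].
#' @param successCriterion `"acceptable"` (default) or `"ideal"`.
#' @return a [TCP-class].
#' @export
fixtureTCP <- function(spec, successCriterion = "acceptable") {
  peak <- spec@baseLevel + spec@amplitude
  tcp(list(
    objectiveSpec("affinity", "pIC50",
                  c(peak - 0.3, Inf), c(peak - 0.1, Inf), spec@dynamicRange),
    objectiveSpec("lipophilicity", "Log P", c(0, 4), c(0, 3), c(-1, 8)),
    objectiveSpec("solubility", "Log S", c(-4, 0), c(-3, 0), c(-8, 1))
  ), successCriterion = successCriterion)
}

#' The default synthetic study conditions
#'
#' Bundles catalog, reaction repertoire, hits, oracles, landscape, and TCP at
#' the package's standard desk scale (120 blocks, 4 reactions, 5 fragment
#' hits).
#'
#' @param seed integer seed.
#' @param nBlocks catalog size.
#' @param nHits number of starting hits.
#' @param hitWindow pIC50 window a starting hit's true affinity must fall in
#'   (the fragment screen delivers weak-but-genuine actives).
#' @return named list: `library`, `templates`, `hits`, `landscape`, `tcp`,
#'   `oracles` (list of affinity/lipophilicity/solubility [Oracle-class]).
#' @export
defaultFixture <- function(seed = 1, nBlocks = 120, nHits = 5,
                           hitWindow = c(4.4, 5.0)) {
  lib <- generateBuildingBlocks(nBlocks, seed = seed)
  tmpl <- defaultReactions()
  land <- designLandscape(lib, tmpl, seed = seed)
  ## a fragment screen delivers weak-but-genuine actives: keep candidate hits
  ## whose true affinity sits in a weak-active window above the landscape floor
  aff <- syntheticAffinity(land)
  cand <- generateHits(16 * nHits, lib, tmpl, seed = seed)
  csm <- vapply(cand, `[[`, character(1), "smiles")
  vals <- oracleValues(aff, csm)
  ## screeners also drop liability motifs: candidates carrying a cliff motif
  ## are excluded so starting chemical matter sits on the smooth SAR flank
  clean <- rep(TRUE, length(csm))
  for (cl in land@cliffs) {
    cnt <- .motifCount(csm, cl$smarts)
    clean <- clean & !is.na(cnt) & cnt == 0
  }
  vals[!clean] <- NA_real_
  keep <- which(!is.na(vals) & vals >= hitWindow[1] & vals <= hitWindow[2])
  if (length(keep) < nHits) {
    ## fill any shortfall with the candidates closest to the window
    mid <- mean(hitWindow)
    rest <- setdiff(order(abs(vals - mid)), keep)
    keep <- c(keep, rest)
  }
  hits <- cand[keep[seq_len(nHits)]]
  list(
    library = lib, templates = tmpl, hits = hits, landscape = land,
    tcp = fixtureTCP(land),
    oracles = list(affinity = syntheticAffinity(land),
                   lipophilicity = lipophilicityOracle(),
                   solubility = syntheticSolubility(seed))
  )
}

#' Write the fixture inputs in the formats real inputs use
#'
#' Emits `catalog.csv`, `reactions.txt`, `hits.smi`, and `landscape.json`
#' into a directory, so real catalogs can drop in unchanged.
#'
#' @param fixture from [defaultFixture()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCatalog(fixture$library, file.path(dir, "catalog.csv"))
  writeReactionTemplates(fixture$templates, file.path(dir, "reactions.txt"))
  writeLines(vapply(fixture$hits, `[[`, character(1), "smiles"),
             file.path(dir, "hits.smi"))
  l <- fixture$landscape
  jsonlite::write_json(list(
    seed = l@seed, center = as.list(l@center), scale = as.list(l@scale),
    optimum = unname(l@optimum), optimumSmiles = l@optimumSmiles,
    smoothScale = l@smoothScale, cliffs = l@cliffs,
    baseLevel = l@baseLevel, amplitude = l@amplitude,
    dynamicRange = l@dynamicRange
  ), file.path(dir, "landscape.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
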