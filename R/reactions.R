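## Reaction engine.
##
## Products are constructed by direct edits of the molecular graph (bond
## formation plus leaving-group removal), then sanitized and canonicalized by
## OpenBabel on the way back to SMILES. The repertoire is a registry of
## standard two-component med-chem couplings keyed by reaction SMARTS;
## functional-group sites are located by graph rules rather than a general
## SMARTS engine (see the methods vignette for the scope of this choice).

## ---- functional-group site finders -----------------------------------------
## each returns a list of sites; a site is a named integer vector of atom roles

.findCarboxylicAcid <- function(g) {
  sites <- list()
  for (c in which(g$elem == "C")) {
    if (g$degree[c] > 3) next
    nb <- .neighbors(g, c)
    dblO <- nb[g$elem[nb[, 1]] == "O" & nb[, 2] == 2 & g$degree[nb[, 1]] == 1, 1]
    sngO <- nb[g$elem[nb[, 1]] == "O" & nb[, 2] == 1 & g$degree[nb[, 1]] == 1, 1]
    if (length(dblO) == 1 && length(sngO) == 1)
      sites[[length(sites) + 1]] <- c(c = c, o = unname(dblO), oh = unname(sngO))
  }
  sites
}

.findAmine <- function(g) {
  sites <- list()
  for (n in which(g$elem == "N")) {
    nb <- .neighbors(g, n)
    if (nrow(nb) == 0 || nrow(nb) > 2) next        # primary or secondary only
    if (any(nb[, 2] != 1)) next                    # all single bonds
    ## exclude amide/sulfonamide nitrogens and conjugated ring nitrogens
    bad <- FALSE
    for (k in nb[, 1]) {
      knb <- .neighbors(g, k)
      if (g$elem[k] == "C" && any(g$elem[knb[, 1]] == "O" & knb[, 2] == 2)) bad <- TRUE
      if (g$elem[k] == "S" && any(g$elem[knb[, 1]] == "O" & knb[, 2] == 2)) bad <- TRUE
    }
    if (g$inRing[n] && g$aromatic[n]) bad <- TRUE
    if (!bad) sites[[length(sites) + 1]] <- c(n = n)
  }
  sites
}

.findAldehyde <- function(g) {
  sites <- list()
  for (c in which(g$elem == "C")) {
    if (g$degree[c] != 2) next                     # one C neighbor + the O
    nb <- .neighbors(g, c)
    dblO <- nb[g$elem[nb[, 1]] == "O" & nb[, 2] == 2 & g$degree[nb[, 1]] == 1, 1]
    other <- nb[g$elem[nb[, 1]] != "O", 1]
    if (length(dblO) == 1 && length(other) == 1)
      sites[[length(sites) + 1]] <- c(c = c, o = unname(dblO))
  }
  sites
}

.findArylHalide <- function(g) {
  sites <- list()
  for (x in which(g$elem %in% c("Br", "Cl", "I"))) {
    if (g$degree[x] != 1) next
    nb <- .neighbors(g, x)
    c <- unname(nb[1, 1])
    if (g$elem[c] == "C" && g$aromatic[c])
      sites[[length(sites) + 1]] <- c(c = c, x = x)
  }
  sites
}

.findBoronicAcid <- function(g) {
  sites <- list()
  for (b in which(g$elem == "B")) {
    nb <- .neighbors(g, b)
    os <- nb[g$elem[nb[, 1]] == "O" & nb[, 2] == 1 & g$degree[nb[, 1]] == 1, 1]
    cs <- nb[g$elem[nb[, 1]] == "C", 1]
    if (length(os) == 2 && length(cs) == 1 && g$aromatic[cs])
      sites[[length(sites) + 1]] <- c(c = unname(cs), b = b, o1 = unname(os[1]), o2 = unname(os[2]))
  }
  sites
}

.findSulfonylChloride <- function(g) {
  sites <- list()
  for (s in which(g$elem == "S")) {
    nb <- .neighbors(g, s)
    os <- nb[g$elem[nb[, 1]] == "O" & nb[, 2] == 2, 1]
    cl <- nb[g$elem[nb[, 1]] == "Cl" & nb[, 2] == 1, 1]
    if (length(os) == 2 && length(cl) == 1)
      sites[[length(sites) + 1]] <- c(s = s, cl = unname(cl))
  }
  sites
}

.neighbors <- function(g, i) {
  b <- g$bonds
  if (nrow(b) == 0) return(matrix(integer(0), ncol = 2))
  sel1 <- b[, 1] == i; sel2 <- b[, 2] == i
  rbind(cbind(b[sel1, 2], b[sel1, 3]), cbind(b[sel2, 1], b[sel2, 3]))
}

.ROLE_FINDERS <- list(
  carboxylic_acid   = .findCarboxylicAcid,
  amine             = .findAmine,
  aldehyde          = .findAldehyde,
  aryl_halide       = .findArylHalide,
  aryl_boronic_acid = .findBoronicAcid,
  sulfonyl_chloride = .findSulfonylChloride
)

## ---- graph edits per template ----------------------------------------------
## combine(gA, siteA, gB, siteB) -> bare merged graph, or NULL

.combineAmide <- function(gA, sA, gB, sB) {
  dA <- .graphDeleteAtoms(gA, sA[["oh"]])
  mg <- .graphMerge(dA, gB)
  .graphAddBond(mg, dA$map[sA[["c"]]], mg$offset + sB[["n"]])
}

.combineSulfonamide <- function(gA, sA, gB, sB) {
  dA <- .graphDeleteAtoms(gA, sA[["cl"]])
  mg <- .graphMerge(dA, gB)
  .graphAddBond(mg, dA$map[sA[["s"]]], mg$offset + sB[["n"]])
}

.combineReductiveAmination <- function(gA, sA, gB, sB) {
  dA <- .graphDeleteAtoms(gA, sA[["o"]])
  mg <- .graphMerge(dA, gB)
  .graphAddBond(mg, dA$map[sA[["c"]]], mg$offset + sB[["n"]])
}

.combineSuzuki <- function(gA, sA, gB, sB) {
  dA <- .graphDeleteAtoms(gA, sA[["x"]])
  dB <- .graphDeleteAtoms(gB, c(sB[["b"]], sB[["o1"]], sB[["o2"]]))
  mg <- .graphMerge(dA, dB)
  .graphAddBond(mg, dA$map[sA[["c"]]], mg$offset + dB$map[sB[["c"]]])
}

.TEMPLATE_COMBINERS <- list(
  amide_coupling       = .combineAmide,
  sulfonamide          = .combineSulfonamide,
  reductive_amination  = .combineReductiveAmination,
  suzuki_coupling      = .combineSuzuki
)

.TEMPLATE_SMARTS <- c(
  amide_coupling      = "[C:1](=[O:2])[OX2H1].[NX3;H2,H1;!$(N[C,S]=O):3]>>[C:1](=[O:2])[N:3]",
  sulfonamide         = "[S:1](=[O:2])(=[O:3])Cl.[NX3;H2,H1;!$(N[C,S]=O):4]>>[S:1](=[O:2])(=[O:3])[N:4]",
  reductive_amination = "[CX3H1:1]=O.[NX3;H2,H1;!$(N[C,S]=O):2]>>[CX4H2:1][N:2]",
  suzuki_coupling     = "[c:1][Br,Cl,I].[c:2]B(O)O>>[c:1][c:2]"
)

.TEMPLATE_ROLES <- list(
  amide_coupling      = c("carboxylic_acid", "amine"),
  sulfonamide         = c("sulfonyl_chloride", "amine"),
  reductive_amination = c("aldehyde", "amine"),
  suzuki_coupling     = c("aryl_halide", "aryl_boronic_acid")
)

#' The built-in reaction repertoire
#'
#' Four robust two-component couplings ubiquitous in medicinal chemistry:
#' amide coupling, sulfonamide formation, reductive amination, and aryl-aryl
#' (Suzuki-type) coupling.
#'
#' @return list of [ReactionTemplate-class] objects.
#' @export
defaultReactions <- function() {
  lapply(names(.TEMPLATE_SMARTS), function(id)
    new("ReactionTemplate", templateId = id,
        smarts = unname(.TEMPLATE_SMARTS[id]), roles = .TEMPLATE_ROLES[[id]]))
}

## sites for one role on a canonical SMILES (memoized)
.roleSites <- function(smiles, role) {
  key <- paste0(smiles, "|", role)
  v <- .cacheGet("sites", key)
  if (!is.null(v)) return(v)
  g <- .molGraph(smiles)
  v <- if (is.null(g)) list() else .ROLE_FINDERS[[role]](g)
  .cacheSet("sites", key, v)
}

#' Does a structure carry a reactant role's functional group?
#'
#' @param smiles character vector of structures.
#' @param role a role name, e.g. `"amine"`.
#' @return logical vector.
#' @export
matchesRole <- function(smiles, role) {
  vapply(smiles, function(s) length(.roleSites(s, role)) > 0, logical(1),
         USE.NAMES = FALSE)
}

## indices of role-compatible blocks of a library, memoized per library
.roleCompatIdx <- function(library, role) {
  uid <- attr(library, "uid")
  if (is.null(uid)) return(which(matchesRole(blockSmiles(library), role)))
  key <- paste0(uid, "|", role)
  v <- .cacheGet("rolecompat", key)
  if (is.null(v))
    v <- .cacheSet("rolecompat", key, which(matchesRole(blockSmiles(library), role)))
  v
}

#' Apply a reaction template to reactants
#'
#' Enumerates products over all combinations of matching functional-group
#' sites (deduplicated by canonical SMILES). With `protect = TRUE`, atoms
#' outside one designated reactive site per reactant are barred from
#' participating: only the site combination in `sites` (default: the first
#' site of each reactant) reacts.
#'
#' @param template a [ReactionTemplate-class].
#' @param reactants character vector of SMILES, one per reactant role, in
#'   role order.
#' @param protect logical; restrict the transform to one site per reactant.
#' @param sites integer vector (one site index per reactant) used when
#'   `protect = TRUE`.
#' @return character vector of distinct canonical product SMILES (possibly
#'   empty on role mismatch); attribute `"dropped"` counts side products that
#'   failed sanitization.
#' @export
applyTemplate <- function(template, reactants, protect = FALSE, sites = NULL) {
  stopifnot(is(template, "ReactionTemplate"))
  roles <- template@roles
  if (length(reactants) != length(roles))
    stop("expected ", length(roles), " reactants for template ", template@templateId)
  combiner <- .TEMPLATE_COMBINERS[[template@templateId]]
  if (is.null(combiner))
    stop("template ", template@templateId, " is not in the built-in repertoire")
  key <- paste0(template@templateId, "|", paste(reactants, collapse = "."), "|",
                protect, "|", paste(sites, collapse = ","))
  v <- .cacheGet("products", key)
  if (!is.null(v)) return(v)
  siteLists <- lapply(seq_along(roles), function(i) .roleSites(reactants[i], roles[i]))
  if (any(vapply(siteLists, length, integer(1)) == 0)) {
    out <- character(0); attr(out, "dropped") <- 0L
    return(.cacheSet("products", key, out))
  }
  gs <- lapply(reactants, .molGraph)
  if (any(vapply(gs, is.null, logical(1)))) {
    out <- character(0); attr(out, "dropped") <- 0L
    return(.cacheSet("products", key, out))
  }
  if (protect) {
    if (is.null(sites)) sites <- rep(1L, length(roles))
    combos <- matrix(as.integer(sites), nrow = 1)
  } else {
    combos <- as.matrix(expand.grid(lapply(siteLists, seq_along)))
  }
  prods <- character(0); dropped <- 0L
  for (r in seq_len(nrow(combos))) {
    sA <- siteLists[[1]][[combos[r, 1]]]
    sB <- siteLists[[2]][[combos[r, 2]]]
    mg <- combiner(gs[[1]], sA, gs[[2]], sB)
    smi <- if (is.null(mg)) NA_character_ else .graphToSmiles(mg)
    if (is.na(smi)) dropped <- dropped + 1L else prods <- c(prods, smi)
  }
  out <- unique(prods)
  attr(out, "dropped") <- dropped
  .cacheSet("products", key, out)
}

#' Upper bound on the enumerable chemical space
#'
#' Sum over templates of the product over reactant roles of the number of
#' role-compatible blocks; duplicates across templates are not discounted.
#'
#' @param roleCounts either a named integer vector of compatible-block counts
#'   per role, or a [BlockLibrary-class] from which counts are computed.
#' @param templates list of [ReactionTemplate-class].
#' @return numeric count.
#' @export
spaceSizeEstimate <- function(roleCounts, templates) {
  if (is(roleCounts, "BlockLibrary")) {
    smis <- blockSmiles(roleCounts)
    roleCounts <- vapply(names(.ROLE_FINDERS),
                         function(r) sum(matchesRole(smis, r)), numeric(1))
  }
  if (length(templates) == 0) return(0)
  sum(vapply(templates, function(t) prod(roleCounts[t@roles]), numeric(1)))
}
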