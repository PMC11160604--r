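## Result and configuration I/O: campaign summaries as JSON, ledgers as CSV
## (routes serialized as JSON), lineage as edge-list CSV and GraphML, event
## logs as JSON-lines, and campaign configs as YAML.

#' Write campaign results to a directory
#'
#' Emits `summary.json`, `ledger.csv` (one row per compound, route serialized
#' as JSON), `lineage.csv` + `lineage.graphml`, and `events.jsonl`.
#'
#' @param result a [CampaignResult-class].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeCampaignResult <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(
    success = result@success, successKey = result@successKey,
    moleculesMade = result@moleculesMade,
    moleculesScored = result@moleculesScored, cycles = result@cycles,
    monetaryCost = result@monetaryCost, budget = result@config@budget,
    seed = result@config@seed
  ), file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  led <- result@ledger
  led$route <- vapply(result@routes, function(r)
    if (is.null(r)) "" else as.character(jsonlite::toJSON(r, auto_unbox = TRUE)),
    character(1))
  utils::write.csv(led, file.path(dir, "ledger.csv"), row.names = FALSE)
  utils::write.csv(result@lineage, file.path(dir, "lineage.csv"), row.names = FALSE)
  if (nrow(result@lineage) > 0) {
    g <- lineageGraph(result)
    igraph::write_graph(g, file.path(dir, "lineage.graphml"), format = "graphml")
  }
  writeLines(vapply(result@events, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, null = "null")),
    character(1)), file.path(dir, "events.jsonl"))
  invisible(dir)
}

#' Serialize a campaign configuration to YAML
#'
#' The TCP mirrors the profile table columns (units, dynamic range,
#' acceptable, ideal); infinite bounds are spelled `inf`/`-inf`. Oracles are
#' referenced by objective name and must be rebound at load time through the
#' oracle registry.
#'
#' @param config a [CampaignConfig-class].
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
writeCampaignConfig <- function(config, path) {
  num <- function(x) ifelse(is.finite(x), x, ifelse(x > 0, "inf", "-inf"))
  obj <- lapply(config@tcp@objectives, function(o) list(
    name = o@name, units = o@units,
    dynamic_range = as.list(num(o@dynamicRange)),
    acceptable = as.list(num(o@acceptable)),
    ideal = as.list(num(o@ideal))))
  yaml::write_yaml(list(
    tcp = list(objectives = obj,
               weights = as.list(config@tcp@weights),
               success_criterion = config@tcp@successCriterion),
    ideation = list(temperature = num(config@ideation@temperature),
                    n_replace = num(config@ideation@nReplace),
                    analogs_per_parent = config@ideation@analogsPerParent,
                    replace_fraction = config@ideation@replaceFraction,
                    growth_max_heavy_atoms = config@ideation@growthMaxHeavyAtoms),
    policy = list(epsilon = config@policy@epsilon),
    sigmas = as.list(config@sigmas),
    scoring_ratio = config@scoringRatio, batch_size = config@batchSize,
    budget = config@budget, cost_per_compound = config@costPerCompound,
    max_cycles = config@maxCycles, parent_pool = config@parentPool,
    stall_limit = config@stallLimit, use_model = config@useModel,
    frozen_noise = config@frozenNoise, seed = config@seed
  ), path)
  invisible(path)
}

#' Read a campaign configuration from YAML
#'
#' @param path YAML file written by [writeCampaignConfig()] (or hand-written
#'   in the same schema).
#' @param oracles named list of ground-truth [Oracle-class] objects, keyed by
#'   objective name (the oracle registry).
#' @return a [CampaignConfig-class].
#' @export
readCampaignConfig <- function(path, oracles) {
  y <- yaml::read_yaml(path)
  num <- function(x) {
    x <- unlist(x)
    v <- suppressWarnings(as.numeric(x))
    v[x == "inf"] <- Inf; v[x == "-inf"] <- -Inf
    v
  }
  objs <- lapply(y$tcp$objectives, function(o)
    objectiveSpec(o$name, o$units, num(o$acceptable), num(o$ideal),
                  num(o$dynamic_range)))
  theTcp <- tcp(objs, weights = num(y$tcp$weights),
                successCriterion = y$tcp$success_criterion %||% "acceptable")
  campaignConfig(
    tcp = theTcp, oracles = oracles,
    sigmas = stats::setNames(num(y$sigmas), names(y$sigmas)),
    ideation = ideationConfig(
      temperature = num(y$ideation$temperature),
      nReplace = num(y$ideation$n_replace),
      analogsPerParent = y$ideation$analogs_per_parent %||% 8,
      replaceFraction = y$ideation$replace_fraction %||% 0.5,
      growthMaxHeavyAtoms = y$ideation$growth_max_heavy_atoms %||% 10),
    policy = selectionPolicy(epsilon = y$policy$epsilon %||% 0.1),
    scoringRatio = y$scoring_ratio %||% 5, batchSize = y$batch_size %||% 8,
    budget = y$budget %||% 120, costPerCompound = y$cost_per_compound %||% 3000,
    maxCycles = y$max_cycles %||% 200, parentPool = y$parent_pool %||% 5,
    stallLimit = y$stall_limit %||% 3, useModel = y$use_model %||% TRUE,
    frozenNoise = y$frozen_noise %||% FALSE, seed = y$seed %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read starting hits from a SMILES file
#'
#' One SMILES per line, optional whitespace-separated name; `#` comments.
#'
#' @param path `.smi` file.
#' @return character vector of SMILES.
#' @export
readHitsFile <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "[ \t]+"), `[[`, character(1), 1)
}
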