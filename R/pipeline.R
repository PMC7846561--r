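# Orchestration: generate -> metrics -> cluster -> stats -> simulate
# from one config, with reproducible seeds, a manifest, cached stage
# outputs keyed by config hash, and tabular reports.

.stageHash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

.readStageHash <- function(dir) {
  f <- file.path(dir, "stage_hash")
  if (file.exists(f)) readLines(f, n = 1L) else NA_character_
}

#' Run the analysis pipeline
#'
#' Executes the requested stages from a single configuration:
#' \describe{
#'   \item{generate}{synthesize a dataset from a preset (or read an
#'     annotation JSON given as `config$input`).}
#'   \item{metrics}{flat feature table, 2D normalized distances and
#'     pooled summaries.}
#'   \item{cluster}{per-synapse cluster analysis cohort and SSD-vs-size
#'     regression.}
#'   \item{stats}{Wilcoxon tests of the normalized distances against the
#'     theoretical median 0.5.}
#'   \item{simulate}{the receptor-activation scenario grid.}
#' }
#' Outputs are CSV/JSON under `outDir`; a manifest records the config,
#' its hash, and the master seed. Stages whose config hash matches a
#' previous run are skipped (cached).
#'
#' @param config named list, or path to a YAML/JSON file with the same
#'   structure. Recognized fields: `stages` (character vector), `preset`
#'   and `nSynapses` (generate), `input` (annotation JSON path instead
#'   of generation), `bootstrap` (B for pooled CIs), `grid` (list of
#'   arguments for [scenarioGrid()]).
#' @param outDir output directory (created if needed).
#' @param seed master seed; per-stage seeds are split from it.
#' @return `outDir`, invisibly; side effect: files under `outDir`.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("syngold_run_"),
                        seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("[.]ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  stages <- config$stages %||% c("generate", "metrics", "cluster",
                                 "stats", "simulate")
  known <- c("generate", "metrics", "cluster", "stats", "simulate")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- splitSeed(seed, length(known))
  names(seeds) <- known

  needsData <- any(c("metrics", "cluster", "stats") %in% stages)
  if (needsData && !"generate" %in% stages && is.null(config$input))
    stop("stage 'metrics'/'cluster'/'stats' needs inputs: add stage ",
         "'generate' or supply config$input")

  manifest <- list(config = config, seed = seed,
                   configHash = .stageHash(c(config, seed = seed)),
                   stages = stages)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)

  gen <- NULL
  dataPath <- file.path(outDir, "annotations.json")
  if ("generate" %in% stages) {
    h <- .stageHash(list(config$preset, config$nSynapses, seeds[["generate"]]))
    if (!identical(.readStageHash(file.path(outDir, "generate")), h)) {
      cfg <- presetConfig(config$preset %||% "AMPA_like",
                          nSynapses = config$nSynapses %||% 50L,
                          seed = seeds[["generate"]])
      gen <- generateDataset(cfg)
      writeAnnotations(gen$dataset, dataPath)
      dir.create(file.path(outDir, "generate"), showWarnings = FALSE)
      writeLines(h, file.path(outDir, "generate", "stage_hash"))
    }
  } else if (!is.null(config$input)) {
    if (!file.exists(config$input))
      stop("stage inputs missing: config$input not found (generate)")
    file.copy(config$input, dataPath, overwrite = TRUE)
  }
  ds <- if (needsData) readAnnotations(dataPath) else NULL

  if ("metrics" %in% stages) {
    writeFeatureCSV(ds, file.path(outDir, "features.csv"))
    d2 <- do.call(rbind, lapply(profiles(ds), function(p) {
      if (!nrow(gold(p))) return(NULL)
      cbind(normalizedDistance2D(gold(p), psdTrace(p)),
            label = p@label, condition = p@condition)
    }))
    if (!is.null(d2)) {
      pool <- poolDistributions(d2, group = d2$label,
                                B = config$bootstrap %||% 2000L,
                                seed = seeds[["metrics"]])
      utils::write.csv(pool$summary,
                       file.path(outDir, "distance_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(pool$ecdf, file.path(outDir, "distance_ecdf.csv"),
                       row.names = FALSE)
      utils::write.csv(d2, file.path(outDir, "distances_2d.csv"),
                       row.names = FALSE)
    }
  }

  if ("cluster" %in% stages) {
    recs <- reconstructSynapses(ds)
    ng <- vapply(recs, function(s)
      sum(vapply(profiles(s), function(p) nrow(gold(p)), integer(1))),
      integer(1))
    if (!any(ng > 0L))
      stop("stage 'cluster' needs gold particles but the dataset has none")
    cseeds <- splitSeed(seeds[["cluster"]], length(recs))
    results <- lapply(seq_along(recs), function(i)
      clusterAnalysis(recs[[i]], nMaps = config$nullMaps %||% 50L,
                      seed = cseeds[i]))
    areas <- vapply(recs, function(s) synapseGeometry3D(s)$areaUm2,
                    numeric(1))
    cohort <- clusterCohort(results, areas = as.list(areas))
    utils::write.csv(cohort, file.path(outDir, "cluster_cohort.csv"),
                     row.names = FALSE)
    if (sum(cohort$n > 0L) >= 3L && stats::var(cohort$area_um2) > 0)
      utils::write.csv(regressSsdVsSize(cohort),
                       file.path(outDir, "cluster_regression.csv"),
                       row.names = FALSE)
  }

  if ("stats" %in% stages) {
    d2 <- do.call(rbind, lapply(profiles(ds), function(p) {
      if (!nrow(gold(p))) return(NULL)
      cbind(normalizedDistance2D(gold(p), psdTrace(p)), label = p@label)
    }))
    if (!is.null(d2)) {
      tests <- lapply(split(d2$normalized, d2$label), wilcoxonOneSample)
      names(tests) <- paste0(names(tests), " vs 0.5")
      utils::write.csv(testBatteryTable(tests),
                       file.path(outDir, "stats_tests.csv"),
                       row.names = FALSE)
    }
  }

  if ("simulate" %in% stages) {
    gridArgs <- config$grid %||% list()
    gridArgs$seed <- seeds[["simulate"]]
    tab <- do.call(scenarioGrid, gridArgs)
    utils::write.csv(tab, file.path(outDir, "scenario_grid.csv"),
                     row.names = FALSE)
  }

  invisible(outDir)
}

#' Tabular report of a pipeline run
#'
#' Collects the figure-style summary tables from a completed run:
#' ECDF tables, median/CI tables, the cluster-count table, and the
#' scenario AUC table (omitted when the corresponding stage did not
#' run). No prose, just tables.
#'
#' @param runDir a directory produced by [runPipeline()].
#' @return named list of data.frames (subset of `distance_summary`,
#'   `distance_ecdf`, `cluster_counts`, `cluster_regression`,
#'   `scenario_auc`, `stats_tests`).
#' @export
makeReport <- function(runDir) {
  if (!file.exists(file.path(runDir, "manifest.json")))
    stop("not a pipeline run directory: ", runDir)
  rd <- function(f) {
    p <- file.path(runDir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE)
    else NULL
  }
  out <- list()
  out$distance_summary <- rd("distance_summary.csv")
  out$distance_ecdf <- rd("distance_ecdf.csv")
  cohort <- rd("cluster_cohort.csv")
  if (!is.null(cohort)) {
    cc <- as.data.frame(table(k_opt = cohort$k_opt[cohort$n > 0L]),
                        stringsAsFactors = FALSE)
    names(cc) <- c("k_opt", "n_synapses")
    out$cluster_counts <- cc
    out$cluster_cohort <- cohort
  }
  out$cluster_regression <- rd("cluster_regression.csv")
  out$stats_tests <- rd("stats_tests.csv")
  grid <- rd("scenario_grid.csv")
  if (!is.null(grid))
    out$scenario_auc <- grid[, c("pattern", "delay_ms", "voltage_mode",
                                 "kind", "auc")]
  out[!vapply(out, is.null, logical(1))]
}
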