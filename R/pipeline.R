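## Single-call orchestration of the full design-build-test workflow.

pipelineStages <- c("rank", "enumerate", "select", "plan",
                    "measure", "fit", "predict")

readPipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stopWithClass("validationError", "config file not found: ", config)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stopWithClass("validationError", "config must be a list or a YAML/JSON path")
  }
  required <- c("parts", "n_runs", "seeds", "output_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stopWithClass("validationError", "config lacks field(s): ",
                  paste(missing, collapse = ", "))
  }
  if (!all(c("design", "simulation") %in% names(config$seeds))) {
    stopWithClass("validationError", "config$seeds must name design and simulation seeds")
  }
  if (!file.exists(config$parts)) {
    stopWithClass("validationError", "parts file not found: ", config$parts)
  }
  config$n_starts <- config$n_starts %||% 10L
  config$replicates <- config$replicates %||% 3L
  config$top_k <- config$top_k %||% 5L
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopWithClass("stageError", "stage '", stage, "' failed: ",
                  conditionMessage(e))
  })
}

#' Run the design-build-test pipeline
#'
#' Executes the workflow stages in order: rank parts, enumerate the design
#' space, select the D-optimal run subset, plan the assembly picklist, then
#' (beyond `mode = "design"`) obtain titres -- simulated
#' (`mode = "simulate"` / `"all"`) or quantified from a measurements file
#' (`mode = "analyse"`, requiring `config$measurements` and
#' `config$standards`) -- fit the effect model and predict the optimum.
#' Every artifact is written under `config$output_dir` and listed, with its
#' MD5 checksum, in `manifest.json`; identical configuration and seeds give
#' identical checksums.
#'
#' @param config configuration list or YAML path; see [lycopeneConfig()] for
#'   the fields.
#' @param mode `"all"`, `"design"`, `"simulate"` or `"analyse"`.
#' @return the manifest, invisibly: a list with the written artifacts,
#'   checksums, seeds and key summary numbers.
#' @export
runPipeline <- function(config, mode = c("all", "design", "simulate", "analyse")) {
  mode <- match.arg(mode)
  config <- readPipelineConfig(config)
  outDir <- config$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  summary <- list()
  emit <- function(name) artifacts <<- c(artifacts, name)

  ## rank
  lib <- runStage("rank", {
    lib <- loadParts(config$parts)
    lib <- rankParts(lib, "promoter")
    lib <- rankParts(lib, "rbs")
    exportDoeTable(lib, file.path(outDir, "ranked_parts.csv"))
    emit("ranked_parts.csv")
    lib
  })

  ## enumerate
  spaceConfigs <- runStage("enumerate", {
    space <- buildDesignSpace(lib, genes = config$genes,
                              geneCodes = config$gene_codes,
                              rbsLinkerMap = config$rbs_linker_map)
    configs <- enumerateConfigurations(space)
    utils::write.csv(configs, file.path(outDir, "design_space.csv"),
                     row.names = FALSE)
    emit("design_space.csv")
    list(space = space, configs = configs)
  })
  space <- spaceConfigs$space
  summary$n_configurations <- nrow(spaceConfigs$configs)

  ## select
  design <- runStage("select", {
    model <- modelSpec(space)
    des <- selectDOptimal(space, model, nRuns = config$n_runs,
                          seed = config$seeds$design,
                          nStarts = config$n_starts)
    des
  })
  summary$d_efficiency <- design@dEfficiency

  ## plan
  planned <- runStage("plan", {
    constructs <- configurationToConstruct(space, designRuns(design))
    constructs <- assignStitchIds(constructs)
    design@runs$stitch_id <- constructs$stitch_id[
      match(design@runs$config_index, constructs$config_index)]
    utils::write.csv(designTable(design, space),
                     file.path(outDir, "design.csv"), row.names = FALSE)
    emit("design.csv")
    jsonlite::write_json(
      list(criterion = "D", seed = design@seed, n_starts = design@nStarts,
           n_runs = design@nRuns, candidate_count = design@candidateCount,
           log_det = design@logDet, d_efficiency = design@dEfficiency),
      file.path(outDir, "design_meta.json"), auto_unbox = TRUE, digits = NA)
    emit("design_meta.json")
    utils::write.csv(constructs, file.path(outDir, "constructs.csv"),
                     row.names = FALSE)
    emit("constructs.csv")
    if (!is.null(config$layout)) {
      layout <- readPlateLayout(config$layout)
      pk <- planAssembly(constructs, layout)
      writePicklist(pk, file.path(outDir, "picklist.csv"))
      emit("picklist.csv")
    }
    constructs
  })

  titres <- NULL
  if (mode != "design") {
    titres <- runStage("measure", {
      if (mode == "analyse") {
        if (is.null(config$measurements) || is.null(config$standards)) {
          stopWithClass("validationError",
                        "analyse mode needs config$measurements and config$standards")
        }
        std <- utils::read.csv(config$standards, stringsAsFactors = FALSE)
        curve <- fitStandardCurve(std$concentration_mg_per_ml, std$peak_area)
        meas <- utils::read.csv(config$measurements, stringsAsFactors = FALSE)
        tt <- peakAreaToTitre(meas, curve)
      } else {
        truth <- defaultGroundTruth(space)
        tt <- simulateTitres(space, designRuns(design), truth,
                             replicates = config$replicates,
                             seed = config$seeds$simulation)
      }
      utils::write.csv(tt, file.path(outDir, "titres.csv"), row.names = FALSE)
      emit("titres.csv")
      tt
    })
    screen <- summariseScreen(titres)
    summary$producers <- unname(screen$producers)
    summary$failure_pct <- unname(screen$failure_pct)

    fit <- runStage("fit", {
      f <- fitEffects(designRuns(design), titres, space, modelSpec(space))
      eff <- effectSummary(f)
      utils::write.csv(eff, file.path(outDir, "effect_summary.csv"),
                       row.names = FALSE)
      emit("effect_summary.csv")
      f
    })

    runStage("predict", {
      preds <- predictOptimum(fit, space, topK = config$top_k)
      utils::write.csv(preds, file.path(outDir, "predictions.csv"),
                       row.names = FALSE)
      emit("predictions.csv")
    })
  }

  paths <- file.path(outDir, artifacts)
  manifest <- list(
    package = "operonDesign",
    mode = mode,
    seeds = config$seeds,
    stages = if (mode == "design") pipelineStages[1:4] else pipelineStages,
    summary = summary,
    artifacts = data.frame(name = artifacts, path = paths,
                           md5 = unname(tools::md5sum(paths)),
                           stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
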