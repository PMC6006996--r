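## End-to-end orchestration: (optional) reduction -> parse -> search ->
## balance -> build -> simulate -> (optional) robustness, with artifact
## persistence and a manifest.

#' Pipeline configuration
#'
#' @param modelPath path to the input SBML network
#' @param databaseDir fixture database root (NULL to skip the search)
#' @param outDir output directory for artifacts
#' @param wanted quantity types for the search
#' @param config a [balancingConfig()]
#' @param reduce reduction mode: \code{"none"}, \code{"prune"} or
#'   \code{"compress"} (compress implies prune first)
#' @param protectedReactions,protectedMetabolites protection sets for
#'   reduction
#' @param tEnd,gridSize simulation schedule parameters
#' @param pulse optional pulse as \code{"<metabolite>:<time>:<factor>"}
#' @param robustness optional list with \code{fractions}, \code{widths},
#'   \code{repetitions}, \code{maxSamples}
#' @param seed master seed
#' @return config list
#' @export
pipelineConfig <- function(modelPath, databaseDir = NULL,
                           outDir = "dynamet-out",
                           wanted = c("kM", "kcat_forward", "keq"),
                           config = balancingConfig(),
                           reduce = c("none", "prune", "compress"),
                           protectedReactions = character(),
                           protectedMetabolites = character(),
                           tEnd = 400, gridSize = 401, pulse = NULL,
                           robustness = NULL, seed = 1L) {
  reduce <- match.arg(reduce)
  list(modelPath = modelPath, databaseDir = databaseDir, outDir = outDir,
       wanted = wanted, config = config, reduce = reduce,
       protectedReactions = protectedReactions,
       protectedMetabolites = protectedMetabolites, tEnd = tEnd,
       gridSize = gridSize, pulse = pulse, robustness = robustness,
       seed = as.integer(seed))
}

.parsePulse <- function(pulse, tEnd, gridSize) {
  if (is.null(pulse)) return(simulationSchedule(tEnd, gridSize))
  parts <- strsplit(pulse, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 3L)
    stop("pulse must be <metabolite>:<time>:<factor>")
  simulationSchedule(tEnd, gridSize, pulses = data.frame(
    time = as.numeric(parts[2L]), metabolite = parts[1L],
    action = "multiply", amount = as.numeric(parts[3L]),
    stringsAsFactors = FALSE))
}

.stageLog <- function(logCon, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(logCon)) writeLines(line, logCon)
}

#' Run the full pipeline
#'
#' Executes, in order: optional flux-based reduction, SBML parsing,
#' exhaustive parameter search over the registered fixture databases,
#' parameter balancing, kinetic-model construction, simulation, and the
#' optional robustness sweep. Every artifact (balancing table, balanced
#' parameters, kinetic SBML, trajectory CSV, score table) is written to
#' the output directory together with a manifest naming the seed, the
#' config hash and each artifact's md5. A stage failure aborts with the
#' stage name; artifacts written so far remain, listed in a partial
#' manifest.
#'
#' @param cfg a [pipelineConfig()]
#' @return the manifest (list), invisibly
#' @export
runPipeline <- function(cfg) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logCon <- file(file.path(cfg$outDir, "pipeline.log"), "w")
  on.exit(close(logCon))
  artifacts <- list()
  manifest <- list(seed = cfg$seed, stages = character(),
                   artifacts = list())
  cfgCopy <- cfg; cfgCopy$config <- cfg$config[c("R", "T", "defaultLogSd")]
  tf <- tempfile(); saveRDS(cfgCopy, tf)
  manifest$configHash <- unname(tools::md5sum(tf)); unlink(tf)
  finish <- function(stage, e) {
    manifest$failedStage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest,
      file.path(cfg$outDir, "manifest.json"), auto_unbox = TRUE,
      digits = NA)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  addArtifact <- function(name, path) {
    manifest$artifacts[[name]] <<- list(path = basename(path),
      md5 = unname(tools::md5sum(path)))
  }
  stage <- function(name, expr) {
    .stageLog(logCon, name, "start")
    r <- tryCatch(expr, error = function(e) finish(name, e))
    manifest$stages <<- c(manifest$stages, name)
    .stageLog(logCon, name, "done")
    r
  }

  network <- stage("parse", readSBML(cfg$modelPath))
  if (cfg$reduce != "none") {
    network <- stage("reduce", {
      spec <- reductionSpec(objective = objectiveReaction(network),
        protectedReactions = cfg$protectedReactions,
        protectedMetabolites = cfg$protectedMetabolites)
      red <- pruneNetwork(network, spec)
      writeReductionLog(red$log, file.path(cfg$outDir, "pruning_log.tsv"))
      addArtifact("pruning_log", file.path(cfg$outDir, "pruning_log.tsv"))
      net <- red$network
      if (cfg$reduce == "compress") {
        comp <- compressNetwork(net, spec)
        writeReductionLog(comp$log,
                          file.path(cfg$outDir, "compression_log.tsv"))
        addArtifact("compression_log",
                    file.path(cfg$outDir, "compression_log.tsv"))
        net <- comp$network
      }
      net
    })
  }
  records <- stage("search", {
    if (is.null(cfg$databaseDir)) {
      .bindRecords(list())
    } else {
      reg <- fixtureRegistry(cfg$databaseDir)
      executeSearch(network, reg, wanted = cfg$wanted,
                    defaultLogSd = cfg$config$defaultLogSd)
    }
  })
  p <- file.path(cfg$outDir, "balancing_table.tsv")
  writeBalancingTable(records, p); addArtifact("balancing_table", p)

  bal <- stage("balance", balanceNetwork(network, records, cfg$config))
  p <- file.path(cfg$outDir, "balanced_parameters.tsv")
  writeBalancedParameters(bal$balanced, p)
  addArtifact("balanced_parameters", p)

  model <- stage("build", assembleOdeSystem(network, bal$balanced))
  p <- file.path(cfg$outDir, "kinetic_model.xml")
  writeSBML(network, p, kinetics = model@params)
  addArtifact("kinetic_model", p)

  traj <- stage("simulate", {
    schedule <- .parsePulse(cfg$pulse, cfg$tEnd, cfg$gridSize)
    simulateModel(model, schedule,
                  initial = balancedConcentrations(bal$balanced))
  })
  p <- file.path(cfg$outDir, "trajectory.csv")
  writeTrajectory(traj, p); addArtifact("trajectory", p)

  if (!is.null(cfg$robustness)) {
    scores <- stage("robustness", {
      rb <- cfg$robustness
      gold <- makeGoldStandard(network, seed = cfg$seed,
                               config = cfg$config)
      sweepRobustness(gold, fractions = rb$fractions,
        widths = if (is.null(rb$widths)) 1 else rb$widths,
        repetitions = if (is.null(rb$repetitions)) 20L else rb$repetitions,
        seed = cfg$seed,
        maxSamples = if (is.null(rb$maxSamples)) 10000L else rb$maxSamples)
    })
    p <- file.path(cfg$outDir, "scores.tsv")
    writeScoreTable(scores, p); addArtifact("scores", p)
  }
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
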