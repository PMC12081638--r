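## Pipeline runner: a single entry point that executes analysis stages in
## dependency order with a shared, validated configuration and writes a
## deterministic run manifest (inputs hashed, parameters, versions, seed).
## A thin command-line wrapper lives in inst/scripts/pipeline.R; the exported
## functions here are the interface.

pipelineStages <- c("synth-plate", "synergy", "synth-image", "colonies",
                    "synth-flow", "flow", "synth-counts", "dge", "enrich",
                    "graph")

#' Build a run configuration
#'
#' Collects the seed, stage list, output directory and the module parameter
#' blocks (synergy thresholds \{2, 5\}, observed-viability floor 1e-4, FDR
#' level 0.01, sub-G1 gate factor 0.8, colony-detection parameters) into a
#' validated list. Configurations can also be read from JSON with
#' [readRunConfig()].
#'
#' @param seed integer seed used for every stochastic stage.
#' @param outDir output directory (created if needed at run time).
#' @param stages character vector of stages to run, a subset of:
#'   `r paste(pipelineStages, collapse = ", ")`.
#' @param inputs named list of input paths for stages that read files
#'   (e.g. `plate`, `image`, `events`, `counts`); stages that follow a
#'   `synth-*` stage in the same run use its outputs automatically.
#' @param fdr FDR level for the transcriptomic stages.
#' @param synergyThresholds per-experiment category boundaries
#'   (lower, upper).
#' @param floor observed-viability floor for synergy scores.
#' @param gateFactor sub-G1 gate position as a fraction of the 2N mode.
#' @param colony parameter list from [colonyParams()].
#' @param pixelSize micrometres per pixel for the colony stage.
#' @return A validated configuration list of class `"RunConfig"`.
#' @export
runConfig <- function(seed = 1L, outDir = tempfile("run"),
                      stages = c("synth-plate", "synergy"),
                      inputs = list(), fdr = 0.01,
                      synergyThresholds = c(2, 5), floor = 1e-4,
                      gateFactor = 0.8, colony = colonyParams(),
                      pixelSize = 5) {
  cfg <- structure(list(seed = as.integer(seed), outDir = outDir,
                        stages = stages, inputs = inputs, fdr = fdr,
                        synergyThresholds = synergyThresholds, floor = floor,
                        gateFactor = gateFactor, colony = colony,
                        pixelSize = pixelSize),
                   class = "RunConfig")
  validateRunConfig(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param config a `"RunConfig"` list (from [runConfig()] or
#'   [readRunConfig()]).
#' @return `config`, invisibly, or an error naming the offending field.
#' @export
validateRunConfig <- function(config) {
  bad <- setdiff(config$stages, pipelineStages)
  if (length(bad))
    fail("unknown stage(s) %s; valid stages are: %s",
         paste(bad, collapse = ", "), paste(pipelineStages, collapse = ", "))
  if (!is.numeric(config$fdr) || config$fdr <= 0 || config$fdr >= 1)
    fail("'fdr' must lie in (0, 1)")
  th <- config$synergyThresholds
  if (length(th) != 2 || !(th[1] < th[2]))
    fail("'synergyThresholds' must be two ordered values (lower < upper)")
  if (!is.numeric(config$floor) || config$floor <= 0)
    fail("'floor' must be > 0")
  if (config$gateFactor <= 0 || config$gateFactor >= 1)
    fail("'gateFactor' must lie in (0, 1)")
  for (p in unlist(config$inputs))
    if (!file.exists(p)) fail("input file does not exist: %s", p)
  invisible(config)
}

#' @rdname runConfig
#' @param path JSON file holding the configuration fields.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) fail("config file does not exist: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw), names(formals(runConfig)))]
  if (!is.null(args$colony)) args$colony <- do.call(colonyParams, args$colony)
  do.call(runConfig, args)
}

#' Run pipeline stages and write a manifest
#'
#' Executes the requested stages in dependency order, writing all results
#' under `config$outDir`, then writes `manifest.json` recording the package
#' and R versions, the seed, the full configuration, and an MD5 checksum of
#' every input and output file -- enough to re-execute the run exactly.
#' Seeded runs are bit-reproducible: the same configuration yields
#' byte-identical result files.
#'
#' @param config a validated `"RunConfig"`.
#' @return Invisibly, the manifest list.
#' @examples
#' cfg <- runConfig(seed = 42L, stages = c("synth-plate", "synergy"))
#' m <- runPipeline(cfg)
#' names(m$outputs)
#' @export
runPipeline <- function(config) {
  validateRunConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$outDir, name)
  written <- character()
  note <- function(p) written <<- union(written, p)
  artifacts <- list()

  for (stage in config$stages) {
    switch(stage,
      "synth-plate" = {
        plate <- simulatePlate(plateSimSpec(seed = config$seed))
        note(writePlateCsv(plate, out("plate.csv")))
        artifacts$plate <- out("plate.csv")
      },
      "synergy" = {
        path <- artifacts$plate %||% config$inputs$plate
        if (is.null(path)) fail("stage 'synergy' needs a plate input")
        vt <- normalizeViability(readPlate(path))
        res <- combinationSynergy(vt, floor = config$floor)
        utils::write.table(synergyTable(res), out("synergy.csv"),
                           sep = ",", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(lapply(res, function(r) list(
          combination = r@combination, score = r@score,
          range = r@scoreRange, label = r@label,
          per_experiment = as.list(r@perExperimentScores))),
          out("synergy.json"), digits = 12, auto_unbox = TRUE)
        note(out("synergy.csv")); note(out("synergy.json"))
      },
      "synth-image" = {
        sim <- simulateColonyImage(randomColonySpec(
          nColonies = 8, seed = config$seed, pixelSize = config$pixelSize))
        note(writePgm(sim$image, out("well.pgm")))
        write.csv(sim$truth, out("well_truth.csv"), row.names = FALSE)
        note(out("well_truth.csv"))
        artifacts$image <- out("well.pgm")
      },
      "colonies" = {
        path <- artifacts$image %||% config$inputs$image
        if (is.null(path)) fail("stage 'colonies' needs an image input")
        det <- detectColonies(readPgm(path), pixelSize = config$pixelSize,
                              params = config$colony)
        write.csv(colonyFeatures(det), out("colonies.csv"),
                  row.names = FALSE)
        jsonlite::write_json(list(count = colonyCount(det)),
                             out("colony_count.json"), auto_unbox = TRUE)
        note(out("colonies.csv")); note(out("colony_count.json"))
      },
      "synth-flow" = {
        ev <- simulateDnaContent(dnaContentSpec(seed = config$seed))
        note(writeEventsCsv(ev, out("events.csv")))
        artifacts$events <- out("events.csv")
      },
      "flow" = {
        path <- artifacts$events %||% config$inputs$events
        if (is.null(path)) fail("stage 'flow' needs an events input")
        ev <- read.csv(path)$intensity
        s <- analyzeDnaContent(ev, gateFactor = config$gateFactor)
        jsonlite::write_json(list(g1_mode = s@g1Mode, g2m_mode = s@g2mMode,
                                  subg1_fraction = s@subg1Fraction),
                             out("flow.json"), digits = 12,
                             auto_unbox = TRUE)
        note(out("flow.json"))
      },
      "synth-counts" = {
        sets <- list(list(id = "PLANTED_UP",
                          genes = geneIdsFor(1000)[1:50], log2Effect = 2))
        se <- simulateCounts(countsSimSpec(plantedSets = sets,
                                           seed = config$seed))
        note(writeCountsTsv(se, out("counts.tsv"), out("samples.csv")))
        note(out("samples.csv"))
        note(writeGmt(S4Vectors::metadata(se)$geneSets, out("sets.gmt")))
        artifacts$se <- se
      },
      "dge" = {
        se <- artifacts$se %||% fail("stage 'dge' needs 'synth-counts'")
        de <- differentialExpression(se, fdr = config$fdr)
        utils::write.table(de, out("de.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        note(out("de.tsv"))
        artifacts$de <- de
      },
      "enrich" = {
        se <- artifacts$se %||% fail("stage 'enrich' needs 'synth-counts'")
        sc <- enrichmentScores(se, S4Vectors::metadata(se)$geneSets)
        dgs <- differentialGeneSets(sc,
          SummarizedExperiment::colData(se)$group, fdr = config$fdr)
        utils::write.table(dgs, out("genesets.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        note(out("genesets.tsv"))
        artifacts$dgs <- dgs
        artifacts$sets <- S4Vectors::metadata(se)$geneSets
      },
      "graph" = {
        dgs <- artifacts$dgs %||% fail("stage 'graph' needs 'enrich'")
        sig <- dgs[dgs$significant, , drop = FALSE]
        if (nrow(sig)) {
          g <- buildGeneSetGraph(sig, artifacts$sets)
          note(writeGeneSetGraph(g, out("graph.graphml")))
        }
      })
  }

  inputFiles <- as.character(unlist(config$inputs, use.names = FALSE))
  inputSums <- if (length(inputFiles))
    as.list(setNames(unname(tools::md5sum(inputFiles)), inputFiles))
  else list()
  manifest <- list(
    package = as.character(packageVersion("OrganoidScreen")),
    rVersion = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, stages = config$stages,
    parameters = config[c("fdr", "synergyThresholds", "floor", "gateFactor",
                          "pixelSize")],
    inputs = inputSums,
    outputs = as.list(setNames(unname(tools::md5sum(written)), written)))
  jsonlite::write_json(manifest, out("manifest.json"), digits = 12,
                       auto_unbox = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
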