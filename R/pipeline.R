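#' @include AllClasses.R
NULL

.resolveSelection <- function(structure, spec, name = "selection") {
  if (is.numeric(spec)) return(as.integer(spec))
  do.call(selectAtoms, c(list(structure = structure), spec))
}

.loadConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

#' Validate a pipeline configuration
#'
#' Checks that input paths exist, that every named selection resolves to
#' at least one atom on the input structure, and that the parameter table
#' covers all atoms. Diagnostics are the output: nothing is thrown.
#'
#' @param config a configuration list or path to a YAML file (see
#'   [runPipeline()] for the schema).
#' @return data.frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows for a clean configuration. Attribute `ok` is
#'   FALSE when any error-level finding is present.
#' @export
validateConfig <- function(config) {
  config <- .loadConfig(config)
  diags <- list()
  note <- function(level, msg)
    diags[[length(diags) + 1L]] <<- data.frame(level = level, message = msg)
  inp <- config$input
  structure <- NULL
  for (field in c("structure", "trajectory", "parameters", "bonds")) {
    v <- inp[[field]]
    if (is.character(v) && !file.exists(v))
      note("error", paste0("input ", field, ": file not found: ", v))
  }
  if (!is.null(inp$structure)) {
    structure <- tryCatch({
      if (is.character(inp$structure)) readStructure(inp$structure)
      else inp$structure
    }, error = function(e) {
      note("error", paste("structure unreadable:", conditionMessage(e)))
      NULL
    })
  } else note("error", "no input structure given")
  if (!is.null(structure)) {
    for (nm in names(config$selections)) {
      sel <- withCallingHandlers(
        tryCatch(.resolveSelection(structure, config$selections[[nm]]),
                 error = function(e) {
                   note("error", paste0("selection '", nm, "': ",
                                        conditionMessage(e)))
                   integer(0)
                 }),
        warning = function(w) {
          note("warning", paste0("selection '", nm, "': ",
                                 conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      if (!length(sel))
        note("warning", paste0("selection '", nm, "' matches no atoms"))
    }
    if (!is.null(inp$parameters)) {
      tryCatch({
        tab <- if (is.character(inp$parameters)) readParameterTable(inp$parameters)
               else inp$parameters
        bonds <- if (is.character(inp$bonds)) readBondList(inp$bonds)
                 else inp$bonds
        loadParameters(structure, tab, bonds)
      }, error = function(e)
        note("error", paste("parameter assignment:", conditionMessage(e))))
    }
  }
  out <- if (length(diags)) do.call(rbind, diags)
         else data.frame(level = character(0), message = character(0))
  attr(out, "ok") <- !any(out$level == "error")
  out
}

.stageEnabled <- function(stage) isTRUE(stage$enabled) || isTRUE(stage)

#' Run the analysis pipeline from a single configuration
#'
#' Executes the requested stages in dependency order (io, then
#' energetics / gbsa / fluctuations / pca / cavity / comparative), writes
#' a manifest (input hashes, package version, seed, stage parameters) and
#' a JSON summary aggregating top interaction pairs, region block sums
#' and asymmetry, the MM-GBSA component table, RMSF/B profiles, the PCA
#' eigen-spectrum, cavity volumes and occupancy, and superposition RMSDs.
#' A failing stage is recorded in the manifest and independent stages
#' continue.
#'
#' Configuration schema (list or YAML): `input` (`structure`,
#' `trajectory`, `parameters`, `bonds` - paths or in-memory objects),
#' `selections` (named lists of [selectAtoms()] arguments or explicit
#' index vectors), `stages` (per-stage lists with `enabled` plus stage
#' parameters naming selections by their keys), `seed` (master seed).
#'
#' @param config configuration list or YAML path.
#' @param outDir output directory (created); NULL to skip writing.
#' @return invisibly, the summary list (also written as
#'   `summary.json` beside `manifest.json` when `outDir` is given).
#' @export
runPipeline <- function(config, outDir = NULL) {
  config <- .loadConfig(config)
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(package = "ChaperoneDynamics",
                   version = as.character(utils::packageVersion("ChaperoneDynamics")),
                   date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = seed, inputs = list(), stages = list(),
                   errors = list())
  summary <- list()
  inp <- config$input
  hashOrClass <- function(v)
    if (is.character(v)) list(path = v, md5 = unname(tools::md5sum(v)))
    else list(class = class(v)[1])
  for (f in names(inp)) manifest$inputs[[f]] <- hashOrClass(inp[[f]])

  structure <- if (is.character(inp$structure)) readStructure(inp$structure)
               else inp$structure
  system <- NULL
  if (!is.null(inp$parameters)) {
    tab <- if (is.character(inp$parameters)) readParameterTable(inp$parameters)
           else inp$parameters
    bonds <- if (is.character(inp$bonds)) readBondList(inp$bonds)
             else inp$bonds
    system <- loadParameters(structure, tab, bonds)
  }
  trajectory <- if (is.null(inp$trajectory)) NULL
    else if (is.character(inp$trajectory))
      readTrajectory(inp$trajectory, template = structure)
    else inp$trajectory

  sels <- lapply(config$selections, .resolveSelection, structure = structure)
  getSel <- function(key) {
    if (is.null(key)) return(NULL)
    if (is.numeric(key)) return(as.integer(key))
    if (!key %in% names(sels)) stop("unknown selection '", key, "'")
    sels[[key]]
  }
  stg <- config$stages
  runStage <- function(name, fun) {
    spec <- stg[[name]]
    if (is.null(spec) || !.stageEnabled(spec)) return()
    manifest$stages[[name]] <<- spec[setdiff(names(spec), "enabled")]
    res <- tryCatch(fun(spec), error = function(e) {
      manifest$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) summary[[name]] <<- res
  }

  runStage("energetics", function(sp) {
    em <- residuePairMatrix(system, if (is.null(trajectory)) structure else trajectory,
                            getSel(sp$groupA), getSel(sp$groupB),
                            stride = if (is.null(sp$stride)) 1 else sp$stride)
    regions <- if (!is.null(sp$regions)) unlist(sp$regions) else NULL
    k <- if (is.null(sp$k)) 10 else sp$k
    rk <- lapply(c(coulomb = "coulomb", vdw = "vdw", total = "total"),
                 function(cmp) rankAndPartition(em, k = k, component = cmp,
                                                regionMap = regions))
    if (!is.null(outDir))
      exportHeatmapTable(em, file.path(outDir, "energetics_total.tsv"))
    st <- replicaStats(em)
    out <- list(topPairs = lapply(rk, `[[`, "topPairs"),
                nReplicas = st$nReplicas)
    if (!is.null(rk$total$blockSums)) out$blockSums <- rk$total$blockSums
    if (!is.null(rk$total$asymmetry)) out$asymmetry <- rk$total$asymmetry
    out
  })
  runStage("gbsa", function(sp) {
    rep <- mmgbsaBinding(system, if (is.null(trajectory)) {
      a <- atoms(structure); cbind(a$x, a$y, a$z)
    } else trajectory, getSel(sp$receptor), getSel(sp$ligand),
      stride = if (is.null(sp$stride)) 1 else sp$stride)
    if (!is.null(outDir))
      utils::write.csv(rep@perFrame, file.path(outDir, "gbsa_perframe.csv"),
                       row.names = FALSE)
    list(summary = rep@summary, replicaStats = rep@replicaStats)
  })
  fitted <- NULL
  runStage("fluctuations", function(sp) {
    fitted <<- fitFrames(trajectory, fitSelection = getSel(sp$fitSelection))
    prof <- normalizeBFactors(rmsf(fitted, selection = getSel(sp$selection)))
    if (!is.null(outDir)) {
      utils::write.table(prof, file.path(outDir, "rmsf_bfactors.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      writeStructure(structure, file.path(outDir, "bfactor_colored.pdb"),
                     scalars = {
                       b <- numeric(natoms(structure)); b[prof$atom] <- prof$bNorm; b
                     })
    }
    list(meanRmsf = mean(prof$rmsf), maxRmsf = max(prof$rmsf),
         profile = prof)
  })
  runStage("pca", function(sp) {
    tr <- if (is.null(fitted)) fitFrames(trajectory,
                                         fitSelection = getSel(sp$fitSelection))
          else fitted
    ms <- trajectoryPCA(tr, selection = getSel(sp$selection),
                        nModes = if (is.null(sp$nModes)) 5 else sp$nModes)
    if (!is.null(outDir))
      exportModeTrajectory(ms, tr@template,
                           file.path(outDir, "pc1_animation.pdb"))
    list(eigenvalues = modeValues(ms),
         varianceFractions = varianceFractions(ms))
  })
  runStage("cavity", function(sp) {
    cav <- luminalCavity(structure, getSel(sp$walls),
                         seed = as.numeric(unlist(sp$seedPoint)),
                         spacing = if (is.null(sp$spacing)) 0.5 else sp$spacing,
                         probe = if (is.null(sp$probe)) 1.4 else sp$probe)
    if (!is.null(sp$client))
      cav <- occupancyFraction(cav, structure, getSel(sp$client))
    list(cavityVolume = cavityVolume(cav), clientVolume = clientVolume(cav),
         occupancy = occupancy(cav))
  })
  runStage("comparative", function(sp) {
    res <- protomerAsymmetry(structure, sp$chainA, sp$chainB)
    list(rmsd = res$rmsd, n = res$n,
         maxDeviation = max(res$deviations$deviation),
         identity = if (is.null(res$alignment)) NA else res$alignment$identity)
  })

  if (!is.null(outDir)) {
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE, dataframe = "columns")
  }
  attr(summary, "manifest") <- manifest
  invisible(summary)
}
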