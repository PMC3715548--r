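#' @include ensemble-analysis.R trajectory-analysis.R
NULL

.logLevels <- c(debug = 1L, info = 2L, warn = 3L)

.mkLogger <- function(level, file = NULL) {
  lvl <- .logLevels[[match.arg(level, names(.logLevels))]]
  function(msgLevel, ...) {
    if (.logLevels[[msgLevel]] >= lvl) {
      line <- paste0("[", msgLevel, "] ", ...)
      message(line)
      if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
    }
  }
}

#' Assemble a pipeline configuration
#'
#' Validated parameter bundle for [runStateAnalysis()] /
#' [runComparison()].  Defaults follow the package-wide conventions: 10 A
#' contact cutoff, the ten slowest GNM modes, ten essential modes, 3.5 A
#' cluster radius.
#'
#' @param input path to a (multi-model) PDB file, or a
#'   [StructureEnsemble-class] given directly.
#' @param analysis \code{"auto"} (single-structure map for one model,
#'   ensemble-averaged map otherwise), \code{"ensemble"}, \code{"single"},
#'   or \code{"trajectory"} (cluster, then GNM on cluster best members).
#' @param chains optional chain filter applied when reading \code{input}.
#' @param cutoff contact cutoff, Angstrom.
#' @param gnmModes integer pair: first and last slow mode.
#' @param pcaModes essential-mode count for trajectory analyses.
#' @param clusterRadius clustering radius, Angstrom.
#' @param discard equilibration frames dropped from a trajectory.
#' @param regions named list of [RegionSpec-class] or a region config file
#'   path (see [readRegionsConfig()]); regions named
#'   \code{hinge_A/hinge_B}, \code{camp_site_A/B}, \code{dna_site_A/B},
#'   \code{dna_domain_A/B} additionally trigger the switch report.
#' @param thresholds switch thresholds \code{c(theta1, theta2)}.
#' @param outDir output directory (created if missing).
#' @param seed integer seed recorded in the manifest (the analysis itself
#'   is deterministic).
#' @param logLevel \code{"debug"}, \code{"info"} or \code{"warn"}.
#' @return A named list of validated parameters (class
#'   \code{"gnmswitchConfig"}).
#' @export
pipelineConfig <- function(input, analysis = c("auto", "ensemble", "single",
                                               "trajectory"),
                           chains = NULL, cutoff = 10,
                           gnmModes = c(1L, 10L), pcaModes = 10L,
                           clusterRadius = 3.5, discard = 0L,
                           regions = NULL,
                           thresholds = c(theta1 = 0.2, theta2 = 0.2),
                           outDir = tempfile("gnmswitch_"), seed = NULL,
                           logLevel = "info") {
  analysis <- match.arg(analysis)
  stopifnot(cutoff > 0, clusterRadius > 0, pcaModes >= 1L,
            length(gnmModes) == 2L, gnmModes[1L] >= 1L,
            gnmModes[2L] >= gnmModes[1L], discard >= 0L)
  if (is.character(regions)) regions <- readRegionsConfig(regions)
  structure(list(input = input, analysis = analysis, chains = chains,
                 cutoff = cutoff, gnmModes = as.integer(gnmModes),
                 pcaModes = as.integer(pcaModes),
                 clusterRadius = clusterRadius, discard = as.integer(discard),
                 regions = regions, thresholds = thresholds, outDir = outDir,
                 seed = seed, logLevel = logLevel),
            class = "gnmswitchConfig")
}

## assemble per-subunit switch regions from a flat named region list;
## NULL unless the full hinge/camp_site/dna_site/dna_domain set is present
.switchRegions <- function(regions) {
  need <- c("hinge", "camp_site", "dna_site", "dna_domain")
  keys <- as.vector(outer(need, c("_A", "_B"), paste0))
  if (is.null(regions) || !all(keys %in% names(regions))) return(NULL)
  list(hinge = list(regions$hinge_A, regions$hinge_B),
       campSite = list(regions$camp_site_A, regions$camp_site_B),
       dnaSite = list(regions$dna_site_A, regions$dna_site_B),
       dnaDomain = list(regions$dna_domain_A, regions$dna_domain_B))
}

#' Run the end-to-end state analysis
#'
#' Executes the standard workflow for one functional state: read the
#' conformers; for a trajectory configuration discard equilibration frames,
#' cluster at the configured radius and take the cluster best members as
#' representative conformational states; compute the GNM cross-correlation
#' map (averaged over members where applicable), mean-square fluctuations,
#' any configured region profiles and the switch report; and write every
#' result as CSV plus a JSON run manifest to \code{config$outDir}.  Outputs
#' are a pure function of (input, config); on failure, files already
#' written by the run are removed and the error names the failing stage.
#'
#' @param config a configuration from [pipelineConfig()].
#' @return Invisibly, a list bundle: \code{map}, \code{msf},
#'   \code{profiles}, \code{switchReport}, \code{cluster}, \code{rmsd},
#'   \code{manifest}, \code{files}.
#' @export
runStateAnalysis <- function(config) {
  stopifnot(inherits(config, "gnmswitchConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log <- .mkLogger(config$logLevel, file.path(config$outDir, "run.log"))
  emit <- function(name, writer) {
    path <- file.path(config$outDir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  ensemble <- stage("input", {
    if (is(config$input, "StructureEnsemble")) config$input
    else readPdbModels(config$input, chains = config$chains)
  })
  range <- modeRange(config$gnmModes[1L], config$gnmModes[2L])
  analysis <- config$analysis
  if (analysis == "auto")
    analysis <- if (length(ensemble) == 1L) "single" else "ensemble"
  log("info", "analysis mode: ", analysis, " (", length(ensemble),
      " conformer(s))")

  cluster <- NULL; rmsd <- NULL
  if (analysis == "trajectory") {
    traj <- stage("trajectory", trajectory(ensemble,
                                           equilibration = config$discard))
    rmsd <- stage("rmsd", rmsdSeries(traj))
    emit("rmsd.csv", function(p)
      utils::write.csv(data.frame(frame = seq_along(rmsd), rmsd = rmsd), p,
                       row.names = FALSE))
    cluster <- stage("cluster", radiusCluster(traj, config$clusterRadius))
    log("info", length(cluster@centroids), " cluster(s) at radius ",
        config$clusterRadius, " A")
    emit("cluster_populations.csv", function(p)
      utils::write.csv(data.frame(cluster = seq_along(cluster@populations),
                                  population = cluster@populations,
                                  best_member = cluster@bestMembers +
                                    cluster@frameOffset), p,
                       row.names = FALSE))
    emit("cluster_evolution.csv", function(p)
      utils::write.csv(data.frame(frame = seq_along(cluster@assignments) +
                                    cluster@frameOffset,
                                  cluster = cluster@assignments), p,
                       row.names = FALSE))
    frames <- .retainedFrames(traj)
    best <- structureEnsemble(frames[cluster@bestMembers])
    emit("best_members.pdb", function(p) writeCalphaPdb(best, p))
    ensemble <- best
  } else if (analysis == "single") {
    ensemble <- structureEnsemble(ensemble@members[1L])
  }

  map <- stage("gnm", ensembleCorrelationMap(ensemble, config$cutoff, range))
  msf <- new("MSFProfile", values = diag(map@raw), modeRange = map@modeRange,
             residues = map@residues)
  emit("map_raw.csv", function(p) writeMatrixCsv(map@raw, map@residues, p))
  emit("map_normalized.csv", function(p)
    writeMatrixCsv(map@normalized, map@residues, p))
  emit("msf.csv", function(p) writeProfileCsv(msf@values, msf@residues, p))

  profiles <- list()
  if (!is.null(config$regions)) {
    profiles <- stage("regions", lapply(config$regions, function(r)
      regionProfile(map, r)))
    for (nm in names(profiles))
      emit(paste0("region_profile_", nm, ".csv"), function(p)
        writeProfileCsv(profiles[[nm]]@values, map@residues, p))
  }

  switchReport <- NULL
  sw <- .switchRegions(config$regions)
  if (!is.null(sw)) {
    switchReport <- stage("switch", switchScore(
      map, sw$hinge, sw$campSite, sw$dnaSite, sw$dnaDomain,
      thresholds = config$thresholds))
    emit("switch_report.csv", function(p) {
      df <- switchReport@couplings
      df$state <- switchReport@stateLabels[df$subunit]
      utils::write.csv(df, p, row.names = FALSE)
    })
    log("info", "switch labels: ",
        paste(names(switchReport@stateLabels), switchReport@stateLabels,
              sep = "=", collapse = " "))
  }

  manifest <- list(
    package = "gnmswitch",
    version = as.character(utils::packageVersion("gnmswitch")),
    analysis = analysis,
    parameters = list(cutoff = config$cutoff, gnmModes = config$gnmModes,
                      pcaModes = config$pcaModes,
                      clusterRadius = config$clusterRadius,
                      discard = config$discard,
                      thresholds = as.list(config$thresholds)),
    seed = config$seed,
    nConformers = length(ensemble),
    nResidues = nrow(map@residues),
    nClusters = if (is.null(cluster)) NULL else length(cluster@centroids),
    outputs = basename(written))
  emit("manifest.json", function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))

  invisible(list(map = map, msf = msf, profiles = profiles,
                 switchReport = switchReport, cluster = cluster, rmsd = rmsd,
                 manifest = manifest, files = written))
}

#' Compare two functional states
#'
#' Runs [runStateAnalysis()] for both configurations (into \code{stateA/}
#' and \code{stateB/} under \code{outDir}), then writes the
#' difference-correlation map, the difference-MSF profile and the paired
#' switch reports on the residue intersection.
#'
#' @param configA,configB configurations from [pipelineConfig()].
#' @param outDir output directory for the comparison bundle.
#' @param labels character pair naming the two states.
#' @return Invisibly, a list with \code{bundleA}, \code{bundleB},
#'   \code{differenceMap} ([DifferenceMap-class]) and \code{differenceMsf}.
#' @export
runComparison <- function(configA, configB,
                          outDir = tempfile("gnmswitch_cmp_"),
                          labels = c("A", "B")) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  configA$outDir <- file.path(outDir, "stateA")
  configB$outDir <- file.path(outDir, "stateB")
  bundleA <- runStateAnalysis(configA)
  bundleB <- runStateAnalysis(configB)
  dmap <- differenceCorrelationMap(bundleA$map, bundleB$map, labels = labels)
  dmsf <- differenceMsf(bundleA$msf, bundleB$msf)
  writeMatrixCsv(dmap@values, dmap@residues,
                 file.path(outDir, "difference_map.csv"))
  utils::write.csv(data.frame(label = names(dmsf), difference_msf = dmsf),
                   file.path(outDir, "difference_msf.csv"), row.names = FALSE)
  if (!is.null(bundleA$switchReport) && !is.null(bundleB$switchReport)) {
    dfA <- bundleA$switchReport@couplings; dfA$state <- labels[1L]
    dfB <- bundleB$switchReport@couplings; dfB$state <- labels[2L]
    utils::write.csv(rbind(dfA, dfB),
                     file.path(outDir, "switch_reports.csv"),
                     row.names = FALSE)
  }
  invisible(list(bundleA = bundleA, bundleB = bundleB,
                 differenceMap = dmap, differenceMsf = dmsf))
}
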