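#' @importFrom jsonlite write_json read_json
NULL

.runManifest <- function(command, inputs = character(), seed = NULL) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  list(command = command,
       package = "cbctdose",
       version = as.character(utils::packageVersion("cbctdose")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       input_digests = digests)
}

.writeDoseReport <- function(res, organTable, manifest, outDir, stem) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(outDir, paste0(stem, "_organ_doses.csv"))
  utils::write.csv(organDoseTable(organTable)[, c("tissue", "H_mSv",
                                                  "category")],
                   csv, row.names = FALSE, quote = FALSE)
  js <- file.path(outDir, paste0(stem, "_effective_dose.json"))
  jsonlite::write_json(list(
    manifest = manifest,
    method = res@methodLabel,
    protocol = attr(res, "protocol"),
    effective_dose_uSv = res@effectiveDoseUSv,
    per_tissue_uSv = as.list(res@perTissueUSv)
  ), js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(organ_doses = csv, effective_dose = js))
}

#' Run the dosimetry arm from files and write its reports
#'
#' Reads a dosimeter reading file, runs the measurement pipeline for one
#' protocol and writes the organ-dose table (CSV, registry ordering) and
#' an effective-dose JSON report embedding the run manifest.
#'
#' @param readingsPath CSV of readings (site_id, run, counts/dose_mGy).
#' @param protocol protocol identifier (e.g. \code{"CS9300 facial"}) or an
#'   \linkS4class{ExposureProtocol}.
#' @param outDir output directory (created if needed).
#' @param registryPath tissue-registry YAML, \code{NULL} for bundled.
#' @param protocolsPath protocol YAML, \code{NULL} for bundled (only used
#'   when \code{protocol} is an identifier).
#' @param curve calibration curve for count readings.
#' @return invisibly, named character vector of written file paths.
#' @export
runOsldReport <- function(readingsPath, protocol, outDir,
                          registryPath = NULL, protocolsPath = NULL,
                          curve = calibrationCurve()) {
  if (!file.exists(readingsPath))
    stop("osld stage: readings file not found: ", readingsPath)
  if (is.character(protocol)) {
    prs <- loadProtocols(protocolsPath)
    if (!protocol %in% names(prs))
      stop("osld stage: unknown protocol '", protocol, "'")
    protocol <- prs[[protocol]]
  }
  registry <- loadTissueRegistry(registryPath)
  readings <- readReadings(readingsPath)
  res <- runOsldArm(readings, registry, protocol, curve = curve)
  attr(res, "protocol") <- protocolId(protocol)
  manifest <- .runManifest("osld", c(readingsPath, registryPath))
  .writeDoseReport(res, attr(res, "organDoses"), manifest, outDir,
                   paste0("osld_", gsub("[^A-Za-z0-9]+", "_",
                                        protocolId(protocol))))
}

#' Run the simulation arm from files and write its reports
#'
#' Monte Carlo rotational simulation for one protocol, scaled by the
#' measured DAP read from file; writes the organ-dose table and an
#' effective-dose JSON embedding seed and manifest.
#'
#' @inheritParams runOsldReport
#' @param dapPath CSV of DAP readings (protocol, reading_mGy_cm2);
#'   \code{NULL} uses the bundled reference summaries.
#' @param phantomPath phantom YAML, \code{NULL} for bundled.
#' @param nPhotons source photons.
#' @param seed integer RNG seed (required).
#' @return invisibly, named character vector of written file paths.
#' @export
runMcReport <- function(protocol, outDir, dapPath = NULL,
                        registryPath = NULL, protocolsPath = NULL,
                        phantomPath = NULL, nPhotons = 1e5, seed) {
  if (missing(seed)) stop("mc stage: seed is required")
  if (is.character(protocol)) {
    prs <- loadProtocols(protocolsPath)
    if (!protocol %in% names(prs))
      stop("mc stage: unknown protocol '", protocol, "'")
    protocol <- prs[[protocol]]
  }
  id <- protocolId(protocol)
  registry <- loadTissueRegistry(registryPath)
  phantom <- loadPhantom(phantomPath)
  if (is.null(dapPath)) {
    ref <- dapReference()
    if (!id %in% ref$protocol)
      stop("mc stage: no bundled DAP reference for '", id, "'")
    r <- ref[ref$protocol == id, ]
    dap <- dapFromSummary(id, r$mean_mGy_cm2, r$sd_mGy_cm2)
  } else {
    daps <- readDapMeasurements(dapPath)
    if (!id %in% names(daps))
      stop("mc stage: no DAP readings for '", id, "' in ", dapPath)
    dap <- daps[[id]]
  }
  if (dap@meanDap <= 0) stop("mc stage: measured DAP must be > 0")
  res <- runMcArm(protocol, dap, registry, phantom,
                  nPhotons = nPhotons, seed = seed)
  attr(res, "protocol") <- id
  manifest <- .runManifest("mc", c(dapPath, registryPath, phantomPath),
                           seed = as.integer(seed))
  .writeDoseReport(res, attr(res, "organDoses"), manifest, outDir,
                   paste0("mc_", gsub("[^A-Za-z0-9]+", "_", id)))
}

#' Compare written effective-dose reports
#'
#' Reads effective-dose JSON reports from both arms (any order; the method
#' label is taken from the files), pairs them by protocol, and writes the
#' comparison table as CSV and JSON.
#'
#' @param reportPaths character vector of effective-dose JSON files; each
#'   protocol must appear once per method.
#' @param outDir output directory.
#' @return the \linkS4class{ComparisonReport}, invisibly; files
#'   \code{comparison.csv} and \code{comparison.json} are written.
#' @export
runComparisonReport <- function(reportPaths, outDir) {
  docs <- lapply(reportPaths, function(p) {
    if (!file.exists(p)) stop("compare stage: report not found: ", p)
    jsonlite::read_json(p, simplifyVector = TRUE)
  })
  methods <- vapply(docs, function(d) d$method, character(1))
  mkRes <- function(d) new("EffectiveDoseResult",
                           effectiveDoseUSv = d$effective_dose_uSv,
                           perTissueUSv = unlist(d$per_tissue_uSv),
                           methodLabel = d$method)
  pick <- function(m) {
    sel <- docs[methods == m]
    stats::setNames(lapply(sel, mkRes),
                    vapply(sel, function(d) d$protocol, character(1)))
  }
  osld <- pick("OSLD")
  mc <- pick("MC")
  if (!length(osld) || !length(mc))
    stop("compare stage: reports from both methods (OSLD and MC) required")
  report <- buildReport(osld, mc)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report@rows, file.path(outDir, "comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    manifest = .runManifest("compare", unlist(reportPaths)),
    rows = report@rows,
    summary = list(min_percent_difference = report@summaryRange[1],
                   max_percent_difference = report@summaryRange[2]),
    annotation = report@annotation
  ), file.path(outDir, "comparison.json"), auto_unbox = TRUE,
  digits = NA, pretty = TRUE)
  invisible(report)
}

#' Generate and write a synthetic reading campaign
#'
#' Convenience wrapper pairing the synthetic generator with the readings
#' file format: site truths, reader noise and repeat structure in, a
#' pipeline-ready CSV plus a metadata JSON out.
#'
#' @param profile a \linkS4class{GroundTruthProfile}.
#' @param outDir output directory.
#' @return invisibly, named character vector of written paths.
#' @export
writeSyntheticReadings <- function(profile, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  readings <- generateReadingSet(profile)
  csv <- file.path(outDir, "readings.csv")
  writeReadings(readings, csv)
  meta <- file.path(outDir, "readings_meta.json")
  jsonlite::write_json(list(
    manifest = .runManifest("synth", seed = profile@seed),
    protocol = profile@protocolRef,
    reader_cv = profile@readerCv,
    n_repeats = profile@nRepeats,
    site_true_dose_mGy = as.list(profile@siteDose)
  ), meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(readings = csv, metadata = meta))
}
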