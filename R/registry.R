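#' @importFrom yaml read_yaml write_yaml
#' @importFrom utils read.csv write.csv
NULL

.protocolFields <- c(
  machine_name = "machineName",
  mode_name = "modeName",
  fov_width_cm = "fovWidthCm",
  fov_height_cm = "fovHeightCm",
  tube_voltage_kVp = "tubeVoltageKvp",
  tube_current_mA = "tubeCurrentMa",
  exposure_time_s = "exposureTimeS",
  rotation_angle_deg = "rotationAngleDeg",
  filtration_mmAl = "filtrationMmAl",
  source_to_reference_cm = "sourceToReferenceCm",
  beam_width_at_center_cm = "beamWidthCm",
  beam_height_at_center_cm = "beamHeightCm"
)

#' Locate a bundled configuration file
#' @param name file name under the package's \code{extdata} directory.
#' @return absolute path.
#' @export
cbctdoseFile <- function(name) {
  p <- system.file("extdata", name, package = "cbctdose", mustWork = FALSE)
  if (!nzchar(p)) stop("bundled file not found: ", name)
  p
}

#' Load exposure protocols
#'
#' Reads a YAML protocol registry (field names documented in
#' \code{protocols.yaml}). With \code{path = NULL} the bundled registry of
#' the four examination modes (CS9300 facial and dual jaw, RAYSCAN alpha+
#' large jaw and jaw) is used.
#'
#' @param path YAML file, or \code{NULL} for the bundled registry.
#' @return named list of \linkS4class{ExposureProtocol}; names are
#'   \code{"<machine> <mode>"}.
#' @examples
#' pr <- loadProtocols()
#' pr[["CS9300 facial"]]
#' @export
loadProtocols <- function(path = NULL) {
  if (is.null(path)) path <- cbctdoseFile("protocols.yaml")
  doc <- yaml::read_yaml(path)
  if (is.null(doc$protocols))
    stop("configuration error: missing field 'protocols'")
  out <- lapply(doc$protocols, function(p) {
    missing <- setdiff(names(.protocolFields), names(p))
    if (length(missing))
      stop("configuration error: missing field(s) ",
           paste(missing, collapse = ", "),
           " in protocol '", paste(p$machine_name, p$mode_name), "'")
    args <- stats::setNames(p[names(.protocolFields)],
                            unname(.protocolFields))
    args$machineName <- as.character(args$machineName)
    args$modeName <- as.character(args$modeName)
    args[-(1:2)] <- lapply(args[-(1:2)], as.numeric)
    do.call(new, c(list("ExposureProtocol"), args))
  })
  names(out) <- vapply(out, protocolId, character(1))
  out
}

#' Protocol identifier
#' @param protocol an \linkS4class{ExposureProtocol}.
#' @return \code{"<machine> <mode>"}.
#' @export
protocolId <- function(protocol) {
  paste(protocol@machineName, protocol@modeName)
}

setMethod("show", "ExposureProtocol", function(object) {
  cat(sprintf(
    "ExposureProtocol '%s': %g kVp, %g mA, %g s, FOV %g x %g cm,\n",
    protocolId(object), object@tubeVoltageKvp, object@tubeCurrentMa,
    object@exposureTimeS, object@fovWidthCm, object@fovHeightCm))
  cat(sprintf(
    "  rotation %g deg, filtration %g mmAl, SRD %g cm, beam %g x %g cm\n",
    object@rotationAngleDeg, object@filtrationMmAl,
    object@sourceToReferenceCm, object@beamWidthCm, object@beamHeightCm))
})

.tissueEntryFromList <- function(t) {
  subsites <- lapply(t$subsites, function(ss) {
    need <- c("subsite_name", "subsite_fraction", "dosimeter_site_ids")
    missing <- setdiff(need, names(ss))
    if (length(missing))
      stop("configuration error: missing field(s) ",
           paste(missing, collapse = ", "), " in a subsite of tissue '",
           t$tissue_name, "'")
    list(name = as.character(ss$subsite_name),
         fraction = as.numeric(ss$subsite_fraction),
         sites = as.integer(unlist(ss$dosimeter_site_ids)))
  })
  new("TissueEntry",
      tissueName = as.character(t$tissue_name),
      weightingFactor = if (is.null(t$weighting_factor)) NA_real_
                        else as.numeric(t$weighting_factor),
      category = as.character(t$category),
      aggregate = as.character(t$aggregate),
      applyMeacr = isTRUE(t$apply_meacr),
      subsites = subsites)
}

#' Load the tissue registry
#'
#' Reads a YAML tissue registry: the dosimeter-site map and, per tissue,
#' the ICRP 103 weighting factor, fraction-irradiated subsites, and the
#' dosimeter sites measuring each subsite. With \code{path = NULL} the
#' bundled head-and-neck registry (22 sites) is loaded.
#'
#' The bundled bone-surface cervical-spine row defaults to dosimeter site
#' 19 (the cervical-spine slot used by bone marrow). Some tabulations print
#' site 21 — a thyroid slot, most likely a typographical slip — and
#' \code{boneSurfaceCspineSite = 21} selects that mapping instead.
#'
#' @param path YAML file, or \code{NULL} for the bundled registry.
#' @param boneSurfaceCspineSite dosimeter site for the bone-surface
#'   cervical-spine subsite; 19 (default) or 21. Only applied to the
#'   bundled registry layout (a \code{bone_surface} tissue with a
#'   \code{cervical_spine} subsite).
#' @return a \linkS4class{TissueRegistry}.
#' @examples
#' reg <- loadTissueRegistry()
#' tissueNames(reg)
#' @export
loadTissueRegistry <- function(path = NULL, boneSurfaceCspineSite = 19L) {
  if (is.null(path)) path <- cbctdoseFile("tissue_registry.yaml")
  boneSurfaceCspineSite <- as.integer(boneSurfaceCspineSite)
  if (!boneSurfaceCspineSite %in% c(19L, 21L))
    stop("boneSurfaceCspineSite must be 19 or 21")
  doc <- yaml::read_yaml(path)
  for (f in c("sites", "tissues"))
    if (is.null(doc[[f]]))
      stop("configuration error: missing field '", f, "'")
  sites <- do.call(rbind, lapply(doc$sites, function(s)
    data.frame(site_id = as.integer(s$site_id),
               anatomical_label = as.character(s$anatomical_label),
               phantom_slice = as.integer(s$phantom_slice))))
  tissues <- lapply(doc$tissues, .tissueEntryFromList)
  names(tissues) <- vapply(tissues, function(t) t@tissueName, character(1))
  if (boneSurfaceCspineSite == 21L && "bone_surface" %in% names(tissues)) {
    bs <- tissues[["bone_surface"]]
    for (i in seq_along(bs@subsites))
      if (bs@subsites[[i]]$name == "cervical_spine")
        bs@subsites[[i]]$sites <- 21L
    tissues[["bone_surface"]] <- bs
  }
  reg <- new("TissueRegistry",
             sites = sites,
             tissues = tissues,
             remainderWeight =
               as.numeric(doc$remainder_weighting_factor %||% 0.12))
  validObject(reg)
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tissue registry back to YAML
#'
#' Inverse of \code{\link{loadTissueRegistry}}; a written registry re-reads
#' to an identical object.
#'
#' @param registry a \linkS4class{TissueRegistry}.
#' @param path output YAML file.
#' @return \code{path}, invisibly.
#' @export
writeTissueRegistry <- function(registry, path) {
  doc <- list(
    sites = lapply(seq_len(nrow(registry@sites)), function(i) {
      s <- registry@sites[i, ]
      list(site_id = s$site_id, anatomical_label = s$anatomical_label,
           phantom_slice = s$phantom_slice)
    }),
    remainder_weighting_factor = registry@remainderWeight,
    tissues = lapply(registry@tissues, function(t) {
      out <- list(tissue_name = t@tissueName,
                  category = t@category,
                  aggregate = t@aggregate,
                  apply_meacr = t@applyMeacr,
                  subsites = lapply(t@subsites, function(ss)
                    list(subsite_name = ss$name,
                         subsite_fraction = ss$fraction,
                         dosimeter_site_ids = ss$sites)))
      if (is.finite(t@weightingFactor))
        out <- c(out[1], list(weighting_factor = t@weightingFactor),
                 out[-1])
      out
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Tissue names of a registry
#' @param registry a \linkS4class{TissueRegistry}.
#' @param category restrict to \code{"weighted_tissue"},
#'   \code{"remainder_component"}, or \code{NULL} for all.
#' @return character vector.
#' @export
tissueNames <- function(registry, category = NULL) {
  t <- registry@tissues
  if (!is.null(category))
    t <- Filter(function(x) x@category == category, t)
  vapply(t, function(x) x@tissueName, character(1), USE.NAMES = FALSE)
}

#' Registry dosimeter-site table
#' @param registry a \linkS4class{TissueRegistry}.
#' @return data.frame with site_id, anatomical_label, phantom_slice.
#' @export
registrySites <- function(registry) registry@sites

#' Derived fraction irradiated of a tissue
#'
#' For distributed tissues (\code{aggregate == "weighted_sum"}) the total
#' fraction is the sum of the subsite fractions; otherwise it is their mean.
#'
#' @param tissue a \linkS4class{TissueEntry}.
#' @return proportion in [0, ~1].
#' @export
fractionIrradiated <- function(tissue) {
  f <- vapply(tissue@subsites, function(ss) ss$fraction, numeric(1))
  if (tissue@aggregate == "weighted_sum") sum(f) else mean(f)
}

#' Sum of represented tissue weighting factors
#'
#' Weighted tissues plus the shared remainder weight; 0.36 for the bundled
#' head-and-neck registry (the out-of-field ICRP 103 tissues are zero-dose
#' and carry the remaining 0.64).
#'
#' @param registry a \linkS4class{TissueRegistry}.
#' @return numeric scalar.
#' @export
tissueWeightSum <- function(registry) {
  w <- vapply(Filter(function(t) t@category == "weighted_tissue",
                     registry@tissues),
              function(t) t@weightingFactor, numeric(1))
  sum(w) + registry@remainderWeight
}

setMethod("show", "TissueRegistry", function(object) {
  cat(sprintf(
    "TissueRegistry: %d dosimeter sites, %d weighted tissues, %d remainder components\n",
    nrow(object@sites),
    sum(vapply(object@tissues, function(t)
      t@category == "weighted_tissue", logical(1))),
    sum(vapply(object@tissues, function(t)
      t@category == "remainder_component", logical(1)))))
  cat(sprintf("  represented weight sum: %.2f (remainder W = %.2f)\n",
              tissueWeightSum(object), object@remainderWeight))
})

#' Construct a DAP measurement from raw readings
#' @param protocolRef protocol identifier ("machine mode").
#' @param readings numeric DAP readings, mGy cm^2.
#' @return a \linkS4class{DapMeasurement}.
#' @export
newDapMeasurement <- function(protocolRef, readings) {
  readings <- as.numeric(readings)
  new("DapMeasurement", protocolRef = as.character(protocolRef),
      readings = readings, meanDap = mean(readings),
      sdDap = if (length(readings) > 1) stats::sd(readings) else 0)
}

#' Construct a DAP measurement from a published mean and SD
#'
#' Builds the two deterministic readings \eqn{m \mp s/\sqrt{2}} whose mean
#' and sample standard deviation reproduce the published summary exactly.
#'
#' @param protocolRef protocol identifier.
#' @param mean,sd published mean and standard deviation, mGy cm^2.
#' @return a \linkS4class{DapMeasurement}.
#' @export
dapFromSummary <- function(protocolRef, mean, sd = 0) {
  if (!is.finite(mean) || mean <= 0) stop("DAP mean must be > 0")
  newDapMeasurement(protocolRef, mean + c(-1, 1) * sd / sqrt(2))
}

#' Read DAP measurements from delimited text
#'
#' Expects a CSV with header columns \code{protocol} and
#' \code{reading_mGy_cm2}, one reading per row.
#'
#' @param path CSV file.
#' @return named list of \linkS4class{DapMeasurement}, one per protocol.
#' @export
readDapMeasurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protocol", "reading_mGy_cm2")
  if (!all(need %in% names(d)))
    stop("DAP file must have columns: ", paste(need, collapse = ", "))
  ids <- unique(d$protocol)
  out <- lapply(ids, function(id)
    newDapMeasurement(id, d$reading_mGy_cm2[d$protocol == id]))
  names(out) <- ids
  out
}

#' Reference DAP summaries for the bundled protocols
#'
#' Measured mean and standard deviation of the dose-area product per
#' examination mode (two meter readings per mode), used as the simulation
#' arm's input dose.
#'
#' @return data.frame with protocol, mean_mGy_cm2, sd_mGy_cm2, n.
#' @export
dapReference <- function() {
  utils::read.csv(cbctdoseFile("dap_reference.csv"),
                  stringsAsFactors = FALSE)
}

setMethod("show", "DapMeasurement", function(object) {
  cat(sprintf("DapMeasurement '%s': %.1f +/- %.1f mGy cm^2 (n = %d)\n",
              object@protocolRef, object@meanDap, object@sdDap,
              length(object@readings)))
})
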