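#' @import methods
NULL

#' Exposure protocol for one CBCT machine/mode
#'
#' Bundles the beam geometry and technique factors of a single examination
#' mode: field of view, tube voltage and current, exposure time, rotation
#' angle, aluminium-equivalent filtration, source-to-reference distance and
#' the beam rectangle (width x height) at the rotation center.
#'
#' @slot machineName character, e.g. \code{"CS9300"}.
#' @slot modeName character, e.g. \code{"facial"}.
#' @slot fovWidthCm,fovHeightCm field-of-view diameter and height, cm.
#' @slot tubeVoltageKvp tube potential, kVp.
#' @slot tubeCurrentMa tube current, mA (carried for provenance; the dose
#'   math is driven by measured DAP, not mAs).
#' @slot exposureTimeS exposure time, s.
#' @slot rotationAngleDeg orbit angle, degrees, in (0, 360].
#' @slot filtrationMmAl total filtration, mm aluminium equivalent.
#' @slot sourceToReferenceCm X-ray source to rotation-center distance, cm.
#' @slot beamWidthCm,beamHeightCm beam rectangle at the rotation center, cm.
#'
#' @export
setClass("ExposureProtocol",
  representation(
    machineName = "character",
    modeName = "character",
    fovWidthCm = "numeric",
    fovHeightCm = "numeric",
    tubeVoltageKvp = "numeric",
    tubeCurrentMa = "numeric",
    exposureTimeS = "numeric",
    rotationAngleDeg = "numeric",
    filtrationMmAl = "numeric",
    sourceToReferenceCm = "numeric",
    beamWidthCm = "numeric",
    beamHeightCm = "numeric"
  )
)

setValidity("ExposureProtocol", function(object) {
  msg <- character()
  num <- c(
    fovWidthCm = object@fovWidthCm, fovHeightCm = object@fovHeightCm,
    tubeVoltageKvp = object@tubeVoltageKvp,
    tubeCurrentMa = object@tubeCurrentMa,
    exposureTimeS = object@exposureTimeS,
    rotationAngleDeg = object@rotationAngleDeg,
    sourceToReferenceCm = object@sourceToReferenceCm,
    beamWidthCm = object@beamWidthCm, beamHeightCm = object@beamHeightCm
  )
  bad <- names(num)[!is.finite(num) | num <= 0]
  if (length(bad))
    msg <- c(msg, paste0("strictly positive value required for: ",
                         paste(bad, collapse = ", ")))
  if (!is.finite(object@filtrationMmAl) || object@filtrationMmAl < 0)
    msg <- c(msg, "filtrationMmAl must be >= 0")
  if (is.finite(object@rotationAngleDeg) && object@rotationAngleDeg > 360)
    msg <- c(msg, "rotationAngleDeg must lie in (0, 360]")
  tol <- 1e-6
  if (all(is.finite(num))) {
    if (object@beamWidthCm > object@fovWidthCm + tol)
      msg <- c(msg, "beam width at center exceeds FOV width")
    if (object@beamHeightCm > object@fovHeightCm + tol)
      msg <- c(msg, "beam height at center exceeds FOV height")
  }
  if (length(msg)) msg else TRUE
})

#' A tissue (or remainder component) of the dose registry
#'
#' One row-group of the head-and-neck tissue registry: the ICRP 103 tissue
#' weighting factor, the fraction of the tissue assumed inside the exposed
#' field, and the dosimeter sites (grouped into subsites) that measure it.
#'
#' @slot tissueName character tissue identifier (snake_case).
#' @slot weightingFactor ICRP 103 W_T; \code{NA} for remainder components
#'   (the remainder set carries a single shared weight).
#' @slot category \code{"weighted_tissue"} or \code{"remainder_component"}.
#' @slot aggregate how subsite doses combine: \code{"weighted_sum"} for
#'   distributed tissues (bone marrow, bone surface: sum of subsite fraction
#'   times subsite mean dose) or \code{"mean"} (average over subsites of
#'   fraction times subsite mean dose).
#' @slot applyMeacr logical; multiply the aggregated dose by the
#'   bone-to-muscle mass energy absorption coefficient ratio (bone surface).
#' @slot subsites list of lists with elements \code{name},
#'   \code{fraction} (proportion in [0,1]) and \code{sites} (dosimeter ids).
#' @export
setClass("TissueEntry",
  representation(
    tissueName = "character",
    weightingFactor = "numeric",
    category = "character",
    aggregate = "character",
    applyMeacr = "logical",
    subsites = "list"
  )
)

setValidity("TissueEntry", function(object) {
  msg <- character()
  if (!object@category %in% c("weighted_tissue", "remainder_component"))
    msg <- c(msg, "category must be weighted_tissue or remainder_component")
  if (!object@aggregate %in% c("weighted_sum", "mean"))
    msg <- c(msg, "aggregate must be weighted_sum or mean")
  if (object@category == "weighted_tissue" &&
      (!is.finite(object@weightingFactor) || object@weightingFactor < 0))
    msg <- c(msg, "weightingFactor must be non-negative")
  for (ss in object@subsites) {
    if (!all(c("name", "fraction", "sites") %in% names(ss))) {
      msg <- c(msg, "each subsite needs name, fraction, sites")
      next
    }
    if (!is.finite(ss$fraction) || ss$fraction < 0 || ss$fraction > 1)
      msg <- c(msg, sprintf("subsite '%s': fraction must lie in [0,1]",
                            ss$name))
    if (!length(ss$sites))
      msg <- c(msg, sprintf("subsite '%s': no dosimeter sites", ss$name))
  }
  if (length(msg)) msg else TRUE
})

#' Head-and-neck tissue registry
#'
#' The dosimeter-site map plus the tissue table both pipeline arms consume.
#' Out-of-field ICRP 103 tissues (lung, stomach, colon, breast, gonads,
#' bladder, liver) are treated as zero-dose and are not listed; the weights
#' represented here (weighted tissues plus the remainder) sum to 0.36, the
#' head-and-neck subset of the ICRP 103 scheme.
#'
#' @slot sites data.frame with columns \code{site_id}, \code{anatomical_label},
#'   \code{phantom_slice} (22 rows in the bundled registry).
#' @slot tissues list of \linkS4class{TissueEntry}.
#' @slot remainderWeight shared W_T of the remainder tissue set (0.12).
#' @export
setClass("TissueRegistry",
  representation(
    sites = "data.frame",
    tissues = "list",
    remainderWeight = "numeric"
  )
)

setValidity("TissueRegistry", function(object) {
  msg <- character()
  s <- object@sites
  if (!all(c("site_id", "anatomical_label") %in% names(s)))
    return("sites needs columns site_id, anatomical_label")
  if (anyDuplicated(s$site_id))
    msg <- c(msg, "site_id values must be unique")
  if (!is.finite(object@remainderWeight) || object@remainderWeight < 0)
    msg <- c(msg, "remainderWeight must be non-negative")
  known <- s$site_id
  for (te in object@tissues) {
    v <- validObject(te, test = TRUE)
    if (is.character(v)) msg <- c(msg, paste0(te@tissueName, ": ", v))
    for (ss in te@subsites) {
      unknown <- setdiff(unlist(ss$sites), known)
      if (length(unknown))
        msg <- c(msg, sprintf("tissue '%s' subsite '%s': unknown site id %s",
                              te@tissueName, ss$name,
                              paste(unknown, collapse = ",")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' A set of DAP meter readings for one protocol
#'
#' Dose-area-product readings (mGy cm^2) for one machine/mode; the mean is
#' the simulation arm's input dose.
#'
#' @slot protocolRef character protocol identifier ("machine mode").
#' @slot readings numeric vector of DAP readings, mGy cm^2.
#' @slot meanDap,sdDap summary of the readings (sd is 0 for one reading).
#' @export
setClass("DapMeasurement",
  representation(
    protocolRef = "character",
    readings = "numeric",
    meanDap = "numeric",
    sdDap = "numeric"
  )
)

setValidity("DapMeasurement", function(object) {
  msg <- character()
  if (!length(object@readings) || any(!is.finite(object@readings)))
    msg <- c(msg, "readings must be finite and non-empty")
  else {
    if (abs(object@meanDap - mean(object@readings)) >
        1e-9 * max(1, abs(object@meanDap)))
      msg <- c(msg, "meanDap does not equal the mean of the readings")
    if (!is.finite(object@sdDap) || object@sdDap < 0)
      msg <- c(msg, "sdDap must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Repeat-averaged dosimeter site doses
#'
#' @slot doses named numeric vector, names are site ids, values mGy.
#' @slot missingSites integer ids of registry sites with no reading.
#' @slot flags character vector of per-site quality flags (e.g. readings
#'   beyond the calibrated range, single-repeat sites).
#' @export
setClass("SiteDoseTable",
  representation(
    doses = "numeric",
    missingSites = "integer",
    flags = "character"
  )
)

setValidity("SiteDoseTable", function(object) {
  if (length(object@doses) && any(object@doses < 0, na.rm = TRUE))
    return("site doses must be >= 0")
  TRUE
})

#' Organ equivalent doses H_T
#'
#' The bridge between both arms and the effective-dose sum: one equivalent
#' dose per weighted tissue and remainder component (photon radiation
#' weighting factor 1, so mGy absorbed dose equals mSv equivalent dose).
#'
#' @slot table data.frame with columns \code{tissue}, \code{H_mSv},
#'   \code{category}, \code{provenance}.
#' @export
setClass("OrganDoseTable", representation(table = "data.frame"))

setValidity("OrganDoseTable", function(object) {
  t <- object@table
  if (!all(c("tissue", "H_mSv", "category") %in% names(t)))
    return("table needs columns tissue, H_mSv, category")
  if (any(t$H_mSv < 0, na.rm = TRUE)) return("H_T must be >= 0")
  TRUE
})

#' Effective dose with its per-tissue breakdown
#'
#' @slot effectiveDoseUSv effective dose E, micro-sievert.
#' @slot perTissueUSv named numeric, W_T * H_T contributions in uSv.
#' @slot methodLabel \code{"OSLD"} or \code{"MC"}.
#' @export
setClass("EffectiveDoseResult",
  representation(
    effectiveDoseUSv = "numeric",
    perTissueUSv = "numeric",
    methodLabel = "character"
  )
)

setValidity("EffectiveDoseResult", function(object) {
  msg <- character()
  if (any(object@perTissueUSv < 0)) msg <- c(msg, "contributions must be >= 0")
  if (abs(object@effectiveDoseUSv - sum(object@perTissueUSv)) >
      1e-9 * max(1, object@effectiveDoseUSv))
    msg <- c(msg, "effective dose must equal the sum of contributions")
  if (!object@methodLabel %in% c("OSLD", "MC"))
    msg <- c(msg, "methodLabel must be OSLD or MC")
  if (length(msg)) msg else TRUE
})

#' Monte Carlo tally result, normalized per unit DAP
#'
#' Per-organ absorbed dose per unit dose-area product, with batch-statistics
#' standard errors, for one protocol and seed. Doses are mGy per mGy cm^2.
#'
#' @slot protocolRef character protocol identifier.
#' @slot nPhotons number of source photons.
#' @slot seed RNG seed used.
#' @slot dosePerDap named numeric, organ -> mGy/(mGy cm^2).
#' @slot stderrPerDap named numeric, batch standard errors, same units.
#' @slot dapPerPhoton simulated DAP per source photon, mGy cm^2.
#' @slot energyBalance named numeric: emitted/deposited/escaped energy (keV).
#' @slot batchDose matrix organ x batch of per-DAP doses (diagnostics).
#' @export
setClass("MCResult",
  representation(
    protocolRef = "character",
    nPhotons = "numeric",
    seed = "integer",
    dosePerDap = "numeric",
    stderrPerDap = "numeric",
    dapPerPhoton = "numeric",
    energyBalance = "numeric",
    batchDose = "matrix"
  )
)

setValidity("MCResult", function(object) {
  msg <- character()
  if (any(object@dosePerDap < 0)) msg <- c(msg, "doses must be >= 0")
  if (any(object@stderrPerDap < 0)) msg <- c(msg, "stderr must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Stylized head-and-neck phantom geometry
#'
#' An ordered list of geometric primitives (sphere, cylinder, ellipsoid,
#' box), each with a material (soft_tissue, bone, air) and an organ label;
#' earlier entries shadow later ones where primitives overlap, which is how
#' shells (brain inside calvaria) and embedded organs are expressed.
#'
#' @slot organs data.frame with columns \code{id}, \code{organ},
#'   \code{primitive}, \code{material}, \code{cx,cy,cz}, \code{d1,d2,d3}
#'   (semi-axes / radius / half-sizes, cm), \code{mass_g}.
#' @slot referencePoint numeric xyz (cm), the rotation center.
#' @slot boundCenter,boundRadius bounding sphere of the geometry (cm).
#' @export
setClass("PhantomGeometry",
  representation(
    organs = "data.frame",
    referencePoint = "numeric",
    boundCenter = "numeric",
    boundRadius = "numeric"
  )
)

setValidity("PhantomGeometry", function(object) {
  o <- object@organs
  need <- c("id", "organ", "primitive", "material",
            "cx", "cy", "cz", "d1", "d2", "d3", "mass_g")
  if (!all(need %in% names(o)))
    return(paste("organs needs columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (any(o$mass_g <= 0)) msg <- c(msg, "organ masses must be > 0")
  if (!all(o$primitive %in% c("sphere", "cylinder", "ellipsoid", "box")))
    msg <- c(msg, "unknown primitive")
  if (!all(o$material %in% c("soft_tissue", "bone", "air")))
    msg <- c(msg, "unknown material")
  if (length(object@referencePoint) != 3)
    msg <- c(msg, "referencePoint must be xyz")
  if (length(msg)) msg else TRUE
})

#' Filtered bremsstrahlung spectrum model
#'
#' Kramers-form photon fluence attenuated by aluminium filtration and
#' renormalized; a deterministic stand-in for a measured tube spectrum.
#'
#' @slot kvp tube potential (endpoint energy), kVp.
#' @slot filtrationMmAl aluminium filtration, mm.
#' @slot energiesKeV bin centers, keV (spacing <= 1 keV).
#' @slot fluence relative photon fluence per bin, sums to 1.
#' @export
setClass("SpectrumModel",
  representation(
    kvp = "numeric",
    filtrationMmAl = "numeric",
    energiesKeV = "numeric",
    fluence = "numeric"
  )
)

setValidity("SpectrumModel", function(object) {
  msg <- character()
  if (any(object@energiesKeV > object@kvp + 1e-9 & object@fluence > 0))
    msg <- c(msg, "fluence must vanish above the kVp endpoint")
  if (abs(sum(object@fluence) - 1) > 1e-9)
    msg <- c(msg, "fluence must sum to 1")
  if (length(object@energiesKeV) > 1 &&
      max(diff(object@energiesKeV)) > 1 + 1e-9)
    msg <- c(msg, "energy grid spacing must be <= 1 keV")
  if (length(msg)) msg else TRUE
})

#' Method-comparison report (effective doses and percent differences)
#'
#' @slot rows data.frame with columns \code{protocol}, \code{E_OSLD_uSv},
#'   \code{E_MC_uSv}, \code{percent_difference} (cells rounded to one
#'   decimal for presentation).
#' @slot summaryRange numeric length-2: min and max percent difference.
#' @slot annotation character notes derived from the rows (which method
#'   read higher per mode).
#' @export
setClass("ComparisonReport",
  representation(
    rows = "data.frame",
    summaryRange = "numeric",
    annotation = "character"
  )
)

setValidity("ComparisonReport", function(object) {
  r <- object@rows
  if (!all(c("protocol", "E_OSLD_uSv", "E_MC_uSv", "percent_difference")
           %in% names(r)))
    return("rows needs protocol, E_OSLD_uSv, E_MC_uSv, percent_difference")
  msg <- character()
  if (any(r$percent_difference < 0 | r$percent_difference >= 200))
    msg <- c(msg, "percent differences must lie in [0, 200)")
  if (nrow(r)) {
    if (abs(object@summaryRange[1] - min(r$percent_difference)) > 1e-9 ||
        abs(object@summaryRange[2] - max(r$percent_difference)) > 1e-9)
      msg <- c(msg, "summary range inconsistent with rows")
  }
  if (length(msg)) msg else TRUE
})

#' Ground-truth site-dose profile for the synthetic-data generator
#'
#' Defines the true dose at every dosimeter site for one protocol, together
#' with the reader noise (coefficient of variation) and repeat structure the
#' generator emulates.
#'
#' @slot protocolRef character protocol identifier.
#' @slot siteDose named numeric, site id -> true dose, mGy.
#' @slot readerCv reader coefficient of variation (1 sigma relative),
#'   default 0.02.
#' @slot nRepeats exposures per site, default 2.
#' @slot seed integer RNG seed.
#' @export
setClass("GroundTruthProfile",
  representation(
    protocolRef = "character",
    siteDose = "numeric",
    readerCv = "numeric",
    nRepeats = "integer",
    seed = "integer"
  )
)

setValidity("GroundTruthProfile", function(object) {
  msg <- character()
  if (any(object@siteDose < 0)) msg <- c(msg, "true doses must be >= 0")
  if (!is.finite(object@readerCv) ||
      object@readerCv < 0 || object@readerCv > 0.2)
    msg <- c(msg, "readerCv must lie in [0, 0.2]")
  if (object@nRepeats < 1L) msg <- c(msg, "nRepeats must be >= 1")
  if (length(msg)) msg else TRUE
})
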