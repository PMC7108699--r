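#' Linear OSLD calibration curve
#'
#' Converts reader photon counts to absorbed dose in mGy. The bundled
#' default slope is a synthetic stand-in chosen so that synthetic fixtures
#' round-trip (a vendor quality-control calibration would replace it);
#' readings supplied directly in mGy bypass calibration entirely.
#'
#' @param slope mGy per count, > 0.
#' @param intercept mGy offset.
#' @param nominalKv tube potential the calibration was established at.
#' @param maxDoseMGy upper end of the calibrated dose range; evaluations
#'   beyond it are flagged, not rejected.
#' @return a list of class \code{CalibrationCurve}.
#' @export
calibrationCurve <- function(slope = 1e-3, intercept = 0,
                             nominalKv = 80, maxDoseMGy = 30) {
  if (!is.finite(slope) || slope <= 0) stop("calibration slope must be > 0")
  structure(list(model = "linear", slope = slope, intercept = intercept,
                 nominalKv = nominalKv, maxDoseMGy = maxDoseMGy),
            class = "CalibrationCurve")
}

#' Convert reader counts to dose
#'
#' Evaluates the linear calibration \code{dose = slope * counts +
#' intercept}. Doses falling outside the calibrated range
#' \code{[0, maxDoseMGy]} are returned unchanged but flagged through the
#' \code{"outOfRange"} attribute and a warning.
#'
#' @param counts numeric photon counts (vectorized), >= 0.
#' @param curve a \code{\link{calibrationCurve}}.
#' @return numeric doses in mGy with logical attribute \code{outOfRange}.
#' @examples
#' countsToDose(1000, calibrationCurve(slope = 0.001))
#' @export
countsToDose <- function(counts, curve = calibrationCurve()) {
  if (any(!is.finite(counts) | counts < 0))
    stop("photon counts must be finite and >= 0")
  dose <- curve$slope * counts + curve$intercept
  oor <- dose < 0 | dose > curve$maxDoseMGy
  if (any(oor))
    warning(sum(oor), " reading(s) outside the calibrated range [0, ",
            curve$maxDoseMGy, "] mGy")
  attr(dose, "outOfRange") <- oor
  dose
}

#' Read a dosimeter reading file
#'
#' Delimited text with header columns \code{site_id}, \code{run} and at
#' least one of \code{counts}, \code{dose_mGy}.
#'
#' @param path CSV file.
#' @return data.frame of readings.
#' @export
readReadings <- function(path) {
  if (!file.exists(path)) stop("readings file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "run") %in% names(d)))
    stop("readings file must have columns site_id, run")
  if (!any(c("counts", "dose_mGy") %in% names(d)))
    stop("readings file needs a counts or dose_mGy column")
  d
}

#' Average repeated exposures into per-site doses
#'
#' Takes per-exposure dosimeter readings (already in mGy) and returns the
#' arithmetic mean per site. Registry sites with no reading are marked
#' missing (with a warning, or an error when \code{failOnMissing}); sites
#' with a single repeat are flagged.
#'
#' @param readings data.frame with columns \code{site_id}, \code{run},
#'   \code{dose_mGy}.
#' @param registry optional \linkS4class{TissueRegistry} whose site list
#'   defines completeness.
#' @param failOnMissing error instead of warn on registry sites without
#'   readings.
#' @return a \linkS4class{SiteDoseTable}.
#' @export
averageRepeats <- function(readings, registry = NULL,
                           failOnMissing = FALSE) {
  if (!"dose_mGy" %in% names(readings))
    stop("readings must carry dose_mGy (apply countsToDose first)")
  if (any(readings$dose_mGy < 0)) stop("doses must be >= 0")
  means <- tapply(readings$dose_mGy, readings$site_id, mean)
  nrep <- tapply(readings$dose_mGy, readings$site_id, length)
  doses <- as.numeric(means)
  names(doses) <- names(means)
  flags <- character()
  single <- names(nrep)[nrep == 1]
  if (length(single)) {
    warning("single repeat at site(s): ", paste(single, collapse = ", "))
    flags <- c(flags, paste0("single_repeat:", single))
  }
  missing <- integer()
  if (!is.null(registry)) {
    missing <- setdiff(registry@sites$site_id, as.integer(names(doses)))
    if (length(missing)) {
      msg <- paste("no readings for site(s):",
                   paste(missing, collapse = ", "))
      if (failOnMissing) stop(msg) else warning(msg)
    }
  }
  new("SiteDoseTable", doses = doses, missingSites = as.integer(missing),
      flags = flags)
}

setMethod("show", "SiteDoseTable", function(object) {
  cat(sprintf("SiteDoseTable: %d sites (%d missing), dose range %.4g-%.4g mGy\n",
              length(object@doses), length(object@missingSites),
              if (length(object@doses)) min(object@doses) else NA,
              if (length(object@doses)) max(object@doses) else NA))
})

.sitesMean <- function(siteTable, siteIds, context) {
  d <- siteTable@doses[as.character(siteIds)]
  if (all(is.na(d)))
    stop("all contributing dosimeter sites missing for ", context)
  mean(d, na.rm = TRUE)
}

#' Bone-to-muscle mass energy absorption coefficient ratio
#'
#' The kVp-dependent factor converting a marrow-site (soft tissue) dose
#' into a bone-surface dose: \code{-0.0618 * (2/3) * kVp + 6.9406}. The
#' negative-slope form is used; the slope acts on two-thirds of the tube
#' potential, an effective-energy surrogate.
#'
#' @param kVp tube potential; values outside the 40-150 diagnostic range
#'   draw a warning.
#' @return dimensionless ratio.
#' @examples
#' meacr(90)  # 3.2326
#' @export
meacr <- function(kVp) {
  if (any(!is.finite(kVp) | kVp <= 0)) stop("kVp must be > 0")
  if (any(kVp < 40 | kVp > 150))
    warning("kVp outside the 40-150 diagnostic range")
  -0.0618 * (2 / 3) * kVp + 6.9406
}

#' Organ dose from several dosimeters in one organ
#'
#' For a tissue measured by multiple dosimeters in a single subsite (e.g.
#' the brain), the organ dose is the arithmetic mean of the sites' doses,
#' times the subsite's fraction irradiated.
#'
#' @param siteTable a \linkS4class{SiteDoseTable}.
#' @param tissue a single-subsite \linkS4class{TissueEntry}.
#' @return dose in mGy.
#' @export
multiSiteOrganDose <- function(siteTable, tissue) {
  if (length(tissue@subsites) != 1)
    stop("multiSiteOrganDose expects a single-subsite tissue; use ",
         "distributedTissueDose for ", tissue@tissueName)
  ss <- tissue@subsites[[1]]
  ss$fraction * .sitesMean(siteTable, ss$sites, tissue@tissueName)
}

#' Dose to a distributed tissue
#'
#' For tissues distributed over several skeletal subsites (bone marrow,
#' bone surface before the attenuation-ratio coefficient) the dose is the
#' sum over subsites of subsite fraction times the mean dose of that
#' subsite's dosimeter sites.
#'
#' @inheritParams multiSiteOrganDose
#' @return dose in mGy.
#' @export
distributedTissueDose <- function(siteTable, tissue) {
  sum(vapply(tissue@subsites, function(ss)
    ss$fraction * .sitesMean(siteTable, ss$sites, tissue@tissueName),
    numeric(1)))
}

#' Bone-surface dose
#'
#' Distributed skeletal-subsite dose multiplied by the bone-to-muscle mass
#' energy absorption coefficient ratio at the protocol's tube potential.
#'
#' @inheritParams multiSiteOrganDose
#' @param kVp tube potential of the exposure.
#' @return dose in mGy.
#' @export
boneSurfaceDose <- function(siteTable, tissue, kVp) {
  meacr(kVp) * distributedTissueDose(siteTable, tissue)
}

#' Partial-body dose
#'
#' Scales a measured site dose by the fraction of the tissue assumed inside
#' the exposed field (skin, lymph nodes and muscle 5\%, esophagus 10\%).
#'
#' @param siteDose dose at the measuring site(s), mGy.
#' @param fractionIrradiated proportion in [0, 1].
#' @return dose in mGy.
#' @export
partialBodyDose <- function(siteDose, fractionIrradiated) {
  if (any(fractionIrradiated < 0 | fractionIrradiated > 1))
    stop("fractionIrradiated must lie in [0, 1]")
  siteDose * fractionIrradiated
}

#' Remainder-tissue dose
#'
#' Arithmetic mean over the remainder components' (fraction-weighted)
#' doses; the remainder set shares a single ICRP 103 weighting factor.
#'
#' @param componentDoses named numeric, one dose per remainder component.
#' @return dose in mGy.
#' @export
remainderDose <- function(componentDoses) {
  if (!length(componentDoses)) stop("empty remainder component set")
  mean(componentDoses)
}

.tissueDose <- function(siteTable, tissue, kVp) {
  vals <- vapply(tissue@subsites, function(ss)
    ss$fraction * .sitesMean(siteTable, ss$sites, tissue@tissueName),
    numeric(1))
  d <- if (tissue@aggregate == "weighted_sum") sum(vals) else mean(vals)
  if (tissue@applyMeacr) d <- meacr(kVp) * d
  d
}

#' Organ equivalent doses from site doses
#'
#' Applies the registry's aggregation rules to repeat-averaged site doses:
#' multi-dosimeter organs are averaged, distributed skeletal tissues are
#' fraction-weighted sums, the bone surface additionally carries the
#' bone-to-muscle coefficient, and partial-body tissues are scaled by their
#' fraction irradiated. Absorbed dose (mGy) is taken numerically equal to
#' equivalent dose (mSv): the photon radiation weighting factor is 1.
#'
#' @param siteTable a \linkS4class{SiteDoseTable}.
#' @param registry a \linkS4class{TissueRegistry}.
#' @param kVp tube potential (for the bone-surface coefficient).
#' @return an \linkS4class{OrganDoseTable}.
#' @export
organDoses <- function(siteTable, registry, kVp) {
  rows <- lapply(registry@tissues, function(t) {
    prov <- paste(vapply(t@subsites, function(ss)
      sprintf("%s(f=%g: sites %s)", ss$name, ss$fraction,
              paste(ss$sites, collapse = ",")), character(1)),
      collapse = " + ")
    if (t@applyMeacr) prov <- sprintf("meacr(%g) * [%s]", kVp, prov)
    data.frame(tissue = t@tissueName,
               H_mSv = .tissueDose(siteTable, t, kVp),
               category = t@category,
               provenance = prov)
  })
  new("OrganDoseTable", table = do.call(rbind, c(rows,
      list(make.row.names = FALSE))))
}

#' Organ-dose table as a data.frame
#' @param organTable an \linkS4class{OrganDoseTable}.
#' @return data.frame with tissue, H_mSv, category, provenance.
#' @export
organDoseTable <- function(organTable) organTable@table

setMethod("show", "OrganDoseTable", function(object) {
  cat("OrganDoseTable (H_T, mSv):\n")
  t <- object@table
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-22s %10.5f  [%s]\n", t$tissue[i], t$H_mSv[i],
                t$category[i]))
})

#' Effective dose from organ equivalent doses
#'
#' ICRP 103 weighted sum \eqn{E = \sum_T W_T H_T}: each weighted tissue
#' contributes its own factor, the remainder components contribute through
#' the mean of their doses times the shared remainder weight. The result is
#' reported in micro-sievert (1000 x the mSv sum); no intermediate rounding
#' is applied.
#'
#' @param organTable an \linkS4class{OrganDoseTable}.
#' @param registry a \linkS4class{TissueRegistry}.
#' @param methodLabel \code{"OSLD"} or \code{"MC"}.
#' @return an \linkS4class{EffectiveDoseResult}.
#' @export
effectiveDose <- function(organTable, registry, methodLabel = "OSLD") {
  tab <- organTable@table
  H <- stats::setNames(tab$H_mSv, tab$tissue)
  contrib <- c()
  for (t in registry@tissues) {
    if (t@category != "weighted_tissue") next
    if (!t@tissueName %in% names(H))
      stop("missing weighted tissue in organ-dose table: ", t@tissueName)
    contrib[t@tissueName] <- t@weightingFactor * H[[t@tissueName]]
  }
  comps <- tissueNames(registry, "remainder_component")
  if (length(comps)) {
    miss <- setdiff(comps, names(H))
    if (length(miss))
      stop("missing remainder component(s): ", paste(miss, collapse = ", "))
    contrib["remainder"] <- registry@remainderWeight *
      remainderDose(H[comps])
  }
  contribUSv <- 1000 * contrib
  new("EffectiveDoseResult",
      effectiveDoseUSv = sum(contribUSv),
      perTissueUSv = contribUSv,
      methodLabel = methodLabel)
}

#' Effective dose in micro-sievert
#' @param x an \linkS4class{EffectiveDoseResult}.
#' @return numeric scalar, uSv.
#' @export
effectiveDoseUSv <- function(x) x@effectiveDoseUSv

#' Per-tissue effective-dose contributions
#' @param x an \linkS4class{EffectiveDoseResult}.
#' @return named numeric, W_T * H_T in uSv.
#' @export
tissueContributionsUSv <- function(x) x@perTissueUSv

setMethod("show", "EffectiveDoseResult", function(object) {
  cat(sprintf("EffectiveDoseResult [%s]: E = %.1f uSv\n",
              object@methodLabel, object@effectiveDoseUSv))
  for (n in names(object@perTissueUSv))
    cat(sprintf("  %-22s %8.2f uSv\n", n, object@perTissueUSv[[n]]))
})

#' Run the full dosimetry arm
#'
#' Composes the measurement pipeline end to end: calibration (when readings
#' arrive as photon counts), repeat averaging, organ-dose aggregation and
#' the effective-dose sum. Deterministic for fixed inputs.
#'
#' @param readings data.frame with columns \code{site_id}, \code{run}, and
#'   \code{counts} and/or \code{dose_mGy}.
#' @param registry a \linkS4class{TissueRegistry}.
#' @param protocol an \linkS4class{ExposureProtocol} (supplies the kVp for
#'   the bone-surface coefficient).
#' @param curve \code{\link{calibrationCurve}} applied when only counts are
#'   present.
#' @param failOnMissing error (instead of warn) when registry sites lack
#'   readings.
#' @return an \linkS4class{EffectiveDoseResult} with attribute
#'   \code{"organDoses"} holding the intermediate
#'   \linkS4class{OrganDoseTable}.
#' @export
runOsldArm <- function(readings, registry, protocol,
                       curve = calibrationCurve(),
                       failOnMissing = FALSE) {
  if (!"dose_mGy" %in% names(readings)) {
    if (!"counts" %in% names(readings))
      stop("calibration stage: readings need counts or dose_mGy")
    readings$dose_mGy <- suppressWarnings(
      as.numeric(countsToDose(readings$counts, curve)))
  }
  sites <- averageRepeats(readings, registry, failOnMissing)
  od <- organDoses(sites, registry, protocol@tubeVoltageKvp)
  res <- effectiveDose(od, registry, methodLabel = "OSLD")
  attr(res, "organDoses") <- od
  res
}
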