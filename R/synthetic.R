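#' Define a ground-truth site-dose profile
#'
#' The generator's study conditions mirror the measurement campaign the
#' pipeline assumes: 22 dosimeter sites, two repeated exposures, and a
#' reader accuracy of about +/-2 percent interpreted as a 1-sigma relative
#' coefficient of variation.
#'
#' @param protocolRef protocol identifier.
#' @param siteDose named numeric, site id -> true dose (mGy).
#' @param readerCv relative 1-sigma reader noise, default 0.02.
#' @param nRepeats exposures per site, default 2.
#' @param seed integer RNG seed.
#' @return a \linkS4class{GroundTruthProfile}.
#' @export
groundTruthProfile <- function(protocolRef, siteDose, readerCv = 0.02,
                               nRepeats = 2L, seed = 1L) {
  new("GroundTruthProfile",
      protocolRef = as.character(protocolRef),
      siteDose = siteDose,
      readerCv = as.numeric(readerCv),
      nRepeats = as.integer(nRepeats),
      seed = as.integer(seed))
}

setMethod("show", "GroundTruthProfile", function(object) {
  cat(sprintf(
    "GroundTruthProfile '%s': %d sites, cv = %.3f, %d repeats, seed %d\n",
    object@protocolRef, length(object@siteDose), object@readerCv,
    object@nRepeats, object@seed))
})

#' Generate a synthetic dosimeter reading set
#'
#' For each site and repeat, a reading is drawn from a normal law centered
#' at the site's true dose with standard deviation \code{readerCv} times
#' the truth, truncated at zero (readings cannot be negative; at cv = 2
#' percent the truncation is inconsequential). Reproducible for a fixed
#' profile seed.
#'
#' @param profile a \linkS4class{GroundTruthProfile}.
#' @param nRepeats override of the profile's repeat count (e.g. for
#'   convergence checks).
#' @return data.frame with columns \code{site_id}, \code{run},
#'   \code{dose_mGy} in the pipeline's readings format.
#' @export
generateReadingSet <- function(profile, nRepeats = profile@nRepeats) {
  validObject(profile)
  siteIds <- as.integer(names(profile@siteDose))
  n <- length(siteIds)
  old <- .Random.seed__save()
  on.exit(.Random.seed__restore(old))
  set.seed(profile@seed)
  rows <- lapply(seq_len(nRepeats), function(run) {
    truth <- unname(profile@siteDose)
    draw <- stats::rnorm(n, mean = truth, sd = profile@readerCv * truth)
    data.frame(site_id = siteIds, run = run, dose_mGy = pmax(draw, 0))
  })
  do.call(rbind, rows)
}

.Random.seed__save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed__restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate synthetic DAP meter readings
#'
#' Draws \code{n} normal readings around a target mean and recomputes the
#' summary fields from the draws (so the object's mean/sd describe the
#' simulated sample, not the target).
#'
#' @param protocolRef protocol identifier.
#' @param mean,sd target mean (> 0) and standard deviation (>= 0),
#'   mGy cm^2.
#' @param n number of readings, default 2.
#' @param seed integer RNG seed.
#' @return a \linkS4class{DapMeasurement}.
#' @export
generateDapReadings <- function(protocolRef, mean, sd, n = 2L, seed = 1L) {
  if (!is.finite(mean) || mean <= 0) stop("mean DAP must be > 0")
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0")
  old <- .Random.seed__save()
  on.exit(.Random.seed__restore(old))
  set.seed(as.integer(seed))
  newDapMeasurement(protocolRef, pmax(stats::rnorm(n, mean, sd), 0))
}

#' Site-dose map of a phantom's dosimeter slots
#'
#' Which phantom organ hosts each dosimeter site of the bundled registry;
#' used to translate simulated organ doses into the site-dose truth a
#' dosimeter placed in that slot would read.
#'
#' @return named character: site id -> phantom organ group.
#' @export
siteHostOrgans <- function() {
  c(`1` = "calvaria", `2` = "calvaria",
    `3` = "brain", `4` = "brain", `5` = "brain", `6` = "brain",
    `7` = "eyes", `8` = "eyes",
    `9` = "brain", `10` = "brain",
    `11` = "extrathoracic_airways", `12` = "oral_mucosa",
    `13` = "skin",
    `14` = "parotid", `15` = "parotid",
    `16` = "esophagus",
    `17` = "submandibular", `18` = "submandibular",
    `19` = "cervical_spine", `20` = "skin",
    `21` = "thyroid", `22` = "thyroid")
}

#' Ground-truth profile from a Monte Carlo result
#'
#' Closes the loop between the two arms: evaluates the simulated organ
#' doses (scaled to a measured DAP) at each dosimeter's host organ,
#' producing the site-dose truth an idealized dosimeter campaign would
#' measure under that simulation.
#'
#' @param mcresult an \linkS4class{MCResult}.
#' @param dap a \linkS4class{DapMeasurement}.
#' @param readerCv,nRepeats,seed generator settings, see
#'   \code{\link{groundTruthProfile}}.
#' @param hosts site -> organ map, default \code{\link{siteHostOrgans}}.
#' @return a \linkS4class{GroundTruthProfile}.
#' @export
profileFromMc <- function(mcresult, dap, readerCv = 0.02, nRepeats = 2L,
                          seed = 1L, hosts = siteHostOrgans()) {
  doses <- mcresult@dosePerDap * dap@meanDap
  miss <- setdiff(unique(unname(hosts)), names(doses))
  if (length(miss))
    stop("MC result lacks organ(s) needed by the site map: ",
         paste(miss, collapse = ", "))
  siteDose <- stats::setNames(doses[unname(hosts)], names(hosts))
  groundTruthProfile(mcresult@protocolRef, siteDose, readerCv = readerCv,
                     nRepeats = nRepeats, seed = seed)
}

#' Write a reading set in the pipeline's file format
#' @param readings data.frame from \code{\link{generateReadingSet}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeReadings <- function(readings, path) {
  utils::write.csv(readings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
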