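# Compact photon interaction data for the transport stand-in.
#
# Two interaction channels are carried (photoelectric absorption and
# incoherent/Compton scattering); Rayleigh scattering and characteristic
# X-rays are deliberately omitted. The Compton channel is exact
# Klein-Nishina (free-electron): the closed-form total cross section times
# electrons per gram. The photoelectric channel is a single power law per
# material anchored at 10 keV to standard attenuation compilations - a
# compact parameterization adequate for 40-90 kVp beams, and exactly
# self-consistent with the transport kernel that samples from it.

.ELECTRON_RADIUS_CM <- 2.8179403262e-13
.ELECTRON_REST_KEV <- 510.99895
.AVOGADRO <- 6.02214076e23

# mean ratio Z/A (electrons per nucleon) and bulk density (g/cm^3)
.materials <- list(
  soft_tissue = list(zOverA = 0.5500, density = 1.06, peAt10keV = 4.70),
  bone        = list(zOverA = 0.5148, density = 1.40, peAt10keV = 27.5),
  air         = list(zOverA = 0.4992, density = 1.2e-3, peAt10keV = 4.54),
  aluminum    = list(zOverA = 0.4818, density = 2.699, peAt10keV = 25.4)
)
.PE_EXPONENT <- 3.1

.matPar <- function(material) {
  m <- .materials[[material]]
  if (is.null(m)) stop("unknown material: ", material)
  m
}

#' Klein-Nishina total cross section
#'
#' Closed-form total Compton cross section per free electron.
#'
#' @param energyKeV photon energy, keV (vectorized).
#' @return cross section in cm^2 per electron.
#' @export
kleinNishinaTotal <- function(energyKeV) {
  k <- energyKeV / .ELECTRON_REST_KEV
  re2 <- .ELECTRON_RADIUS_CM^2
  2 * pi * re2 * (
    (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
      log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2
  )
}

# mean fraction of the photon energy transferred to the electron in a
# Compton event (Klein-Nishina), by quadrature over the scattering angle
.knTransferFraction <- function(energyKeV) {
  vapply(energyKeV, function(E) {
    k <- E / .ELECTRON_REST_KEV
    ct <- seq(-1, 1, length.out = 2001)
    r <- 1 / (1 + k * (1 - ct))          # E'/E
    w <- r^2 * (1 / r + r - (1 - ct^2))  # dsigma/dcos(theta), unnormalized
    sum(w * (1 - r)) / sum(w)
  }, numeric(1))
}

#' Mass attenuation coefficient of the transport model
#'
#' @param material one of \code{"soft_tissue"}, \code{"bone"},
#'   \code{"air"}, \code{"aluminum"}.
#' @param energyKeV photon energy, keV (vectorized), 1-200 keV.
#' @param part \code{"total"}, \code{"photoelectric"} or \code{"compton"}.
#' @return mu/rho in cm^2/g.
#' @export
muRho <- function(material, energyKeV,
                  part = c("total", "photoelectric", "compton")) {
  part <- match.arg(part)
  m <- .matPar(material)
  pe <- m$peAt10keV * (energyKeV / 10)^(-.PE_EXPONENT)
  co <- kleinNishinaTotal(energyKeV) * .AVOGADRO * m$zOverA
  switch(part, total = pe + co, photoelectric = pe, compton = co)
}

#' Linear attenuation coefficient
#' @inheritParams muRho
#' @return mu in 1/cm at the material's bulk density.
#' @export
muLinear <- function(material, energyKeV, part = "total") {
  muRho(material, energyKeV, part) * .matPar(material)$density
}

# mass energy-transfer coefficient of air (collision kerma; charged
# particle equilibrium assumed, radiative losses neglected)
.muTrRhoAir <- function(energyKeV) {
  muRho("air", energyKeV, "photoelectric") +
    muRho("air", energyKeV, "compton") * .knTransferFraction(energyKeV)
}

# air kerma-area product of one photon crossing the scoring plane,
# mGy cm^2 (1 keV = 1.602176634e-16 J; Gy cm^2/g -> mGy cm^2 factor 1e6)
.dapPerPhoton <- function(energyKeV, muTr = .muTrRhoAir(energyKeV)) {
  energyKeV * 1.602176634e-16 * muTr * 1e6
}

# deposited energy (keV) in a mass (g) -> absorbed dose in mGy
.keVtoMGy <- function(energyKeV, massG) {
  energyKeV * 1.602176634e-10 / massG
}

#' Build a filtered bremsstrahlung spectrum
#'
#' Kramers-form photon fluence \code{(kVp - E)/E} on a 1-keV grid from
#' 5 keV to the endpoint, attenuated by the aluminium filtration and
#' renormalized to unit sum. Deterministic.
#'
#' @param kVp tube potential, 40-150.
#' @param filtrationMmAl aluminium filtration, mm, >= 0.
#' @return a \linkS4class{SpectrumModel}.
#' @examples
#' s <- buildSpectrum(90, 2.8)
#' spectrumMeanEnergy(s)
#' @export
buildSpectrum <- function(kVp, filtrationMmAl) {
  if (!is.finite(kVp) || kVp < 40 || kVp > 150)
    stop("kVp must lie in [40, 150]")
  if (!is.finite(filtrationMmAl) || filtrationMmAl < 0)
    stop("filtration must be >= 0")
  E <- seq(5, kVp, by = 1)
  raw <- (kVp - E) / E
  atten <- exp(-muLinear("aluminum", E) * filtrationMmAl / 10)
  fluence <- raw * atten
  fluence <- fluence / sum(fluence)
  new("SpectrumModel", kvp = kVp, filtrationMmAl = filtrationMmAl,
      energiesKeV = E, fluence = fluence)
}

#' Mean energy of a spectrum
#' @param spectrum a \linkS4class{SpectrumModel}.
#' @return fluence-weighted mean photon energy, keV.
#' @export
spectrumMeanEnergy <- function(spectrum) {
  sum(spectrum@energiesKeV * spectrum@fluence)
}

#' Sample photon energies from a spectrum
#' @param spectrum a \linkS4class{SpectrumModel}.
#' @param n number of samples.
#' @return numeric energies, keV.
#' @export
sampleSpectrum <- function(spectrum, n) {
  sample(spectrum@energiesKeV, n, replace = TRUE, prob = spectrum@fluence)
}

setMethod("show", "SpectrumModel", function(object) {
  cat(sprintf(
    "SpectrumModel: %g kVp, %g mmAl, %d bins, mean energy %.1f keV\n",
    object@kvp, object@filtrationMmAl, length(object@energiesKeV),
    spectrumMeanEnergy(object)))
})
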