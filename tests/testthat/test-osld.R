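reg <- loadTissueRegistry()
facial <- loadProtocols()[["CS9300 facial"]]

test_that("calibration converts counts linearly and flags range excursions", {
  curve <- calibrationCurve(slope = 0.001, intercept = 0)
  expect_equal(as.numeric(countsToDose(0, curve)), 0)
  expect_equal(as.numeric(countsToDose(1000, curve)), 1.0)
  expect_warning(d <- countsToDose(1e9, curve), "calibrated range")
  expect_true(attr(d, "outOfRange"))
  expect_error(countsToDose(-5, curve), ">= 0")
  expect_error(calibrationCurve(slope = 0), "> 0")
})

test_that("repeat averaging is the per-site arithmetic mean", {
  r <- data.frame(site_id = c(7, 7), run = 1:2, dose_mGy = c(2, 2))
  expect_equal(unname(averageRepeats(r)@doses), 2)
  r$dose_mGy <- c(1, 2)
  expect_equal(unname(averageRepeats(r)@doses), 1.5)
  one <- data.frame(site_id = 7, run = 1, dose_mGy = 3)
  expect_warning(st <- averageRepeats(one), "single repeat")
  expect_equal(unname(st@doses), 3)
  expect_match(st@flags, "single_repeat:7")
  # registry sites without readings are marked missing
  expect_warning(st <- averageRepeats(r, reg), "no readings")
  expect_length(st@missingSites, 21L)
  expect_error(averageRepeats(r, reg, failOnMissing = TRUE), "no readings")
})

test_that("multi-dosimeter organs average their sites", {
  brain <- reg@tissues[["brain"]]
  st <- uniformSiteTable(1.0, reg)
  expect_equal(multiSiteOrganDose(st, brain), 1.0)
  d <- stats::setNames(numeric(22), 1:22)
  d[as.character(c(3, 4, 5, 6, 9, 10))] <- c(0.5, 0.5, 1, 1, 1.5, 1.5)
  expect_equal(multiSiteOrganDose(siteTableFrom(d), brain), 1.0)
  eyes <- reg@tissues[["eyes"]]
  d[c("7", "8")] <- c(2, 4)
  expect_equal(multiSiteOrganDose(siteTableFrom(d), eyes), 3.0)
  expect_error(multiSiteOrganDose(st, reg@tissues[["bone_marrow"]]),
               "distributedTissueDose")
})

test_that("distributed tissues sum fraction-weighted subsite means", {
  bm <- reg@tissues[["bone_marrow"]]
  expect_equal(distributedTissueDose(uniformSiteTable(1, reg), bm), 0.123)
  expect_equal(distributedTissueDose(uniformSiteTable(0, reg), bm), 0)
  d <- stats::setNames(numeric(22), 1:22)
  d[c("14", "15")] <- 10  # mandible sites only
  expect_equal(distributedTissueDose(siteTableFrom(d), bm), 0.08)
  # all contributing sites missing is an error naming the tissue
  empty <- siteTableFrom(stats::setNames(1, "5"))
  expect_error(distributedTissueDose(empty, bm), "bone_marrow")
})

test_that("the bone-to-muscle coefficient follows its published form", {
  expect_equal(meacr(90), 3.2326, tolerance = 1e-12)
  expect_equal(meacr(80), 3.6446, tolerance = 1e-12)
  expect_true(meacr(90) < meacr(80))
  expect_error(meacr(0), "> 0")
  expect_warning(meacr(30), "diagnostic range")
})

test_that("bone-surface dose applies the coefficient to the subsite sum", {
  bs <- reg@tissues[["bone_surface"]]
  expect_equal(boneSurfaceDose(uniformSiteTable(0, reg), bs, 90), 0)
  expect_equal(boneSurfaceDose(uniformSiteTable(1, reg), bs, 90),
               0.165 * 3.2326, tolerance = 1e-12)
  expect_equal(boneSurfaceDose(uniformSiteTable(1, reg), bs, 80),
               0.165 * 3.6446, tolerance = 1e-12)
})

test_that("partial-body and remainder rules are products and means", {
  expect_equal(partialBodyDose(2.0, 0.05), 0.10)
  expect_equal(partialBodyDose(1.0, 0.10), 0.10)
  expect_equal(partialBodyDose(3.3, 1.0), 3.3)
  expect_error(partialBodyDose(1, 1.2), "0, 1")
  expect_equal(remainderDose(rep(1, 5)), 1)
  expect_equal(remainderDose(c(0, 0, 1, 1, 0.5)), 0.5)
  expect_equal(remainderDose(0.7), 0.7)
  expect_error(remainderDose(numeric()), "empty")
})

test_that("effective dose is the ICRP-weighted sum in micro-sievert", {
  H0 <- stats::setNames(numeric(length(reg@tissues)), names(reg@tissues))
  expect_equal(effectiveDoseUSv(effectiveDose(organTableFrom(H0, reg), reg)),
               0)
  H <- H0; H["thyroid"] <- 1
  expect_equal(effectiveDoseUSv(effectiveDose(organTableFrom(H, reg), reg)),
               40)
  H1 <- H0 + 1
  expect_equal(effectiveDoseUSv(effectiveDose(organTableFrom(H1, reg), reg)),
               360, tolerance = 1e-12)
  # a missing weighted tissue is named
  expect_error(effectiveDose(organTableFrom(H0[-2], reg), reg),
               names(reg@tissues)[2])
})

test_that("effective dose matches a brute-force oracle on random registries", {
  for (seed in 1:25) {
    r <- randomSmallRegistry(seed)
    H <- stats::setNames(stats::runif(length(r@tissues), 0, 5),
                         names(r@tissues))
    expect_equal(
      effectiveDoseUSv(effectiveDose(organTableFrom(H, r), r)),
      bruteForceEffectiveDoseUSv(H, r),
      tolerance = 1e-12)
  }
})

test_that("the measurement arm is linear, monotone and conservative", {
  truth <- fixtureSiteTruth(reg)
  readings <- generateReadingSet(
    groundTruthProfile("t", truth, readerCv = 0.02, seed = 11))
  base <- runOsldArm(readings, reg, facial)

  # linearity: scaling every reading scales E exactly
  sc <- readings; sc$dose_mGy <- sc$dose_mGy * 3.7
  expect_equal(effectiveDoseUSv(runOsldArm(sc, reg, facial)),
               3.7 * effectiveDoseUSv(base), tolerance = 1e-12)

  # monotonicity: raising any single site never lowers E
  for (s in c(1, 7, 14, 19, 21)) {
    up <- readings
    up$dose_mGy[up$site_id == s] <- up$dose_mGy[up$site_id == s] + 0.5
    expect_gte(effectiveDoseUSv(runOsldArm(up, reg, facial)),
               effectiveDoseUSv(base))
  }

  # breakdown conservation
  expect_equal(sum(tissueContributionsUSv(base)),
               effectiveDoseUSv(base), tolerance = 1e-9)

  # determinism: identical inputs give identical E bit for bit
  expect_identical(effectiveDoseUSv(runOsldArm(readings, reg, facial)),
                   effectiveDoseUSv(base))

  # zero readings everywhere give E = 0
  z <- readings; z$dose_mGy <- 0
  expect_equal(effectiveDoseUSv(runOsldArm(z, reg, facial)), 0)
})

test_that("the measurement arm recovers a known truth within noise", {
  truth <- fixtureSiteTruth(reg)
  trueE <- effectiveDoseUSv(effectiveDose(
    organDoses(siteTableFrom(truth), reg, 90), reg))
  cf <- siteCoefficients(reg, 90)
  se <- sqrt(sum(cf^2 * (0.02 * truth)^2 / 2))
  est <- effectiveDoseUSv(runOsldArm(
    generateReadingSet(groundTruthProfile("t", truth, seed = 4)),
    reg, facial))
  expect_lt(abs(est - trueE), 3 * se)
})

test_that("counts-based readings run through calibration end to end", {
  truth <- fixtureSiteTruth(reg)
  curve <- calibrationCurve(slope = 1e-3)
  readings <- generateReadingSet(
    groundTruthProfile("t", truth, readerCv = 0, seed = 1))
  counts <- readings
  counts$counts <- counts$dose_mGy / curve$slope
  counts$dose_mGy <- NULL
  expect_equal(
    effectiveDoseUSv(runOsldArm(counts, reg, facial, curve = curve)),
    effectiveDoseUSv(runOsldArm(readings, reg, facial)),
    tolerance = 1e-12)
})
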