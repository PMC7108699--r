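test_that("bundled protocols carry the published technique factors", {
  pr <- loadProtocols()
  expect_setequal(names(pr), c("CS9300 facial", "CS9300 dual jaw",
                               "RAYSCAN alpha+ large jaw",
                               "RAYSCAN alpha+ jaw"))
  fac <- pr[["CS9300 facial"]]
  expect_equal(fac@tubeVoltageKvp, 90)
  expect_equal(c(fac@fovWidthCm, fac@fovHeightCm), c(17, 13.5))
  expect_equal(fac@sourceToReferenceCm, 49.50)
  expect_equal(fac@filtrationMmAl, 2.8)
  jaw <- pr[["RAYSCAN alpha+ jaw"]]
  expect_equal(jaw@tubeVoltageKvp, 80)
  expect_equal(jaw@tubeCurrentMa, 12)
  expect_equal(c(jaw@fovWidthCm, jaw@fovHeightCm), c(10, 10))
  expect_equal(jaw@sourceToReferenceCm, 55.88)
  # merged-cell resolution: exposure time and beam height per mode
  expect_equal(vapply(pr, function(p) p@exposureTimeS, numeric(1)),
               c("CS9300 facial" = 20, "CS9300 dual jaw" = 12,
                 "RAYSCAN alpha+ large jaw" = 14, "RAYSCAN alpha+ jaw" = 14))
  expect_equal(unname(vapply(pr, function(p) p@beamHeightCm, numeric(1))),
               c(13.5, 10, 10, 10))
})

test_that("protocol validation rejects degenerate geometry", {
  fac <- loadProtocols()[["CS9300 facial"]]
  bad <- fac
  bad@rotationAngleDeg <- 0
  expect_error(validObject(bad), "rotationAngleDeg|positive")
  bad <- fac
  bad@beamWidthCm <- fac@fovWidthCm + 1
  expect_error(validObject(bad), "beam width")
  # missing field in a user config names the field
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(protocols = list(list(
    machine_name = "X", mode_name = "m", fov_width_cm = 10))), tmp)
  expect_error(loadProtocols(tmp), "fov_height_cm")
})

test_that("bundled tissue registry reproduces the published table", {
  reg <- loadTissueRegistry()
  expect_equal(nrow(registrySites(reg)), 22L)
  expect_false(anyDuplicated(registrySites(reg)$site_id) > 0)

  thyroid <- reg@tissues[["thyroid"]]
  expect_equal(sort(thyroid@subsites[[1]]$sites), c(21L, 22L))
  expect_equal(thyroid@subsites[[1]]$fraction, 1.0)
  expect_equal(thyroid@weightingFactor, 0.04)

  bm <- reg@tissues[["bone_marrow"]]
  expect_equal(vapply(bm@subsites, `[[`, numeric(1), "fraction"),
               c(0.008, 0.077, 0.038))
  expect_equal(fractionIrradiated(bm), 0.123, tolerance = 1e-12)

  bs <- reg@tissues[["bone_surface"]]
  expect_equal(fractionIrradiated(bs), 0.165, tolerance = 1e-12)

  expect_equal(reg@tissues[["esophagus"]]@subsites[[1]]$fraction, 0.10)
  expect_equal(reg@tissues[["skin"]]@subsites[[1]]$fraction, 0.05)
  expect_equal(sort(reg@tissues[["brain"]]@subsites[[1]]$sites),
               c(3L, 4L, 5L, 6L, 9L, 10L))
  expect_setequal(tissueNames(reg, "remainder_component"),
                  c("lymphatic_nodes", "muscle", "extrathoracic_airways",
                    "oral_mucosa", "eyes"))
  expect_equal(tissueWeightSum(reg), 0.36, tolerance = 1e-12)
})

test_that("registry validation rejects bad fractions and unknown sites", {
  reg <- loadTissueRegistry()
  bad <- reg
  bad@tissues[["skin"]]@subsites[[1]]$fraction <- 1.2
  expect_error(validObject(bad), "fraction")
  bad <- reg
  bad@tissues[["skin"]]@subsites[[1]]$sites <- 99L
  expect_error(validObject(bad), "unknown site")
})

test_that("bone-surface cervical-spine site mapping is selectable", {
  d19 <- loadTissueRegistry()
  d21 <- loadTissueRegistry(boneSurfaceCspineSite = 21)
  getCs <- function(reg) {
    bs <- reg@tissues[["bone_surface"]]
    for (ss in bs@subsites) if (ss$name == "cervical_spine") return(ss$sites)
  }
  expect_equal(getCs(d19), 19L)
  expect_equal(getCs(d21), 21L)
  expect_error(loadTissueRegistry(boneSurfaceCspineSite = 20), "19 or 21")
})

test_that("registry round-trips through YAML unchanged", {
  reg <- loadTissueRegistry()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeTissueRegistry(reg, tmp)
  reg2 <- loadTissueRegistry(tmp)
  expect_equal(registrySites(reg2), registrySites(reg))
  expect_equal(reg2@remainderWeight, reg@remainderWeight)
  expect_equal(names(reg2@tissues), names(reg@tissues))
  for (n in names(reg@tissues))
    expect_equal(reg2@tissues[[n]], reg@tissues[[n]])
})

test_that("DAP measurements keep summary and readings consistent", {
  d <- newDapMeasurement("p", c(214.9, 215.3))
  expect_equal(d@meanDap, 215.1)
  s <- dapFromSummary("p", 215.1, 0.4)
  expect_equal(s@meanDap, 215.1, tolerance = 1e-12)
  expect_equal(s@sdDap, 0.4, tolerance = 1e-12)
  expect_error(dapFromSummary("p", 0), "> 0")

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("protocol,reading_mGy_cm2", "a,90.7", "a,91.3", "b,100"),
             tmp)
  daps <- readDapMeasurements(tmp)
  expect_equal(daps[["a"]]@meanDap, 91.0)
  expect_equal(length(daps[["b"]]@readings), 1L)
})
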