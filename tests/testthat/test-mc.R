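facial <- loadProtocols()[["CS9300 facial"]]
phantom <- loadPhantom()

test_that("absorption-only slab transmission matches the closed form", {
  t <- 4
  slab <- slabPhantom(t)
  n <- 2e4
  beam <- pencilBeam(n, 60)
  set.seed(3)
  tr <- transportPhotons(slab, beam$pos, beam$dir, beam$E, beam$batch,
                         absorptionOnly = TRUE)
  p <- exp(-muLinear("soft_tissue", 60) * t)
  phat <- sum(tr$escapedCount) / n
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  # everything not transmitted was absorbed in the slab
  expect_equal(sum(tr$deposit) + sum(tr$escapedEnergy),
               sum(tr$emittedEnergy), tolerance = 1e-12)
})

test_that("a beam collimated away from the thyroid deposits nothing there", {
  narrow <- facial
  narrow@beamHeightCm <- 4   # z in [-2, 2] at the rotation center
  mc <- runRotationalSimulation(narrow, phantom, nPhotons = 5000, seed = 2,
                                absorptionOnly = TRUE)
  expect_equal(unname(dosePerDap(mc)["thyroid"]), 0)
  expect_gt(unname(dosePerDap(mc)["oral_mucosa"]), 0)
})

test_that("tallies are seed-deterministic and seed-consistent", {
  a <- runRotationalSimulation(facial, phantom, nPhotons = 5000, seed = 5)
  b <- runRotationalSimulation(facial, phantom, nPhotons = 5000, seed = 5)
  expect_identical(dosePerDap(a), dosePerDap(b))
  expect_identical(a@batchDose, b@batchDose)
  c <- runRotationalSimulation(facial, phantom, nPhotons = 5000, seed = 6)
  for (org in c("brain", "parotid")) {
    se <- sqrt(a@stderrPerDap[org]^2 + c@stderrPerDap[org]^2)
    expect_lt(abs(dosePerDap(a)[org] - dosePerDap(c)[org]), 3 * se)
  }
})

test_that("energy is conserved batch by batch", {
  mc <- runRotationalSimulation(facial, phantom, nPhotons = 5000, seed = 9)
  expect_lt(mc@energyBalance[["maxBatchRelImbalance"]], 1e-6)
  eb <- mc@energyBalance
  expect_equal(eb[["deposited"]] + eb[["escaped"]], eb[["emitted"]],
               tolerance = 1e-9)
})

test_that("bilateral organs receive equal doses under a full orbit", {
  mc <- runRotationalSimulation(facial, phantom, nPhotons = 3e4, seed = 12)
  ed <- attr(mc, "entryDose")
  for (pair in list(c("eye_right", "eye_left"),
                    c("parotid_right", "parotid_left"))) {
    a <- ed[ed$id == pair[1], ]
    b <- ed[ed$id == pair[2], ]
    se <- sqrt(a$stderrPerDap^2 + b$stderrPerDap^2)
    expect_lt(abs(a$dosePerDap - b$dosePerDap), 3 * se)
  }
})

test_that("DAP scaling is exactly linear and rejects degenerate input", {
  mc <- runRotationalSimulation(facial, phantom, nPhotons = 2000, seed = 1)
  d1 <- dapFromSummary("CS9300 facial", 215.1, 0.4)
  d2 <- dapFromSummary("CS9300 facial", 430.2, 0.4)
  expect_identical(2 * scaledOrganDoses(mc, d1),
                   scaledOrganDoses(mc, d2))
  expect_equal(scaledOrganDoses(mc, d1),
               dosePerDap(mc) * 215.1, tolerance = 1e-12)
  zero <- new("DapMeasurement", protocolRef = "z", readings = c(0, 0),
              meanDap = 0, sdDap = 0)
  expect_error(scaleToMeasuredDap(mc, zero, kVp = 90), "> 0")
})

test_that("per-DAP doses are stable in n and errors shrink as 1/sqrt(n)", {
  ns <- c(1e4, 4e4, 16e4)
  runs <- lapply(seq_along(ns), function(i)
    runRotationalSimulation(facial, phantom, nPhotons = ns[i],
                            seed = 20 + i, nBatches = 20))
  organs <- names(dosePerDap(runs[[1]]))
  organs <- setdiff(organs, "lymphatic_nodes")  # smallest-mass tally
  # n-invariance of the per-DAP estimate (3 sigma per organ pair)
  for (org in c("brain", "mandible", "oral_mucosa")) {
    se <- sqrt(runs[[1]]@stderrPerDap[org]^2 + runs[[3]]@stderrPerDap[org]^2)
    expect_lt(abs(dosePerDap(runs[[1]])[org] - dosePerDap(runs[[3]])[org]),
              3 * se)
  }
  # convergence rate: median over organs of the stderr ratio at 4x photons
  r12 <- stats::median(runs[[2]]@stderrPerDap[organs] /
                         runs[[1]]@stderrPerDap[organs])
  r23 <- stats::median(runs[[3]]@stderrPerDap[organs] /
                         runs[[2]]@stderrPerDap[organs])
  expect_lt(abs(r12 - 0.5), 0.1)
  expect_lt(abs(r23 - 0.5), 0.1)
})

test_that("simulation guards its preconditions", {
  expect_error(runRotationalSimulation(facial, phantom, nPhotons = 100,
                                       seed = 1), ">= 1000")
  expect_error(runRotationalSimulation(facial, phantom, nPhotons = 5000),
               "seed")
  inside <- facial
  inside@sourceToReferenceCm <- 5  # source would sit inside the head
  expect_error(runRotationalSimulation(inside, phantom, nPhotons = 1000,
                                       seed = 1), "inside an organ")
})

test_that("the simulation arm produces a complete effective-dose result", {
  dap <- dapFromSummary("CS9300 facial", 215.1, 0.4)
  reg <- loadTissueRegistry()
  res <- runMcArm(facial, dap, reg, phantom, nPhotons = 5000, seed = 3)
  expect_s4_class(res, "EffectiveDoseResult")
  expect_identical(res@methodLabel, "MC")
  expect_gt(effectiveDoseUSv(res), 0)
  od <- organDoseTable(attr(res, "organDoses"))
  expect_setequal(od$tissue, names(reg@tissues))
  expect_true(all(od$H_mSv >= 0))
})
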