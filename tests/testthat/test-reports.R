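reg <- loadTissueRegistry()

writeFixtureReadings <- function(dir, seed = 6) {
  prof <- groundTruthProfile("CS9300 facial", fixtureSiteTruth(reg),
                             seed = seed)
  writeSyntheticReadings(prof, dir)[["readings"]]
}

stripTimestamp <- function(path) {
  grep("timestamp", readLines(path), invert = TRUE, value = TRUE)
}

test_that("the measurement-arm report writes organ doses and a manifest", {
  dir <- withr::local_tempdir()
  readings <- writeFixtureReadings(dir)
  paths <- runOsldReport(readings, "CS9300 facial", file.path(dir, "out"))
  expect_true(all(file.exists(paths)))
  doc <- jsonlite::read_json(paths[["effective_dose"]],
                             simplifyVector = TRUE)
  expect_identical(doc$method, "OSLD")
  expect_gt(doc$effective_dose_uSv, 0)
  expect_identical(doc$manifest$command, "osld")
  expect_true(length(doc$manifest$input_digests) >= 1)
  od <- utils::read.csv(paths[["organ_doses"]])
  expect_equal(od$tissue, names(reg@tissues))

  # determinism modulo the manifest timestamp
  p2 <- runOsldReport(readings, "CS9300 facial", file.path(dir, "out2"))
  expect_identical(stripTimestamp(paths[["effective_dose"]]),
                   stripTimestamp(p2[["effective_dose"]]))

  expect_error(runOsldReport(file.path(dir, "nope.csv"), "CS9300 facial",
                             dir), "nope.csv")
  expect_error(runOsldReport(readings, "no such mode", dir),
               "unknown protocol")
})

test_that("the simulation-arm report is seed-reproducible", {
  dir <- withr::local_tempdir()
  p1 <- runMcReport("CS9300 facial", file.path(dir, "a"), nPhotons = 2000,
                    seed = 9)
  p2 <- runMcReport("CS9300 facial", file.path(dir, "b"), nPhotons = 2000,
                    seed = 9)
  expect_identical(stripTimestamp(p1[["effective_dose"]]),
                   stripTimestamp(p2[["effective_dose"]]))
  expect_error(runMcReport("CS9300 facial", dir, nPhotons = 2000), "seed")

  # a zero-mean DAP file is rejected
  dapFile <- file.path(dir, "dap.csv")
  writeLines(c("protocol,reading_mGy_cm2", "CS9300 facial,0",
               "CS9300 facial,0"), dapFile)
  expect_error(runMcReport("CS9300 facial", dir, dapPath = dapFile,
                           nPhotons = 2000, seed = 1), "must be > 0")

  # two seeds agree within combined simulation uncertainty
  d1 <- jsonlite::read_json(p1[["effective_dose"]],
                            simplifyVector = TRUE)$effective_dose_uSv
  p3 <- runMcReport("CS9300 facial", file.path(dir, "c"), nPhotons = 2000,
                    seed = 10)
  d3 <- jsonlite::read_json(p3[["effective_dose"]],
                            simplifyVector = TRUE)$effective_dose_uSv
  expect_lt(abs(d1 - d3) / ((d1 + d3) / 2), 0.5)
})

test_that("the comparison command pairs reports from files", {
  dir <- withr::local_tempdir()
  writeFake <- function(protocol, method, E) {
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9]", "_", protocol), "_",
                               method, ".json"))
    jsonlite::write_json(list(method = method, protocol = protocol,
                              effective_dose_uSv = E,
                              per_tissue_uSv = list(total = E)),
                         p, auto_unbox = TRUE, digits = NA)
    p
  }
  osldE <- c("CS9300 facial" = 181.4, "CS9300 dual jaw" = 90.7,
             "RAYSCAN alpha+ large jaw" = 228.5,
             "RAYSCAN alpha+ jaw" = 213.8)
  mcE <- c("CS9300 facial" = 160.9, "CS9300 dual jaw" = 94.4,
           "RAYSCAN alpha+ large jaw" = 198.0, "RAYSCAN alpha+ jaw" = 195.2)
  fs <- c(mapply(writeFake, names(osldE), "OSLD", osldE),
          mapply(writeFake, names(mcE), "MC", mcE))
  rep <- runComparisonReport(fs, file.path(dir, "cmp"))
  expect_equal(reportRows(rep)$percent_difference, c(12.0, 4.0, 14.3, 9.1))
  csv <- utils::read.csv(file.path(dir, "cmp", "comparison.csv"))
  expect_named(csv, c("protocol", "E_OSLD_uSv", "E_MC_uSv",
                      "percent_difference"))
  # argument order does not matter
  rep2 <- runComparisonReport(rev(fs), file.path(dir, "cmp2"))
  expect_equal(sort(reportRows(rep2)$percent_difference),
               sort(reportRows(rep)$percent_difference))
  # both methods are required
  expect_error(runComparisonReport(fs[1:4], file.path(dir, "cmp3")),
               "both methods")
})
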