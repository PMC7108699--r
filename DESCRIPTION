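Package: cbctdose
Title: Dual-Method Patient Dose Assessment for Dental Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses patient dose from dental cone-beam computed tomography
    (CBCT) by two independent routes and compares them. The dosimetry arm
    converts calibrated optically stimulated luminescence dosimeter (OSLD)
    readings into organ equivalent doses and the ICRP 103 effective dose
    using a fraction-irradiated aggregation scheme for head-and-neck
    tissues. The simulation arm performs Monte Carlo photon transport of a
    rotating cone beam around a stylized head-and-neck phantom, tallying
    organ doses per unit dose-area product (DAP) and scaling them by
    measured DAP values. A comparison stage computes the symmetric percent
    difference between the two methods' effective doses per examination
    mode. Includes a synthetic-data generator emulating the structure of a
    dosimeter measurement campaign for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
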