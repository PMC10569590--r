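Package: diatomdose
Title: Micro- and Nanodosimetry of Alpha Exposure for Microorganisms in
    Radioactive Mineral Springs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale coupled micro- and nanodosimetric assessment of the
    external alpha-particle exposure of spherical microorganisms (benthic
    diatoms) living in naturally radioactive mineral springs. Converts
    measured Rn-222 (water) and Ra-226 (sediment) activity concentrations
    into absorbed dose rates via a continuous-slowing-down, straight-track
    transport model through concentric sphere geometries (nucleus,
    microorganism, optional silica frustule, porosity-mixed environment),
    records phase spaces at the microorganism and nucleus boundaries,
    generates nanoscale energy-transfer points along residual tracks,
    scores specific-energy spectra in randomly placed nucleosome-sized
    cylinders, and predicts clustered single- and double-strand DNA break
    yields with a DBSCAN-based damage scorer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
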