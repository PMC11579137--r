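Package: pddrecon
Title: Photon Energy Spectrum Estimation by Percentage Depth Dose Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates megavoltage photon energy spectra as functions of radial
    distance from the beam central axis by constrained unfolding of percentage
    depth dose (PDD) curves against a monoenergetic depth dose (MDD) basis.
    Spectra are discrete relative fluences on variable-width energy bins,
    obtained by minimizing the variance of the relative difference between
    reconstructed and measured PDDs along divergent fan lines, subject to
    unimodality and off-axis softening constraints. Includes fan line geometry
    for cylindrical MDD grids, off-axis ratio computation with fitted radial
    fluence ratios, a synthetic beam generator (analytic MDD basis, ground
    truth spectrum families, noisy scans) for end-to-end validation, and
    CSV readers and writers for the tabular interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    quadprog,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
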