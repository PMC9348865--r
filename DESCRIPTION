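Package: refdesign
Title: Fisher Information Optimal Experimental Design for Neutron Reflectometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates time-of-flight neutron reflectometry experiments with
    Poisson counting statistics and uses the Fisher information (FI) of the
    expected counts to optimize experimental design. Provides an exact slab-model
    (Abeles matrix) reflectivity kernel with Nevot-Croce roughness, hydration
    mixing, resolution smearing and polarized (non-spin-flip) channels; a
    wavelength-resolved instrument model with constant-footprint angle scaling;
    the Poisson-count FI matrix over model parameters with importance scaling,
    eigen-analysis and Cramer-Rao uncertainty bounds; parameterized sample
    models for supported lipid bilayers (with solvent contrast variation and
    underlayers), degrading lipid monolayers (area-per-molecule kinetics) and
    magnetic thin-film stacks; grid scans and differential-evolution search of
    measurement conditions (contrasts, angles, time splits, underlayers)
    maximizing the minimum eigenvalue of the importance-scaled FI; and
    likelihood-based validation including model-discrimination scans versus
    counting time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
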