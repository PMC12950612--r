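Package: lysedpa
Title: Dual-Wavelength Photoacoustic Modeling and Quantification of Lysed Blood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modeling of photoacoustic measurements on
    partially lysed blood samples. Converts a blood state (hematocrit, lysis
    level, oxygen saturation, suspending medium) into intracellular and bulk
    optical properties, computes single-cell scattering with a discrete dipole
    approximation solver on a voxelized biconcave red-cell geometry, transports
    photons through a voxel grid by Monte Carlo to obtain fluence maps,
    propagates the induced initial pressure to a focused transducer with a
    k-space spectral solver, and inverts dual-wavelength peak-to-peak
    amplitudes into total hemoglobin, oxygen saturation, hematocrit and lysis
    level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
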