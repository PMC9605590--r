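Package: ocraman
Title: Optical-Clearing Kinetics from Confocal Raman Depth Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs depth- and time-resolved optical clearing agent
    concentrations in collagenous tissue from confocal Raman
    micro-spectroscopy band intensities. Provides spectral preprocessing
    (iterative polynomial baseline subtraction, Savitzky-Golay smoothing,
    PCA denoising), a linear glycerol calibration, an optical-clearing
    efficiency correction that removes the signal inflation caused by
    clearing of overlying layers, nonlinear fitting of the semi-infinite
    erfc solution of Fick's second law to recover diffusion coefficients
    and saturation concentrations, and a ten-Gaussian deconvolution of the
    high-wavenumber OH-stretch region into bound and unbound water
    mobility states. A fully parameterized synthetic-experiment generator
    makes every pipeline stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
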