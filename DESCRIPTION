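Package: sofisim
Title: Simulation and Analysis of Super-Resolution Optical Fluctuation Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates image sequences of stochastically blinking fluorophores
    under a parameterized microscope and camera model (pixel-integrated
    Gaussian point-spread function, two-state continuous-time Markov
    photoswitching with photobleaching, Poisson shot noise, Gamma-distributed
    electron-multiplying gain and Gaussian dark noise), and analyzes them with
    n-th order cross-cumulant SOFI including the balanced-SOFI
    post-processing chain (flattening, Richardson-Lucy deconvolution,
    brightness linearization) as well as a basic single-molecule localization
    (STORM) pipeline. Quality metrics (signal-to-noise ratio,
    signal-to-background ratio, on-time ratio, full width at half maximum)
    allow matching simulations to experimental acquisitions before imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    minpack.lm,
    tiff,
    yaml,
    withr,
    EBImage,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
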