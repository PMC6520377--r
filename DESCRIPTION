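Package: slicephys
Title: Electromechanical Phenotyping of Cultured Myocardial Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification toolkit for living myocardial-slice preparations
    cultured under defined mechanical preload and electrical stimulation.
    Implements laser-diffraction sarcomere-length estimation and the
    percent-stretch calibration line, multielectrode-array activation mapping
    with anisotropic conduction-velocity estimation, force and calcium
    transient feature extraction, isoproterenol dose-escalation analysis
    (aftercontraction rates, sustained-tachyarrhythmia threshold, linear
    arrhythmogenicity score, four-parameter logistic EC50), and confocal image
    metrics (percent positive area, t-tubule density and spectral regularity,
    stain heterogeneity, cardiomyocyte morphometrics).  Every input the
    pipeline consumes can be simulated with known ground truth, so all stages
    are testable without laboratory recordings.
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
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
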