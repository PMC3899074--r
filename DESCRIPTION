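Package: susi
Title: Spectral Ultrasound Imaging of Engineered Tissue Constructs
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative high-frequency ultrasound characterization of
    engineered tissue constructs and bead phantoms from raw backscattered
    radiofrequency (RF) data. Implements bulk acoustic property estimation
    (construct thickness, speed of sound, frequency-dependent attenuation,
    volume from serial B-mode contours), calibrated power-spectrum analysis
    with spectral slope and mid-band fit regression, attenuation correction,
    and Lizzi-framework inversion to effective scatterer radius, acoustic
    concentration, number concentration, relative acoustic impedance, and
    deposited calcium mass. Includes a point-scatterer RF backscatter
    simulator with Gaussian form factor so every estimator can be validated
    by parameter recovery, parametric color-map overlays on B-mode images,
    a documented on-disk RF container, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
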