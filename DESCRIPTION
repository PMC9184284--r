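Package: nanoscatter
Title: Simulation and Analysis of Nanofluidic Scattering Microscopy Kymographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free single-molecule characterization in
    nanofluidic channels. Provides a physics-based forward simulator of
    kymographs of Brownian point scatterers in a nanochannel (interference
    contrast, point-spread blur, motion blur, pixelation, camera noise) and
    the complete inverse pipeline: background estimation and normalization,
    per-frame dip detection and subpixel localization, trajectory linking
    with transient-binding exclusion, covariance-based diffusivity
    estimation, conversion of integrated optical contrast to molecular
    weight and of confined diffusivity to hydrodynamic radius via a
    hindrance-corrected Stokes-Einstein relation, and population statistics
    (weighted histograms, Gaussian fits, FWHM resolution).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    tiff,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
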