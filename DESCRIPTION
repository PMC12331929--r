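Package: pam3p
Title: Forward Simulation and Trace Processing for Multiphoton Photoacoustic Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale digital twin of a label-free multiphoton photoacoustic
    microscope for NAD(P)H imaging. Provides synthetic specimen phantoms (gel
    cylinders, cell fields, organoid spheres, hair fiducials), a three-photon
    excitation model (focal field, depth attenuation, absorbed heat and
    fluorescence), an acoustic signal chain (initial pressure, far-field
    propagation, frequency-dependent tissue attenuation, transducer and
    amplifier response), continuous-wavelet-transform trace analysis and
    band-limited denoising, time-gated A-scan image reconstruction with
    Richardson-Lucy deconvolution, and drivers for the standard in-silico
    calibration experiments (concentration series, power series, depth sweeps,
    dual-channel depth comparison, acquisition timing and depth budgets).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    tiff
Config/testthat/edition: 3
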