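Package: capnoflow
Title: Dynamic Modelling and Kalman Inversion of Transcutaneous CO2 Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and real-time inversion of carbon dioxide
    transport through the skin for an open-chamber capnometry wristband. The
    transport of CO2 from blood-irrigated tissue through the stratum corneum
    into the measurement and collection cells of the device is modelled by a
    one-dimensional convection-diffusion equation with Henry-law interface
    conditions, discretized by finite differences in space and an implicit
    Euler scheme in time. A Kalman filter on an AR(1)-augmented state-space
    model estimates the blood CO2 concentration (and hence partial pressure)
    from the non-dispersive infrared (NDIR) measurement sequence. The package
    also provides the NDIR dual-wavelength calibration model, a suite of
    capnometry performance metrics (settled phase means, aligned RMSE, global
    SNR, rise time, cross-correlation delays), and scenario runners for step,
    air-flow-sweep and clinical-chronogram experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
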