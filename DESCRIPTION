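Package: tfusnav
Title: Optically Navigated Transcranial Focused Ultrasound Simulation and
    Targeting-Error Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subject-specific planning tools for optically tracked transcranial
    focused ultrasound (tFUS). Builds acoustic simulation grids from a
    neuronavigation transform hierarchy (image, physical, tracker, ultrasound
    and simulation frames), performs paired-point fiducial registration with
    automatic correspondence and fiducial registration error, rasterizes
    spherical-cap (bowl) transducer sources, maps CT Hounsfield units to
    acoustic skull properties through a linear porosity model, simulates the
    steady-state transcranial pressure field with a one-way split-step
    angular-spectrum solver validated against a Rayleigh-integral oracle,
    localizes the simulated focus, decomposes targeting errors into axial and
    lateral components, and re-targets the simulation with a measured-focus
    distance-vector correction. A synthetic-scene generator produces
    ground-truth-known phantom and skull-cap datasets so the whole pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
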