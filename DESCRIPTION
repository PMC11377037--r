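Package: chromv1
Title: Chromatic Receptive-Field Analysis of Mouse Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for chromatic (UV/green) center-surround
    receptive fields in mouse primary visual cortex. Generates balanced
    binary color-noise, sparse-noise and two-channel noise-scene stimuli,
    simulates ground-truth neuron populations through a rectified
    linear-nonlinear model, estimates event-triggered averages with a
    variance-ratio quality criterion and sparse-PCA denoising, maps neurons
    into a luminance/color contrast space, decodes stimulus luminance and
    color with a cross-validated RBF kernel classifier converted to mutual
    information, clusters response types with a Gaussian mixture model and
    a cortical distribution index, computes spatial receptive-field overlap
    from sparse noise, and simulates per-type detectability of dark objects
    in the UV channel of naturalistic scenes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
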