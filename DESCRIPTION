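Package: vibsolv
Title: Vibrational Solvatochromism and Frequency-Fluctuation Analysis from
    Molecular Dynamics Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for characterizing molecular environments through the
    instantaneous vibrational frequency of a probe mode (the amide I C=O
    stretch of N-methylacetamide as the reference case). Reads MD trajectory
    frames (extended XYZ with a YAML topology sidecar), carves solute-centred
    solvation-shell clusters with periodic-image correction and a
    frozen-environment mask, obtains per-snapshot normal-mode frequencies
    either by preparing/parsing external GFN2-xTB jobs or through a built-in
    deterministic electrostatic-map engine, and computes the three vibrational
    observables used to fingerprint an environment: the central frequency
    (solvatochromism), the frequency-fluctuation correlation function with
    Kubo bi-exponential fits (correlation times), and the fluctuation
    amplitude from Gaussian analysis of the frequency distribution. Includes
    forward Kubo lineshape synthesis (g(t), linear absorption band, FWHM),
    exact-discretization Ornstein-Uhlenbeck trajectory generators for
    validation, and regression reports of computed versus experimental
    observables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
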