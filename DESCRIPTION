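Package: hjmap
Title: Mapping Single-Base DNA Differences from Holliday Junction Nanomechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates single-base differences between two homologous DNA
    sequences from magnetic-tweezers rotation-extension measurements of a
    palindromic Holliday-junction construct. Sequence mismatches act as a
    ratchet that blocks junction branch migration; each blockage produces a
    rescaled, shifted copy of the plectoneme formation curve whose rotation
    offset maps, through the DNA helical repeat, to a base position. The
    package provides a forward simulator of such traces (migration line,
    plectoneme curve-segments, fast/slow go-and-return protocol, rotation
    skids, measurement noise), estimation of the tether parameters and of a
    mirror-symmetric segmented cubic-spline reference curve, weighted
    Levenberg-Marquardt fitting of blockage curve-segments with a
    residual-resampling bootstrap, matching of fitted blockage rotations to
    sequence-predicted positions, and Arrhenius analysis of blockage-bypass
    kinetics with a linear twist-elasticity torque estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    splines,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
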