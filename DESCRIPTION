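Package: connharm
Title: Connectome-Harmonic Decomposition of Whole-Brain Activity
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compute harmonic brain states as eigenmodes of the symmetric
    graph Laplacian of a vertex-level structural connectome, project
    vertex-mapped functional time series onto that basis, and analyse the
    resulting spectral coefficients: binned energy spectra, repertoire
    distributions, cross-frequency co-activation, power-law (criticality)
    fits with logarithmic binning, and paired condition comparisons with
    permutation testing and Bonferroni correction. Includes generators for
    synthetic icosphere-based connectomes and functional series with known
    ground truth, and a small pipeline/CLI for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
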