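Package: hicsig
Title: Significant Chromatin Interaction Calling from Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("hicsig", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ingests Hi-C contact maps produced by common upstream
    pipelines (HiCUP-style paired reads plus a restriction digest,
    HiC-Pro sparse matrix plus bed, and a minimal HOMER-style table),
    preprocesses them (rebinning, diagonal removal, cis/trans splits),
    and identifies statistically significant chromatin interactions
    under three background models: a coverage-product cumulative
    binomial null (GOTHiC), Poisson-regression normalization with
    effective-length, GC and mappability covariates (HiCNorm), and a
    distance-decay spline null with equal-occupancy binning and
    two-phase refinement (Fit-Hi-C).  Includes a synthetic-data
    generator matched to each model's own generative assumptions,
    static arc-diagram and heatmap rendering, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    graphics,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
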