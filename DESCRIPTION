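Package: resectr
Title: Single-Cell Measurement of DNA Double-Strand Break End Resection Rates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies long-range 5' end resection at site-specific DNA
    double-strand breaks in live fission yeast from two-channel time-lapse
    fluorescence stacks. A LacO/LacI-GFP array downstream of an HO cut site
    loses its focus as resection converts the array to single-stranded DNA,
    while a Rad52-mCherry focus marks resection onset; the interval between
    Rad52 focus appearance and complete GFP focus loss, divided into the
    known cut-site-to-array distance, gives a per-cell resection rate in
    kb/hr. The package provides cylinder-aperture focus photometry with
    shell background subtraction on full Z-stacks, automated event calling
    with censoring, photobleaching controls, genotype rate tables with
    Bonferroni-corrected pairwise tests, fluorescence-to-molecule-count
    calibration, an orthogonal ApoI-protection qPCR resection analysis, and
    a ground-truth-annotated synthetic movie generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
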