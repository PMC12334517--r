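Package: secmFluor
Title: Zone-Based Synchronous Fluorescence and miRNA Analysis of Spent Embryo Culture Medium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive assessment of embryo implantation potential from spent
    embryo culture medium (SECM). Processes 3D synchronous fluorescence maps
    (excitation 200-400 nm, wavelength offset 30-170 nm) into fluorescence
    profiles and additive (PBS + PBS:DMSO) profiles, integrates them over the
    Z1-Z5 spectral zones, subtracts the free-medium background, and decomposes
    Z3-anchored total fluorescence into human serum albumin, residual
    metabolites and an embryo metabolic activity statistic. Includes the
    companion statistical toolkit (ROUT outlier removal, Shapiro-Wilk gated
    Mann-Whitney comparisons, percent-difference reporting), medium-normalized
    qPCR relative expression for SECM miRNAs, and a synthetic cohort generator
    emulating the band structure of the real spectra so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'decomposition.R'
    'io.R'
    'utils.R'
    'stats.R'
    'mirna.R'
    'synthetic.R'
    'zones.R'
    'pipeline.R'
    'profiling.R'
    'secmFluor-package.R'
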