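Package: biofilmetry
Title: Quantitative Phenotyping of Epibiotic Co-Culture Biofilms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative phenotyping of bacterial co-culture
    experiments built around host-epibiont biofilm systems. Computes
    COMSTAT-style morphometrics (maximal thickness, biovolume, compactness,
    roughness variance, continuity ratio) from confocal Z-stacks with
    documented Otsu segmentation; estimates generation times from
    background-corrected absorbance growth curves; derives relative gene
    expression from qPCR Ct tables against a 16S reference; quantifies the
    AI-2 precursor DPD from GC-MS extracted-ion peak areas with deuterated
    internal-standard and OD600 normalization against an external
    calibration curve; and reproduces the group-comparison statistics
    (two-tailed t-tests, one-way ANOVA, asterisk annotation). A synthetic
    data generator provides ground truth for every stage so the pipeline is
    testable end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    tiff,
    jsonlite,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
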