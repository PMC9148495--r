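Package: mlidscan
Title: Multi-Locus Imprinting Disturbance Calling and Maternal-Effect
    Variant Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Diagnoses multi-locus imprinting disturbances (MLID) from
    imprinted-DMR methylation beta values: region-average methylation,
    control reference statistics, 3-SD hypo/hypermethylation calls,
    mosaic-fraction estimation and the diagnostic-plus-one MLID rule.
    Companion analyses cover cohort episignature summaries, uniparental
    disomy segmentation from pedigree SNP genotypes with parental-origin
    inference from imprinted methylation, maternal-effect SCMC variant
    frequency tiering, segregation and phasing, and Beckwith-Wiedemann
    clinical scoring. Includes a synthetic-data generator so the whole
    pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
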