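Package: radspectra
Title: Germline Variant Spectrum Comparison for Radiation-Exposed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream comparison of germline variants between a chronically
    radiation-exposed cohort and a matched control cohort: two-caller consensus
    filtering with GATK-style hard filters, population-frequency removal of
    common polymorphisms, pyrimidine-normalized substitution-spectrum and
    CpG/5-mer sequence-context analysis, group-unique variant detection,
    protein-affecting and pathogenic mutation triage (REVEL, ALoFT),
    nonparametric group statistics (exact Mann-Whitney, Benjamini-Hochberg
    FDR, PCA), and indoor/outdoor gamma dosimetry arithmetic. Includes a fully
    synthetic two-group cohort generator with plantable CpG C>T enrichment so
    every analysis stage is testable with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
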