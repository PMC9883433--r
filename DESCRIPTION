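Package: rdvload
Title: Rare Deleterious Variant Burden and Load Analysis for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control analysis of germline rare deleterious variants (RDVs)
    from multi-sample VCF genotypes: genotype- and site-level quality control,
    kinship-based relative pruning and PCA ancestry gating, classification of
    variants as rare and deleterious from ClinVar annotations (including
    propagation of pathogenic loss-of-function status to truncating variants
    lying 5' in the coding sequence), carrier-collapsing burden tests at gene
    and gene-set level with Firth-penalized logistic regression, per-individual
    RDV load grouping, and associations of load with age of onset, tumor
    mutational burden, tumor immune-cell fractions and survival. Includes a
    seeded synthetic-cohort generator so the full pipeline can be exercised
    and calibrated without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
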