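Package: SomaticScreen
Title: Somatic Variant Screening, Recurrence and Survival Analysis for
    Tumor Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the candidate somatic variant selection cascades used
    in tumor/normal and tumor-only sequencing studies of peripheral T-cell
    lymphoma: depth and allele-fraction gates, panel-of-normals and
    hyperplastic-control subtraction, germline database (dbSNP/1000 Genomes)
    exclusion with COSMIC retention, RNA-seq concordance, and flanking-context
    uniqueness checks, with a full per-variant audit trace. Downstream layers
    provide consensus damaging-prediction voting, protein-stability (ddG)
    classification, mutation-spectrum and burden statistics, gene-recurrence
    matrices, native Kaplan-Meier estimation and Mantel-Cox log-rank
    comparison of mutation-stratified survival. A deterministic synthetic
    cohort generator emulates the published cohort structure (discovery and
    extension tumors, matched saliva, panel-of-normals and hyperplastic
    controls, RNA evidence, clinical follow-up) with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    survival,
    VariantAnnotation,
    withr
biocViews: SomaticMutation, VariantAnnotation, Sequencing, Survival,
    Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
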