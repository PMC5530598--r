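Package: cloneforest
Title: Reconstruction of Clonal Evolution from Serial Tumour Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct clonal composition and evolution of
    myelodysplastic syndromes (and other haematological neoplasms) from
    longitudinal variant read counts. Implements tumour-versus-germline
    somatic variant filtering, deep-sequencing validation rules,
    copy-number-corrected cancer cell fractions, clustering of mutation
    trajectories across serial samples, exhaustive clone tree/forest
    inference under the pigeonhole and sum rules with detection of
    unrelated clones, genotyping of single-cell-derived colonies, and
    classification of evolution patterns (single clone, linear,
    branching). A fully seeded synthetic cohort generator produces
    ground-truthed longitudinal patients - clone forests, treatment
    bottlenecks, deep targeted and exome read counts, and CFU-GEMM
    colony genotypes - for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
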