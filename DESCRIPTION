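Package: mplaclone
Title: Clonal Architecture and Intertumoural Heterogeneity of Synchronous
    Multiple Primary Lung Adenocarcinomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intertumoural heterogeneity in synchronous
    multiple primary lung adenocarcinomas (sMPLA) from targeted-panel somatic
    variant calls. Classifies per-patient mutation events as trunk (present in
    every lesion), shared (in at least two but not all lesions) or branch
    (private to one lesion); calls patient-level concordance; reconstructs
    germline-rooted maximum-parsimony phylogenies for small lesion sets with
    events assigned to edges; tabulates strand-collapsed six-class substitution
    spectra stratified by smoking history and sex; screens driver-gene status
    against clinicopathological and imaging covariates with chi-square and
    Fisher exact tests; and compares variant allele frequencies across
    clonality classes. Includes a seeded synthetic-cohort simulator with
    recorded ground-truth clonality labels and a deterministic study-constrained
    fixture cohort for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ape,
    yaml
Config/testthat/edition: 3
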