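Package: ovacin
Title: Allele-Specific Copy-Number Calling, Chromosomal-Instability
    Profiling and Expression Subtyping for Ovarian Carcinoma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated copy-number and expression analysis toolkit for
    paired tumor/normal SNP-array cohorts. Computes allele-specific
    tumor/normal probe ratios, calls copy-number alterations (gain,
    hemizygous loss, homozygous deletion, copy-number-neutral LOH) by
    ratio thresholding with running-median smoothing, classifies events as
    focal or whole-arm, summarises per-sample chromosomal-instability
    (CIN) burden, tabulates tumor-suppressor-gene LOH co-occurrence, and
    subtypes tumors from expression arrays via global normalization, probe
    filtering, hierarchical clustering, gene-subsampled consensus k-means
    and NMF-based cluster-number selection. Fisher-exact contingency and
    Kaplan-Meier/log-rank/Cox survival statistics link subtypes to
    outcome. A synthetic-cohort generator with planted alterations,
    expression clusters and cluster-dependent hazards makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
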