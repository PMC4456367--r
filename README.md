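# ovacin

Integrated copy-number and expression analysis for ovarian carcinoma
cohorts assayed on paired tumor/normal SNP arrays and expression
arrays. The package is aimed at analysts reproducing or stress-testing
the classic array-era workflow that distinguishes ovarian clear cell
carcinoma (CCC) — few, predominantly whole-arm copy-number alterations
— from high-grade serous carcinoma (SC) — many focal alterations that
concentrate loss of heterozygosity on TP53, NF1, BRCA1, RB1 and BRCA2
— and that subtypes CCC by expression into groups with distinct
prognosis.

## What it computes

**Allele-specific CNA calling.** At a heterozygous SNP the tumor/normal
signal ratio for an allele in *c* copies at tumor purity *p* is

    r(c) = (1 − p)·1 + p·(1 + c)/2

(0.5, 1, 1.5 for 0, 1, 2 copies in a pure tumor). Ratios are smoothed
with a per-arm running median and thresholded — gain above 1.3, loss
below 0.7, strict — and runs of constant per-allele state become
segments classed as gain, hemizygous loss, homozygous deletion, or
copy-number-neutral LOH (one allele lost, the other duplicated).
Segments spanning more than 98% of their chromosome arm are whole-arm,
the rest focal.

**CIN profiling.** Samples are classed by the number of arms carrying
alterations (CNN-LOH included): CIN-high (≥ 9 arms), CIN-low (1–8),
CIN-negative (0). Per-arm event tables, whole-arm ratios with Fisher
comparison, mean CNA counts, ordinal-profile hierarchical clustering
and tumor-suppressor LOH co-occurrence summarize the cohort.

**Expression subtyping.** Global normalization to array mean 100, probe
filtering (max ≥ 100, mean ≥ 10, CV ≥ 0.3), Euclidean/complete
hierarchical clustering, consensus k-means over random 3000-gene
subsets, and NMF reconstruction error over the consensus matrices to
choose k.

**Statistics.** Two-sided Fisher exact tests (point-probability rule),
Kaplan–Meier/log-rank survival comparison, multivariate Cox regression.

**Synthetic cohorts.** A generator plants CNAs (configurable purity and
noise), expression clusters with marker genes, and clinical tables with
cluster-dependent hazards, so the full pipeline runs and is validated
without any array download. Bundled reference tables carry the
published per-arm event counts and tumor-suppressor LOH calls of a
57-tumor cohort (31 CCC, 14 SC, 12 endometrioid).

## Worked example

```r
library(ovacin)

## published cohort summaries bundled with the package
tab <- reference_arm_events()
whole_arm_ratio_test(tab, "CCC", "SC")
#> Whole-arm CNA ratio: CCC 46.9% (99/211) vs SC 22.0% (51/232) ; Fisher P = 4.44e-08
mean_cna_count(tab, "CCC")   #> 6.8
mean_cna_count(tab, "SC")    #> 17.8
fisher_exact_two_sided(reference_contingency_tables()$coalteration)
#> Fisher exact (two-sided) : P = 0.00387
#> odds ratio Inf (95% CI 2.13-Inf)

## a fully simulated cohort through the whole pipeline
cfg <- pipeline_config(
  sim = sim_config(
    archetypes = list(
      SC  = archetype(n = 5, mean_cna = 17.8, whole_arm_prob = 0.22,
                      tsg_co_loss = TRUE),
      CCC = archetype(n = 5, mean_cna = 6.8,  whole_arm_prob = 0.47),
      EC  = archetype(n = 5, mean_cna = 11,   whole_arm_prob = 0.35)),
    probes_per_arm = 100, n_expr_probes = 1000, seed = 1),
  consensus = list(k_range = 2:4, n_iter = 50, n_genes = 3000),
  seed = 1)
report <- run_pipeline(cfg)
report
#> Analysis report (seed 1 )
#> sections: cin_table, arm_event_table, whole_arm_ratio_test, tsg_loh_table,
#>           cna_cluster_labels, cluster_labels, contingency_tests, survival_tests
#> CIN classes:
#> high  low
#>   12    3
#> whole-arm ratio SC 31.5% vs CCC 56.4% (P = 0.0104)
#> chosen expression k: 3
#> log-rank P = 0.111
```

The first block reproduces the published cohort arithmetic: clear-cell
tumors average 6.8 alterations of which 46.9% are whole-arm, serous
tumors 17.8 mostly focal alterations, and the difference in whole-arm
ratio is highly significant; the PIK3CA/ARID1A co-alteration contrast
between CCC subtypes gives the exact p-value 0.0039. The second block
simulates a 15-tumor cohort, calls CNAs, classes CIN, recovers the
planted whole-arm contrast between the serous-like and clear-cell-like
archetypes, picks k = 3 for the planted expression clusters, and runs
the survival stage (at 15 tumors the log-rank test is underpowered, as
its p-value shows).

A thin CLI over the same functions lives at
`inst/scripts/ovacin-pipeline.R` (`run-all` and `simulate`
subcommands).

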