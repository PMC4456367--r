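#' Describe one histology archetype for the cohort simulator
#'
#' An archetype fixes the CNA-burden regime of one histological group:
#' the expected number of altered arms per tumor and the probability that
#' an alteration spans its whole arm. The defaults of [sim_config()]
#' parameterize a serous-like archetype (many, mostly focal events, with
#' frequent co-occurring loss of the chromosome 17/13 tumor-suppressor
#' loci), a clear-cell-like archetype (few events, roughly half whole-arm)
#' and an intermediate endometrioid-like archetype.
#'
#' @param n Samples to simulate for this archetype.
#' @param mean_cna Expected number of altered arms per sample (Poisson
#'   mean, capped at the number of modeled arms).
#' @param whole_arm_prob Probability that a planted event spans its whole
#'   arm (in `[0, 1]`).
#' @param tsg_co_loss If `TRUE`, a fraction `tsg_co_loss_prob` of samples
#'   additionally carry hemizygous whole-arm loss of 17p, 17q and 13q, the
#'   co-occurrence pattern of TP53/NF1/BRCA1 with RB1/BRCA2 LOH.
#' @param tsg_co_loss_prob Fraction of samples carrying the co-loss.
#' @return A list of class `archetype`.
#' @export
archetype <- function(n = 15, mean_cna = 7, whole_arm_prob = 0.47,
                      tsg_co_loss = FALSE, tsg_co_loss_prob = 0.85) {
  stopifnot_scalar(n, "n", lo = 1)
  stopifnot_scalar(mean_cna, "mean_cna", lo = 0)
  stopifnot_scalar(whole_arm_prob, "whole_arm_prob", lo = 0, hi = 1)
  stopifnot_scalar(tsg_co_loss_prob, "tsg_co_loss_prob", lo = 0, hi = 1)
  structure(list(n = as.integer(n), mean_cna = mean_cna,
                 whole_arm_prob = whole_arm_prob,
                 tsg_co_loss = isTRUE(tsg_co_loss),
                 tsg_co_loss_prob = tsg_co_loss_prob),
            class = "archetype")
}

#' Simulation configuration for a synthetic ovarian-carcinoma cohort
#'
#' Bundles every tunable of the cohort generator: histology archetypes,
#' tumor purity and signal noise for the SNP-array tracks, planted
#' expression-cluster structure, and the proportional-hazards model behind
#' the clinical table. Defaults mirror the study conditions the package is
#' built around: three histotypes with clear-cell tumors averaging 6.8
#' altered arms of which ~47% are whole-arm, serous tumors averaging 17.8
#' mostly focal events, purity 0.8, three expression clusters with a
#' log2 effect of 2 on 100 marker genes each, and a protective second
#' cluster (hazard multiplier 0.2) under administrative censoring at 60
#' months.
#'
#' @param archetypes Named list of [archetype()] objects; names are used
#'   as histology labels.
#' @param purity Tumor-cell fraction in `(0, 1]`; observed allele ratios
#'   are the purity-weighted mixture of tumor and diploid signal.
#' @param noise_sd Standard deviation (log scale) of the multiplicative
#'   log-normal noise on probe signals; `>= 0`.
#' @param chromosomes Chromosomes to model (default chr1-chr22, chrX).
#' @param probes_per_arm SNP probes per modeled arm.
#' @param n_expr_probes,n_expr_clusters,markers_per_cluster,log2_effect
#'   Expression simulator: matrix size, planted cluster count, marker
#'   genes per cluster, and the log2 shift applied to markers.
#' @param baseline_hazard Baseline progression hazard (events per month).
#' @param hazard_multipliers Per-cluster multiplicative hazards (> 0),
#'   recycled to the cluster count.
#' @param followup_horizon Administrative censoring time (months).
#' @param stage_early_prob,chemosensitive_prob,coalteration_prob
#'   Per-cluster probabilities of early stage (I/II), chemosensitive
#'   response, and coexistent PIK3CA/ARID1A alteration.
#' @param seed Master random seed recorded in all outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    archetypes = list(
      SC = archetype(n = 15, mean_cna = 17.8, whole_arm_prob = 0.22,
                     tsg_co_loss = TRUE),
      CCC = archetype(n = 15, mean_cna = 6.8, whole_arm_prob = 0.47),
      EC = archetype(n = 15, mean_cna = 11, whole_arm_prob = 0.35)),
    purity = 0.8, noise_sd = 0.1,
    chromosomes = paste0("chr", c(1:22, "X")), probes_per_arm = 200,
    n_expr_probes = 2000, n_expr_clusters = 3, markers_per_cluster = 100,
    log2_effect = 2,
    baseline_hazard = 0.02, hazard_multipliers = c(1, 0.2, 1),
    followup_horizon = 60,
    stage_early_prob = c(0.9, 0.8, 0.5),
    chemosensitive_prob = c(0.2, 0.9, 0.4),
    coalteration_prob = c(0.65, 0, 0.5),
    seed = 1L) {
  if (!is.list(archetypes) || is.null(names(archetypes)) ||
      any(names(archetypes) == ""))
    stop("'archetypes' must be a named list of archetype() objects")
  for (a in archetypes)
    if (!inherits(a, "archetype")) stop("each archetype must be archetype()")
  stopifnot_scalar(purity, "purity", lo = 0, hi = 1, lo_open = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", lo = 0)
  stopifnot_scalar(probes_per_arm, "probes_per_arm", lo = 1)
  stopifnot_scalar(n_expr_probes, "n_expr_probes", lo = 1)
  stopifnot_scalar(n_expr_clusters, "n_expr_clusters", lo = 1)
  stopifnot_scalar(markers_per_cluster, "markers_per_cluster", lo = 0)
  stopifnot_scalar(baseline_hazard, "baseline_hazard", lo = 0,
                   lo_open = TRUE)
  if (any(hazard_multipliers <= 0))
    stop("hazard multipliers must be positive")
  stopifnot_scalar(followup_horizon, "followup_horizon", lo = 0)
  for (p in list(stage_early_prob, chemosensitive_prob, coalteration_prob))
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot_scalar(seed, "seed")
  structure(list(
    archetypes = archetypes, purity = purity, noise_sd = noise_sd,
    chromosomes = chromosomes,
    probes_per_arm = as.integer(probes_per_arm),
    n_expr_probes = as.integer(n_expr_probes),
    n_expr_clusters = as.integer(n_expr_clusters),
    markers_per_cluster = as.integer(markers_per_cluster),
    log2_effect = log2_effect,
    baseline_hazard = baseline_hazard,
    hazard_multipliers = hazard_multipliers,
    followup_horizon = followup_horizon,
    stage_early_prob = stage_early_prob,
    chemosensitive_prob = chemosensitive_prob,
    coalteration_prob = coalteration_prob,
    seed = as.integer(seed)), class = "sim_config")
}

# allele copy states by planted category: c(copy_a, copy_b)
category_copies <- function(category) {
  switch(category,
         "gain" = c(1L, 2L),
         "hemizygous-loss" = c(0L, 1L),
         "cnn-loh" = c(0L, 2L),
         "homozygous-deletion" = c(0L, 0L),
         stop("unknown category: ", category))
}

# relative frequencies of planted categories; gains and hemizygous losses
# dominate, CNN-LOH and homozygous deletions are rarer
category_probs <- function() {
  c("gain" = 0.45, "hemizygous-loss" = 0.35,
    "cnn-loh" = 0.15, "homozygous-deletion" = 0.05)
}

#' Plant ground-truth copy-number alterations for a simulated cohort
#'
#' Draws, per sample, a Poisson number of altered arms (capped at the arm
#' count, at most one event per arm so planted intervals never overlap).
#' Each event is whole-arm with the archetype's probability, otherwise a
#' focal sub-interval; its allele-specific state is one of gain (1,2),
#' hemizygous loss (0,1), copy-number-neutral LOH (0,2) or homozygous
#' deletion (0,0). Serous-like archetypes with `tsg_co_loss` additionally
#' receive hemizygous whole-arm loss of 17p, 17q and 13q in a configured
#' fraction of samples, the planted counterpart of co-occurring
#' TP53/NF1/BRCA1 and RB1/BRCA2 LOH.
#'
#' @param genome A [generate_genome()] annotation.
#' @param config A [sim_config()].
#' @param seed Optional seed (defaults to `config$seed`).
#' @param min_focal_probes Minimum probe span of a focal event.
#' @return A data frame of class `cna_truth` with one row per planted
#'   event: `sample_id`, `histology`, `chrom`, `arm`, `start`, `end`
#'   (0-based half-open), `copy_a`, `copy_b`, `category`, `planted_span`.
#'   The diploid background (1,1) is never stored.
#' @export
simulate_cna_profiles <- function(genome, config, seed = NULL,
                                  min_focal_probes = 20) {
  stopifnot(inherits(genome, "genome_annotation"),
            inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  span <- arm_probe_span(genome)
  with_seed(seed, {
    rows <- list()
    for (h in names(config$archetypes)) {
      a <- config$archetypes[[h]]
      for (s in seq_len(a$n)) {
        sid <- sprintf("%s_%02d", h, s)
        n_ev <- min(stats::rpois(1, a$mean_cna), nrow(span))
        ev_arms <- if (n_ev > 0) sample(nrow(span), n_ev) else integer(0)
        co_loss <- a$tsg_co_loss &&
          stats::runif(1) < a$tsg_co_loss_prob
        forced <- if (co_loss)
          which(span$key %in% c("17p", "17q", "13q")) else integer(0)
        ev_arms <- union(setdiff(ev_arms, forced), forced)
        for (i in ev_arms) {
          arm <- span[i, ]
          armrow <- genome$arms[genome$arms$chrom == arm$chrom &
                                  genome$arms$arm == arm$arm, ]
          if (i %in% forced) {
            category <- "hemizygous-loss"
            whole <- TRUE
          } else {
            category <- sample(names(category_probs()), 1,
                               prob = category_probs())
            whole <- stats::runif(1) < a$whole_arm_prob
          }
          np <- armrow$n_probes
          if (whole) {
            p_from <- 1L; p_to <- np
          } else {
            lo <- min(min_focal_probes, np)
            hi <- max(lo, floor(0.9 * np))
            len <- if (hi > lo) sample(lo:hi, 1) else lo
            p_from <- if (np - len >= 1) sample(seq_len(np - len + 1), 1)
                      else 1L
            p_to <- p_from + len - 1L
          }
          arm_probes <- genome$probes[genome$probes$chrom == arm$chrom &
                                        genome$probes$arm == arm$arm, ]
          cp <- category_copies(category)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, histology = h, chrom = arm$chrom,
            arm = arm$arm, start = arm_probes$pos[p_from],
            end = arm_probes$pos[p_to] + 1,
            copy_a = cp[1], copy_b = cp[2], category = category,
            planted_span = if (whole) "whole-arm" else "focal",
            stringsAsFactors = FALSE)
        }
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(sample_id = character(), histology = character(),
                 chrom = character(), arm = character(),
                 start = numeric(), end = numeric(),
                 copy_a = integer(), copy_b = integer(),
                 category = character(), planted_span = character(),
                 stringsAsFactors = FALSE)
    attr(truth, "seed") <- seed
    class(truth) <- c("cna_truth", "data.frame")
    truth
  })
}

# expected tumor/normal allele ratio for planted copy number c at a given
# purity; the pure-tumor ratios (1+c)/2 are 0.5, 1 and 1.5 for 0, 1 and 2
# copies, attenuated toward the diploid value 1 by the normal-cell fraction
expected_allele_ratio <- function(copies, purity) {
  (1 - purity) * 1 + purity * (1 + copies) / 2
}

#' Simulate paired tumor/normal allele-level probe signals for one sample
#'
#' Normal allele signals are log-normal noise around a constant diploid
#' level; the tumor signal at each probe is the realized normal signal
#' times the expected allele ratio for the planted copy number (see
#' Details) times independent log-normal noise, so the tumor/normal ratio
#' at a probe with planted allele copy `c` has expectation
#' `(1 - purity) + purity * (1 + c) / 2` with multiplicative noise of
#' log-scale standard deviation `noise_sd`. At purity 1 and zero noise the
#' ratios are exactly 0.5, 1 and 1.5 for 0, 1 and 2 copies.
#'
#' @param truth A `cna_truth` data frame for a single sample (rows with
#'   one `sample_id`), or an empty truth set for a flat diploid sample.
#' @param genome A `genome_annotation`.
#' @param purity Tumor purity in `(0, 1]`.
#' @param noise_sd Log-scale noise standard deviation, `>= 0`.
#' @param seed Optional seed.
#' @param sample_id Sample label when `truth` is empty.
#' @return A data frame of class `probe_signals`: `snp_id`, `chrom`,
#'   `pos`, `tumorA`, `tumorB`, `normalA`, `normalB`, genome-ordered.
#' @export
simulate_probe_signals <- function(truth, genome, purity = 0.8,
                                   noise_sd = 0.1, seed = NULL,
                                   sample_id = NULL) {
  stopifnot(inherits(genome, "genome_annotation"))
  stopifnot_scalar(purity, "purity", lo = 0, hi = 1, lo_open = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", lo = 0)
  if (nrow(truth) > 0) {
    if (length(unique(truth$sample_id)) > 1)
      stop("simulate_probe_signals() expects the truth rows of one sample")
    sample_id <- truth$sample_id[1]
    bad <- !(truth$chrom %in% genome$arms$chrom)
    if (any(bad))
      stop("planted event outside modeled genome: ",
           paste(unique(truth$chrom[bad]), collapse = ", "))
  }
  if (is.null(sample_id)) sample_id <- "sample"
  probes <- genome$probes
  n <- nrow(probes)
  copy_a <- rep(1L, n); copy_b <- rep(1L, n)
  for (i in seq_len(nrow(truth))) {
    hit <- probes$chrom == truth$chrom[i] &
      probes$pos >= truth$start[i] & probes$pos < truth$end[i]
    copy_a[hit] <- truth$copy_a[i]
    copy_b[hit] <- truth$copy_b[i]
  }
  with_seed(seed, {
    normalA <- exp(stats::rnorm(n, 0, noise_sd))
    normalB <- exp(stats::rnorm(n, 0, noise_sd))
    tumorA <- normalA * expected_allele_ratio(copy_a, purity) *
      exp(stats::rnorm(n, 0, noise_sd))
    tumorB <- normalB * expected_allele_ratio(copy_b, purity) *
      exp(stats::rnorm(n, 0, noise_sd))
    out <- data.frame(snp_id = probes$snp_id, chrom = probes$chrom,
                      pos = probes$pos, tumorA = tumorA, tumorB = tumorB,
                      normalA = normalA, normalB = normalB,
                      stringsAsFactors = FALSE)
    attr(out, "sample_id") <- sample_id
    class(out) <- c("probe_signals", "data.frame")
    out
  })
}

#' Simulate signals for every sample of a planted cohort
#'
#' @param truth A `cna_truth` table (all samples).
#' @param genome A `genome_annotation`.
#' @param config A [sim_config()]; purity, noise and seed are taken from
#'   it, with per-sample sub-seeds derived from the master seed.
#' @return Named list of `probe_signals`, one per sample (samples with no
#'   planted events included).
#' @export
simulate_cohort_signals <- function(truth, genome, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- cohort_sample_ids(config)
  out <- lapply(seq_along(ids), function(i) {
    tr <- truth[truth$sample_id == ids[i], , drop = FALSE]
    simulate_probe_signals(tr, genome, purity = config$purity,
                           noise_sd = config$noise_sd,
                           seed = (config$seed * 1000L + i) %% 2147483647L,
                           sample_id = ids[i])
  })
  names(out) <- ids
  out
}

cohort_sample_ids <- function(config) {
  unlist(lapply(names(config$archetypes), function(h)
    sprintf("%s_%02d", h, seq_len(config$archetypes[[h]]$n))))
}

#' Simulate a linear-scale expression matrix with planted clusters
#'
#' Baseline log2 abundances are gene-specific normal draws; each planted
#' cluster has its own disjoint marker-gene set shifted by `log2_effect`
#' in that cluster's samples. All remaining genes are exchangeable noise.
#' Output is linear scale (`2^log2`).
#'
#' @param labels Integer cluster assignment per sample (1-based); sample
#'   names are taken from `names(labels)` when present.
#' @param config A [sim_config()]; uses `n_expr_probes`,
#'   `markers_per_cluster`, `log2_effect`.
#' @param seed Optional seed.
#' @return A numeric matrix (probes x samples) of class `expr_matrix`
#'   with probe and sample ids in dimnames and attributes `markers` (list
#'   of marker row indices per cluster) and `labels`.
#' @export
simulate_expression <- function(labels, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  k <- length(unique(labels))
  if (k < 2 && config$log2_effect != 0)
    stop("at least two clusters are required unless the effect is 0")
  g <- config$n_expr_probes
  n <- length(labels)
  n_mark <- config$markers_per_cluster
  if (n_mark * k > g)
    stop("marker genes (", n_mark * k, ") exceed gene count (", g, ")")
  if (is.null(names(labels)))
    names(labels) <- sprintf("S%02d", seq_len(n))
  with_seed(seed, {
    base_mu <- stats::rnorm(g, mean = 6, sd = 1.5)
    log2x <- matrix(stats::rnorm(g * n, mean = 0, sd = 0.5), g, n) + base_mu
    markers <- split(seq_len(n_mark * k),
                     rep(seq_len(k), each = n_mark))
    if (n_mark > 0)
      for (c in seq_len(k))
        log2x[markers[[c]], labels == sort(unique(labels))[c]] <-
          log2x[markers[[c]], labels == sort(unique(labels))[c]] +
          config$log2_effect
    x <- 2^log2x
    dimnames(x) <- list(sprintf("probe_%05d", seq_len(g)), names(labels))
    structure(x, markers = markers, labels = labels,
              class = c("expr_matrix", "matrix", "array"))
  })
}

#' Simulate a clinical table with a cluster-dependent hazard
#'
#' Progression-free survival times are exponential draws under a
#' proportional-hazards model (`baseline_hazard` times the cluster's
#' multiplier) with administrative censoring at `followup_horizon`
#' months. Stage, chemoresponse and PIK3CA/ARID1A co-alteration status are
#' Bernoulli draws with per-cluster probabilities.
#'
#' @param labels Integer cluster assignment per sample.
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return A data frame of class `clinical_table`: `sample_id`, `cluster`,
#'   `age`, `stage` ("I/II" or "III/IV"), `chemoresponse` ("sensitive" or
#'   "resistant"), `coalteration` (0/1), `pfs_months`, `progression`
#'   (1 = progressed/relapsed, 0 = censored).
#' @export
simulate_clinical <- function(labels, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$followup_horizon < 0) stop("follow-up horizon must be >= 0")
  n <- length(labels)
  if (is.null(names(labels)))
    names(labels) <- sprintf("S%02d", seq_len(n))
  k <- max(labels)
  mult <- rep_len(config$hazard_multipliers, k)
  p_early <- rep_len(config$stage_early_prob, k)
  p_sens <- rep_len(config$chemosensitive_prob, k)
  p_coalt <- rep_len(config$coalteration_prob, k)
  with_seed(seed, {
    rate <- config$baseline_hazard * mult[labels]
    t_event <- stats::rexp(n, rate = rate)
    progression <- as.integer(t_event <= config$followup_horizon)
    pfs <- pmin(t_event, config$followup_horizon)
    data.frame(
      sample_id = names(labels), cluster = as.integer(labels),
      age = round(stats::rnorm(n, 55, 10)),
      stage = ifelse(stats::runif(n) < p_early[labels], "I/II", "III/IV"),
      chemoresponse = ifelse(stats::runif(n) < p_sens[labels],
                             "sensitive", "resistant"),
      coalteration = as.integer(stats::runif(n) < p_coalt[labels]),
      pfs_months = pfs, progression = progression,
      stringsAsFactors = FALSE) -> out
    class(out) <- c("clinical_table", "data.frame")
    attr(out, "seed") <- seed
    out
  })
}
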