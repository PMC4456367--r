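test_that("identical tumor and normal give unit ratios and no segments", {
  g <- tiny_genome(50)
  sig <- flat_signals(g)
  sig$tumorA <- sig$normalA; sig$tumorB <- sig$normalB
  r <- compute_allelic_ratios(sig)
  expect_true(all(r$ratio_a == 1 & r$ratio_b == 1))
  for (cfgv in list(caller_config(),
                    caller_config(gain_threshold = 1.1,
                                  loss_threshold = 0.9))) {
    cc <- call_cna(sig, g, cfgv)
    expect_equal(nrow(cc$segments), 0)
  }
})

test_that("replicate intensities are summarised by the trimmed median", {
  g <- tiny_genome(3)
  n <- nrow(g$probes)
  reps <- matrix(rep(c(0.8, 1.0, 1.2, 5.0, 0.9), each = n), n, 5)
  tab <- list(snp_id = g$probes$snp_id, chrom = g$probes$chrom,
              pos = g$probes$pos,
              tumorA = reps, tumorB = reps,
              normalA = matrix(1, n, 5), normalB = matrix(1, n, 5))
  r <- compute_allelic_ratios(tab)
  # drop 5.0 and 0.8, median of {0.9, 1.0, 1.2} = 1.0
  expect_true(all(r$ratio_a == 1.0))
  tab$tumorA <- reps[, 1:2]
  expect_error(compute_allelic_ratios(tab), ">= 3 replicates")
})

test_that("non-positive normal signal errors naming the SNP", {
  g <- tiny_genome(5)
  sig <- flat_signals(g)
  sig$normalA[3] <- 0
  expect_error(compute_allelic_ratios(sig), sig$snp_id[3], fixed = TRUE)
})

test_that("running-median smoothing matches the brute-force oracle", {
  set.seed(42)
  x <- exp(rnorm(101, 0, 0.3))
  for (w in c(1, 5, 15)) {
    expect_equal(ovacin:::running_median(x, w),
                 running_median_oracle(x, w))
  }
  g <- tiny_genome(50)
  # constant track unchanged; single outlier removed; window 1 identity
  const <- ratio_track(g, rep(1, 150), rep(1, 150))
  expect_equal(smooth_ratios(const)$ratio_a, rep(1, 150))
  out <- ratio_track(g, c(rep(1, 70), 5, rep(1, 79)), rep(1, 150))
  sm <- smooth_ratios(out, caller_config(smooth_window = 15))
  expect_equal(sm$ratio_a[71], 1.0)
  expect_equal(smooth_ratios(out, caller_config(smooth_window = 1)),
               out)
})

test_that("oversized window falls back to the unit median with a warning", {
  g <- generate_genome(sim_config(chromosomes = "chr13",
                                  probes_per_arm = 9))
  tr <- ratio_track(g, seq(0.5, 1.5, length.out = 9), rep(1, 9))
  expect_warning(sm <- smooth_ratios(tr, caller_config(smooth_window = 11)),
                 "median")
  expect_equal(sm$ratio_a, rep(median(tr$ratio_a), 9))
})

test_that("segment categories follow the allele-state mapping", {
  g <- generate_genome(sim_config(chromosomes = "chr13",
                                  probes_per_arm = 60))
  n <- 60
  cases <- list(
    list(a = 0.5, b = 1.5, cat = "cnn-loh"),
    list(a = 0.5, b = 0.5, cat = "homozygous-deletion"),
    list(a = 1.0, b = 1.5, cat = "gain"),
    list(a = 0.65, b = 1.0, cat = "hemizygous-loss"),
    list(a = 1.5, b = 1.5, cat = "gain"))
  for (cs in cases) {
    tr <- ratio_track(g, c(rep(1, 5), rep(cs$a, 50), rep(1, 5)),
                      c(rep(1, 5), rep(cs$b, 50), rep(1, 5)))
    segs <- call_segments(tr, g, caller_config())
    expect_equal(nrow(segs), 1)
    expect_equal(segs$category, cs$cat)
    expect_equal(segs$n_probes, 50)
  }
  # thresholds are strict: 1.29 on one allele emits nothing
  tr <- ratio_track(g, rep(1.29, n), rep(1, n))
  expect_equal(nrow(call_segments(tr, g, caller_config())), 0)
  tr <- ratio_track(g, rep(1.3, n), rep(0.7, n))
  expect_equal(nrow(call_segments(tr, g, caller_config())), 0)
})

test_that("calls are monotone in the thresholds", {
  g <- tiny_genome(40)
  cfg <- tiny_config(40, archetypes = list(
    A = archetype(n = 3, mean_cna = 2, whole_arm_prob = 0.5)))
  truth <- simulate_cna_profiles(g, cfg, seed = 12)
  for (s in unique(truth$sample_id)) {
    sig <- simulate_probe_signals(truth[truth$sample_id == s, ], g,
                                  purity = 0.8, noise_sd = 0.05,
                                  seed = 13)
    r <- smooth_ratios(compute_allelic_ratios(sig), genome = g)
    base <- call_segments(r, g, caller_config())
    stricter <- call_segments(r, g, caller_config(gain_threshold = 1.5,
                                                  loss_threshold = 0.55))
    expect_lte(sum(stricter$a_state == "gain" | stricter$b_state == "gain"),
               sum(base$a_state == "gain" | base$b_state == "gain"))
    expect_lte(sum(stricter$a_state == "loss") + sum(stricter$b_state == "loss"),
               sum(base$a_state == "loss") + sum(base$b_state == "loss"))
  }
})

test_that("probe-grid mismatch is rejected", {
  g <- tiny_genome(10)
  tr <- ratio_track(g, rep(1, 30), rep(1, 30))
  tr <- tr[-1, ]
  expect_error(call_segments(tr, g), "probe grid")
})

test_that("span classification applies the strict 98% whole-arm rule", {
  # regular-grid arm with exact probe spacing so span fractions are exact
  arms <- data.frame(chrom = "chr13", arm = "q", start = 0, end = 1010,
                     stringsAsFactors = FALSE)
  g <- genome_from_arms(arms, probes_per_arm = 101)
  mk_seg <- function(frac) {
    # pick probes so the segment spans exactly frac of the arm probe span
    n_span <- round(frac * 100) + 1
    tr <- ratio_track(g, c(rep(0.5, n_span), rep(1, 101 - n_span)),
                      rep(1, 101))
    call_segments(tr, g, caller_config(min_probes = 2))
  }
  full <- classify_arm_span(mk_seg(1.0), g)
  expect_equal(full$segments$span_class, "whole-arm")
  expect_equal(full$events$event_class, "whole-arm")
  at97 <- classify_arm_span(mk_seg(0.97), g)
  expect_equal(at97$segments$span_class, "focal")
  at98 <- classify_arm_span(mk_seg(0.98), g)
  expect_equal(at98$segments$span_fraction, 0.98, tolerance = 1e-9)
  expect_equal(at98$segments$span_class, "focal")  # strictly > 0.98 only
})

test_that("a centromere-spanning run is split at the arm boundary", {
  g <- generate_genome(sim_config(chromosomes = "chr17",
                                  probes_per_arm = 50))
  tr <- ratio_track(g, rep(0.5, 100), rep(1, 100))  # loss across all 17
  segs <- call_segments(tr, g, caller_config())
  cls <- classify_arm_span(segs, g)
  expect_equal(nrow(cls$segments), 2)
  expect_setequal(cls$segments$arm, c("p", "q"))
  expect_true(all(cls$segments$span_class == "whole-arm"))
  expect_equal(nrow(cls$events), 2)
})

test_that("simulated cohorts are recovered with high sensitivity/low FDR", {
  # compact version of the cohort benchmark: one archetype, 8 samples
  cfg <- sim_config(archetypes = list(
    CCC = archetype(n = 8, mean_cna = 7, whole_arm_prob = 0.47)))
  g <- generate_genome(cfg)
  truth <- simulate_cna_profiles(g, cfg, seed = 21)
  sig <- simulate_cohort_signals(truth, g, cfg)
  calls <- lapply(sig, call_cna, genome = g)
  segs <- do.call(rbind, lapply(calls, `[[`, "segments"))
  evs <- do.call(rbind, lapply(calls, `[[`, "events"))
  ev <- evaluate_calls(segs, evs, truth)
  expect_gte(ev$sensitivity, 0.95)
  expect_lte(ev$fdr, 0.05)
})

test_that("seg round trip preserves segments and sidecar annotations", {
  cfg <- tiny_config(50, archetypes = list(
    A = archetype(n = 1, mean_cna = 3, whole_arm_prob = 0.5)))
  g <- tiny_genome(50)
  truth <- simulate_cna_profiles(g, cfg, seed = 31)
  sig <- simulate_probe_signals(truth, g, purity = 1, noise_sd = 0,
                                seed = 1)
  cc <- call_cna(sig, g)
  path <- withr::local_tempfile(fileext = ".seg")
  write_seg(cc$segments, path)
  back <- read_seg(path)
  expect_equal(back$category, cc$segments$category)
  expect_equal(back$span_class, cc$segments$span_class)
  expect_equal(back$start, cc$segments$start)
})
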