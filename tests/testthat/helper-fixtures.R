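# shared fixtures and independent oracles

# small two-chromosome genome for caller tests (17 has p+q, 13 q only)
tiny_config <- function(probes_per_arm = 50, ...) {
  sim_config(chromosomes = c("chr17", "chr13"),
             probes_per_arm = probes_per_arm, ...)
}

tiny_genome <- function(probes_per_arm = 50) {
  generate_genome(tiny_config(probes_per_arm))
}

# a flat diploid signal table for one sample, no noise
flat_signals <- function(genome, sample_id = "S1") {
  truth <- simulate_cna_profiles(
    genome,
    sim_config(archetypes = list(X = archetype(n = 1, mean_cna = 0)),
               chromosomes = unique(genome$arms$chrom),
               probes_per_arm = genome$arms$n_probes[1]),
    seed = 1)
  simulate_probe_signals(truth, genome, purity = 1, noise_sd = 0,
                         seed = 1, sample_id = sample_id)
}

# brute-force two-sided Fisher p: enumerate every table with the observed
# margins and sum the point probabilities not exceeding the observed one
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  point <- function(a) dhyper(a, c1, n - c1, r1)
  p_obs <- point(tab[1, 1])
  ps <- vapply(a_range, point, 0)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force truncated-window running median
running_median_oracle <- function(x, w) {
  h <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n),
         function(i) median(x[max(1, i - h):min(n, i + h)]), 0)
}

# build an allelic_ratios track directly from per-probe ratio vectors
ratio_track <- function(genome, ratio_a, ratio_b, sample_id = "S1") {
  out <- data.frame(snp_id = genome$probes$snp_id,
                    chrom = genome$probes$chrom,
                    pos = genome$probes$pos,
                    ratio_a = ratio_a, ratio_b = ratio_b,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("allelic_ratios", "data.frame")
  out
}
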