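mk_events <- function(sample_id, arms, classes = "focal") {
  data.frame(sample_id = sample_id,
             chrom = paste0("chr", sub("[pq]$", "", arms)),
             arm = sub("^[0-9X]+", "", arms),
             event_class = rep_len(classes, length(arms)),
             categories = "gain", stringsAsFactors = FALSE)
}

test_that("CIN class boundaries sit exactly at 0/1 and 8/9 arms", {
  g <- generate_genome(sim_config())
  arm_keys <- ovacin:::arm_key(g$arms$chrom, g$arms$arm)
  cases <- list(c(0, "negative"), c(1, "low"), c(8, "low"), c(9, "high"),
                c(41, "high"))
  ev <- do.call(rbind, lapply(seq_along(cases), function(i)
    if (as.integer(cases[[i]][1]) > 0)
      mk_events(paste0("S", i), arm_keys[seq_len(as.integer(cases[[i]][1]))])
    else NULL))
  prof <- build_cna_profile(ev, g,
                            sample_ids = paste0("S", seq_along(cases)))
  for (i in seq_along(cases)) {
    expect_equal(prof$samples$n_arms[i], as.integer(cases[[i]][1]))
    expect_equal(prof$samples$cin_class[i], cases[[i]][2])
  }
})

test_that("an arm is counted once however many segments it carries", {
  g <- generate_genome(sim_config())
  ev <- mk_events("S1", c("8q", "8q", "8q"))
  prof <- build_cna_profile(ev, g)
  expect_equal(prof$samples$n_arms, 1)
  expect_equal(prof$samples$cin_class, "low")
})

test_that("CIN classification matches a re-count oracle on random profiles", {
  g <- generate_genome(sim_config())
  arm_keys <- ovacin:::arm_key(g$arms$chrom, g$arms$arm)
  set.seed(99)
  n_arms <- sample(0:41, 1000, replace = TRUE)
  ev <- do.call(rbind, lapply(seq_len(1000), function(i)
    if (n_arms[i] > 0)
      mk_events(sprintf("S%04d", i), sample(arm_keys, n_arms[i]))
    else NULL))
  prof <- build_cna_profile(ev, g, sample_ids = sprintf("S%04d", 1:1000))
  oracle <- ifelse(n_arms >= 9, "high", ifelse(n_arms >= 1, "low",
                                               "negative"))
  expect_identical(prof$samples$cin_class, oracle)
  expect_identical(prof$samples$n_arms, as.integer(n_arms))
})

test_that("arm event table equals a brute-force recount of a planted map", {
  g <- generate_genome(sim_config())
  arm_keys <- ovacin:::arm_key(g$arms$chrom, g$arms$arm)
  set.seed(7)
  planted <- do.call(rbind, lapply(1:10, function(i) {
    k <- sample(0:6, 1)
    if (k == 0) return(NULL)
    mk_events(sprintf("S%02d", i), sample(arm_keys, k),
              classes = sample(c("focal", "whole-arm"), k, replace = TRUE))
  }))
  ids <- sprintf("S%02d", 1:10)
  groups <- setNames(rep(c("G1", "G2"), each = 5), ids)
  prof <- build_cna_profile(planted, g, sample_ids = ids)
  tab <- arm_event_table(prof, groups)
  # independent tally straight from the planted rows
  for (r in sample(nrow(tab), 30)) {
    sub <- planted[paste0(sub("chr", "", planted$chrom), planted$arm) ==
                     tab$arm[r] &
                     groups[planted$sample_id] == tab$group[r], ]
    expect_equal(tab$whole_arm[r], sum(sub$event_class == "whole-arm"))
    expect_equal(tab$focal[r], sum(sub$event_class == "focal"))
  }
  # additivity: grand total equals the number of planted (sample, arm) rows
  expect_equal(sum(tab$whole_arm + tab$focal), nrow(planted))
  expect_error(arm_event_table(prof, groups[1:3]), "unknown group")
})

test_that("reference arm-event table reproduces the published summaries", {
  tab <- reference_arm_events()
  ccc <- tab[tab$group == "CCC", ]
  expect_equal(sum(ccc$whole_arm), 99)
  expect_equal(sum(ccc$focal), 112)
  wt <- whole_arm_ratio_test(tab, "CCC", "SC")
  expect_equal(round(100 * wt$ratio_a, 1), 46.9)
  expect_lt(wt$test$p_value, 0.0001)
  expect_equal(mean_cna_count(tab, "CCC", n_samples = 31), 6.8)
  expect_equal(mean_cna_count(tab, "SC", n_samples = 13), 17.8)
})

test_that("whole-arm ratio test degenerate cases behave", {
  tab <- reference_arm_events()
  same <- whole_arm_ratio_test(tab, "CCC", "CCC")
  expect_equal(same$test$p_value, 1.0)
  empty <- tab; empty$whole_arm[empty$group == "SC"] <- 0L
  empty$focal[empty$group == "SC"] <- 0L
  expect_warning(
    expect_warning(res <- whole_arm_ratio_test(empty, "CCC", "SC"),
                   "undefined"),
    "empty margin")
  expect_true(is.na(res$ratio_b))
})

test_that("CNA-profile clustering separates archetypes and handles edges", {
  # sparse/whole-arm vs dense/focal burden contrast; recovery is averaged
  # over seeds because complete linkage on the ordinal encoding has a
  # narrow margin for any single draw
  cfg <- sim_config(archetypes = list(
    CCC = archetype(n = 10, mean_cna = 2, whole_arm_prob = 0.9),
    SC = archetype(n = 10, mean_cna = 30, whole_arm_prob = 0.1)))
  g <- generate_genome(cfg)
  ids <- ovacin:::cohort_sample_ids(cfg)
  aris <- vapply(1:5, function(sd) {
    truth <- simulate_cna_profiles(g, cfg, seed = sd)
    ev <- data.frame(sample_id = truth$sample_id, chrom = truth$chrom,
                     arm = truth$arm, event_class = truth$planted_span,
                     categories = truth$category, stringsAsFactors = FALSE)
    ev <- ev[!duplicated(paste(ev$sample_id, ev$chrom, ev$arm)), ]
    prof <- build_cna_profile(ev, g, sample_ids = ids)
    cl <- cluster_cna_profiles(prof, k = 2)
    ari(cl$labels, sub("_.*", "", ids))
  }, 0)
  expect_gte(mean(aris), 0.9)
  truth <- simulate_cna_profiles(g, cfg, seed = 1)
  ev <- data.frame(sample_id = truth$sample_id, chrom = truth$chrom,
                   arm = truth$arm, event_class = truth$planted_span,
                   categories = truth$category, stringsAsFactors = FALSE)
  ev <- ev[!duplicated(paste(ev$sample_id, ev$chrom, ev$arm)), ]
  prof <- build_cna_profile(ev, g, sample_ids = ids,
                            histology = setNames(sub("_.*", "", ids), ids))
  # duplicated sample merges at height zero
  prof2 <- prof
  prof2$arm_matrix <- rbind(prof$arm_matrix,
                            dup = prof$arm_matrix[1, ])
  prof2$samples <- rbind(prof$samples, prof$samples[1, ])
  prof2$samples$sample_id[nrow(prof2$samples)] <- "dup"
  cl2 <- cluster_cna_profiles(prof2, k = 2)
  expect_equal(min(cl2$hclust$height), 0)
  # k = n gives singletons; k > n errors
  cln <- cluster_cna_profiles(prof, k = nrow(prof$arm_matrix))
  expect_equal(length(unique(cln$labels)), nrow(prof$arm_matrix))
  expect_error(cluster_cna_profiles(prof, k = 21), "exceeds")
})

test_that("TSG LOH status follows segment overlap and category", {
  g <- generate_genome(sim_config())
  seg <- function(sample, chrom, start, end, category)
    data.frame(sample_id = sample, chrom = chrom, start = start,
               end = end, n_probes = 50, a_state = "loss",
               b_state = "neutral", category = category,
               seg_mean = 0, stringsAsFactors = FALSE)
  segs <- rbind(
    seg("S1", "chr17", 0, 81195210, "hemizygous-loss"),
    seg("S2", "chr13", 19500000, 115169878, "cnn-loh"))
  tab <- tsg_loh_status(segs, tsg_loci(),
                        sample_ids = c("S1", "S2", "S3"), genome = g)
  expect_equal(unname(unlist(tab[tab$sample_id == "S1",
                                 c("TP53", "NF1", "BRCA1")])),
               rep("LOH", 3))
  expect_equal(unname(unlist(tab[tab$sample_id == "S1",
                                 c("RB1", "BRCA2")])), rep("nl", 2))
  expect_equal(unname(unlist(tab[tab$sample_id == "S2",
                                 c("RB1", "BRCA2")])), rep("CNN LOH", 2))
  expect_equal(unname(unlist(tab[tab$sample_id == "S3",
                                 c("TP53", "NF1", "BRCA1", "RB1",
                                   "BRCA2")])), rep("nl", 5))
  bad <- tsg_loci(); bad$chrom[1] <- "chrZ"
  expect_error(tsg_loh_status(segs, bad, genome = g), "outside")
})

test_that("reference TSG table reproduces the published co-occurrence", {
  loh <- reference_tsg_loh()
  groups <- setNames(loh$histology, loh$sample_id)
  co <- loh_cooccurrence(loh[setdiff(names(loh), "histology")], groups)
  sc <- co[co$group == "SC", ]
  # every SC with BRCA1 LOH also has NF1 and TP53 LOH
  expect_equal(sc$fraction[sc$gene_x == "BRCA1" & sc$gene_y == "NF1"], 1)
  expect_equal(sc$fraction[sc$gene_x == "BRCA1" & sc$gene_y == "TP53"], 1)
  # every SC with BRCA2 LOH has RB1 LOH too
  expect_equal(sc$fraction[sc$gene_x == "BRCA2" & sc$gene_y == "RB1"], 1)
  # published marginal rates: TP53 92%, NF1/BRCA1 85%, RB1/BRCA2 62%
  altered <- colMeans(loh[loh$histology == "SC",
                          c("TP53", "NF1", "BRCA1", "RB1", "BRCA2")] != "nl")
  expect_equal(round(100 * unname(altered)), c(92, 85, 85, 62, 62))
})

test_that("planted shared-segment co-loss yields conditional fraction 1", {
  cfg <- sim_config(archetypes = list(
    SC = archetype(n = 12, mean_cna = 3, whole_arm_prob = 0.3,
                   tsg_co_loss = TRUE, tsg_co_loss_prob = 1)))
  g <- generate_genome(cfg)
  truth <- simulate_cna_profiles(g, cfg, seed = 23)
  sig <- simulate_cohort_signals(truth, g, cfg)
  calls <- lapply(sig, call_cna, genome = g)
  segs <- do.call(rbind, lapply(calls, `[[`, "segments"))
  loh <- tsg_loh_status(segs, tsg_loci(), sample_ids = names(sig),
                        genome = g)
  co <- loh_cooccurrence(loh)
  expect_equal(co$fraction[co$gene_x == "BRCA1" & co$gene_y == "NF1"], 1)
  expect_equal(co$fraction[co$gene_x == "BRCA2" & co$gene_y == "RB1"], 1)
})
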