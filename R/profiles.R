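#' Per-sample CNA burden and chromosomal-instability class
#'
#' Counts, for each sample, the chromosome arms carrying at least one
#' called segment of any category (copy-number-neutral LOH included) and
#' assigns the CIN class: `high` for 9 or more altered arms, `low` for 1
#' to 8, `negative` for none. An arm is counted once no matter how many
#' segments it carries.
#'
#' @param events Arm-event rows as produced by [classify_arm_span()] (or
#'   the `events` of one or more [call_cna()] results row-bound
#'   together).
#' @param genome A `genome_annotation` (fixes the arm universe).
#' @param sample_ids Samples to report; defaults to those present in
#'   `events`. Supply the full cohort so CIN-negative samples (no events)
#'   appear.
#' @param histology Optional named vector of group labels per sample.
#' @return An object of class `cna_profiles`: list with `samples` (data
#'   frame `sample_id`, `histology`, `n_arms`, `cin_class`) and
#'   `arm_matrix` (samples x arms; 0 none, 1 focal, 2 whole-arm).
#' @export
build_cna_profile <- function(events, genome, sample_ids = NULL,
                              histology = NULL) {
  stopifnot(inherits(genome, "genome_annotation"))
  arm_keys <- arm_key(genome$arms$chrom, genome$arms$arm)
  if (is.null(sample_ids)) sample_ids <- unique(events$sample_id)
  m <- matrix(0L, nrow = length(sample_ids), ncol = length(arm_keys),
              dimnames = list(sample_ids, arm_keys))
  if (nrow(events)) {
    ek <- arm_key(events$chrom, events$arm)
    if (!all(ek %in% arm_keys))
      stop("event on an arm outside the modeled genome: ",
           paste(setdiff(ek, arm_keys), collapse = ", "))
    for (i in seq_len(nrow(events))) {
      v <- if (events$event_class[i] == "whole-arm") 2L else 1L
      m[events$sample_id[i], ek[i]] <-
        max(m[events$sample_id[i], ek[i]], v)
    }
  }
  n_arms <- rowSums(m > 0)
  cin <- ifelse(n_arms >= 9, "high", ifelse(n_arms >= 1, "low", "negative"))
  hist_lab <- if (is.null(histology)) NA_character_
              else unname(histology[sample_ids])
  samples <- data.frame(sample_id = sample_ids, histology = hist_lab,
                        n_arms = as.integer(n_arms), cin_class = cin,
                        stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  structure(list(samples = samples, arm_matrix = m),
            class = "cna_profiles")
}

#' @export
print.cna_profiles <- function(x, ...) {
  cat("CNA profiles:", nrow(x$samples), "samples,",
      ncol(x$arm_matrix), "arms\n")
  print(table(x$samples$cin_class))
  invisible(x)
}

#' Tabulate whole-arm and focal events per arm and group
#'
#' For each chromosome arm and sample group, counts the samples whose
#' event on that arm is whole-arm versus focal. A sample contributes at
#' most one event per arm (whole-arm taking precedence when both occur).
#'
#' @param profiles A `cna_profiles` object.
#' @param groups Named character vector mapping every profiled sample to
#'   a group label; defaults to the stored histology.
#' @return A data frame of class `arm_event_table`: `arm`, `group`,
#'   `whole_arm`, `focal` (long layout, one row per arm x group).
#'   Attribute `group_sizes` records samples per group.
#' @export
arm_event_table <- function(profiles, groups = NULL) {
  stopifnot(inherits(profiles, "cna_profiles"))
  ids <- profiles$samples$sample_id
  if (is.null(groups)) {
    groups <- stats::setNames(profiles$samples$histology, ids)
    if (anyNA(groups)) stop("no histology stored; supply 'groups'")
  }
  if (!all(ids %in% names(groups)))
    stop("unknown group label for sample(s): ",
         paste(setdiff(ids, names(groups)), collapse = ", "))
  g <- groups[ids]
  m <- profiles$arm_matrix
  out <- do.call(rbind, lapply(colnames(m), function(a) {
    do.call(rbind, lapply(unique(g), function(grp) {
      col <- m[g == grp, a]
      data.frame(arm = a, group = grp,
                 whole_arm = sum(col == 2L), focal = sum(col == 1L),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "group_sizes") <- table(g)
  class(out) <- c("arm_event_table", "data.frame")
  out
}

#' Whole-arm CNA ratio per group with Fisher exact comparison
#'
#' The whole-arm ratio of a group is its whole-arm events over all its
#' events, summed over arms. The two groups are compared by a two-sided
#' Fisher exact test of the 2x2 (whole-arm, focal) x (group A, group B)
#' table.
#'
#' @param table An `arm_event_table`.
#' @param group_a,group_b Group labels to compare.
#' @return A list of class `whole_arm_ratio_test`: per-group counts and
#'   ratios, the 2x2 table, and the Fisher `assoc_test`.
#' @export
whole_arm_ratio_test <- function(table, group_a, group_b) {
  counts <- function(grp) {
    sub <- table[table$group == grp, , drop = FALSE]
    if (!nrow(sub)) stop("group not present: ", grp)
    c(whole = sum(sub$whole_arm), focal = sum(sub$focal))
  }
  ca <- counts(group_a); cb <- counts(group_b)
  ratio <- function(x) {
    tot <- sum(x)
    if (tot == 0) { warning("zero events; ratio undefined"); NA_real_ }
    else unname(x["whole"] / tot)
  }
  tab2 <- matrix(c(ca, cb), nrow = 2,
                 dimnames = list(c("whole-arm", "focal"),
                                 c(group_a, group_b)))
  structure(list(
    group_a = group_a, group_b = group_b,
    counts = list(ca, cb), table = tab2,
    ratio_a = ratio(ca), ratio_b = ratio(cb),
    test = fisher_exact_two_sided(tab2)),
    class = "whole_arm_ratio_test")
}

#' @export
print.whole_arm_ratio_test <- function(x, ...) {
  f <- function(r, ct) sprintf("%.1f%% (%d/%d)", 100 * r, ct["whole"],
                               sum(ct))
  cat("Whole-arm CNA ratio:", x$group_a, f(x$ratio_a, x$counts[[1]]),
      "vs", x$group_b, f(x$ratio_b, x$counts[[2]]),
      sprintf("; Fisher P = %.3g\n", x$test$p_value))
  invisible(x)
}

#' Mean CNA count per sample in a group
#'
#' Total arm events (one per altered (sample, arm) pair) divided by the
#' number of samples, reported to one decimal.
#'
#' @param table An `arm_event_table`.
#' @param group Group label.
#' @param n_samples Sample count for the group; defaults to the size
#'   recorded in the table.
#' @return Mean events per sample, rounded to one decimal.
#' @export
mean_cna_count <- function(table, group, n_samples = NULL) {
  sub <- table[table$group == group, , drop = FALSE]
  if (!nrow(sub)) stop("group not present: ", group)
  if (is.null(n_samples)) {
    sizes <- attr(table, "group_sizes")
    if (is.null(sizes) || !group %in% names(sizes))
      stop("supply 'n_samples' (no group sizes recorded)")
    n_samples <- as.numeric(sizes[group])
  }
  if (n_samples <= 0) stop("group is empty")
  round(sum(sub$whole_arm + sub$focal) / n_samples, 1)
}

#' Hierarchical clustering of per-arm CNA profiles
#'
#' Encodes each sample's per-arm event state ordinally (0 none, 1 focal,
#' 2 whole-arm) and clusters samples by Euclidean distance with complete
#' linkage, cutting the tree at `k`.
#'
#' @param profiles A `cna_profiles` object.
#' @param k Number of clusters (`<=` samples).
#' @return List with `labels` (named integer vector), `hclust` (the
#'   dendrogram) and `matrix` (the encoded profile matrix).
#' @export
cluster_cna_profiles <- function(profiles, k) {
  stopifnot(inherits(profiles, "cna_profiles"))
  m <- profiles$arm_matrix
  if (k > nrow(m)) stop("k exceeds the number of samples")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "complete")
  list(labels = stats::cutree(hc, k = k), hclust = hc, matrix = m)
}

#' Built-in tumor-suppressor gene loci
#'
#' Approximate GRCh37 coordinates (0-based half-open) for the five
#' tumor-suppressor genes whose LOH co-occurrence is tabulated: TP53,
#' NF1 and BRCA1 on chromosome 17 and RB1 and BRCA2 on 13q. Override
#' with a BED file via [read_gene_loci_bed()].
#'
#' @return Data frame: `gene`, `chrom`, `cytoband`, `start`, `end`.
#' @export
tsg_loci <- function() {
  data.frame(
    gene = c("TP53", "NF1", "BRCA1", "RB1", "BRCA2"),
    chrom = c("chr17", "chr17", "chr17", "chr13", "chr13"),
    cytoband = c("17p13.1", "17q11.2", "17q21.2", "13q14.2", "13q13.2"),
    start = c(7565097, 29421944, 41196311, 48877882, 32889610),
    end = c(7590856, 29708905, 41277500, 49056122, 32973805),
    stringsAsFactors = FALSE)
}

#' Read gene loci from a BED file
#'
#' @param path BED file (0-based half-open: chrom, start, end, name).
#' @return Data frame with `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_loci_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("BED file needs chrom, start, end, name")
  data.frame(gene = bed[[4]], chrom = bed[[1]], start = bed[[2]],
             end = bed[[3]], stringsAsFactors = FALSE)
}

#' Tumor-suppressor LOH status per sample and gene
#'
#' A gene's status in a sample is `LOH` when a hemizygous-loss or
#' homozygous-deletion segment overlaps the locus, `CNN LOH` when a
#' copy-number-neutral LOH segment does (deletion LOH takes precedence
#' when both overlap), and `nl` (no alteration) otherwise; any overlap
#' counts.
#'
#' @param segments A `cna_segments` data frame (multiple samples).
#' @param loci Gene loci data frame ([tsg_loci()] by default).
#' @param sample_ids Samples to report (default: those in `segments`).
#' @param genome Optional `genome_annotation` used to validate that each
#'   locus lies inside the modeled genome.
#' @return A data frame of class `tsg_loh_table`: `sample_id` plus one
#'   status column per gene.
#' @export
tsg_loh_status <- function(segments, loci = tsg_loci(), sample_ids = NULL,
                           genome = NULL) {
  if (!is.null(genome)) {
    for (i in seq_len(nrow(loci))) {
      arms <- genome$arms[genome$arms$chrom == loci$chrom[i] &
                            genome$arms$start <= loci$start[i] &
                            genome$arms$end >= loci$end[i], ]
      if (nrow(arms) == 0)
        stop("locus outside modeled genome: ", loci$gene[i])
    }
  }
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  status <- matrix("nl", nrow = length(sample_ids), ncol = nrow(loci),
                   dimnames = list(sample_ids, loci$gene))
  loh_cats <- c("hemizygous-loss", "homozygous-deletion")
  for (s in sample_ids) {
    segs <- segments[segments$sample_id == s, , drop = FALSE]
    for (j in seq_len(nrow(loci))) {
      ov <- segs$chrom == loci$chrom[j] &
        interval_overlap(segs$start, segs$end,
                         loci$start[j], loci$end[j]) > 0
      cats <- segs$category[ov]
      status[s, j] <- if (any(cats %in% loh_cats)) "LOH"
                      else if (any(cats == "cnn-loh")) "CNN LOH"
                      else "nl"
    }
  }
  out <- data.frame(sample_id = sample_ids, status,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("tsg_loh_table", "data.frame")
  out
}

#' LOH co-occurrence between tumor-suppressor genes
#'
#' For every ordered gene pair (X, Y) and each group, the fraction of
#' samples altered at X (LOH or CNN LOH) that are also altered at Y.
#'
#' @param loh A `tsg_loh_table`.
#' @param groups Optional named vector of group labels per sample; with
#'   `NULL` all samples form one group.
#' @return A data frame: `group`, `gene_x`, `gene_y`, `n_x` (samples
#'   altered at X), `n_xy`, `fraction` (`NA` when `n_x` is 0).
#' @export
loh_cooccurrence <- function(loh, groups = NULL) {
  genes <- setdiff(names(loh), "sample_id")
  if (is.null(groups))
    groups <- stats::setNames(rep("all", nrow(loh)), loh$sample_id)
  g <- groups[loh$sample_id]
  altered <- as.matrix(loh[genes]) != "nl"
  out <- do.call(rbind, lapply(unique(g), function(grp) {
    sub <- altered[g == grp, , drop = FALSE]
    do.call(rbind, lapply(genes, function(x) do.call(rbind, lapply(
      setdiff(genes, x), function(y) {
        nx <- sum(sub[, x])
        nxy <- sum(sub[, x] & sub[, y])
        data.frame(group = grp, gene_x = x, gene_y = y, n_x = nx,
                   n_xy = nxy,
                   fraction = if (nx > 0) nxy / nx else NA_real_,
                   stringsAsFactors = FALSE)
      }))))
  }))
  rownames(out) <- NULL
  out
}
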