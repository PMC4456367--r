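#' Benchmark called segments against planted truth
#'
#' Matches called segments to planted events by genomic overlap within
#' each sample and chromosome. A planted event counts as recovered when
#' a single called segment covers at least `min_overlap` of its length;
#' a called segment counts as a false discovery when no planted event
#' covers at least `min_overlap` of the segment. Category agreement is
#' assessed on recovered events against their best-overlapping segment.
#' The whole-arm fraction is compared between planted events and called
#' arm events.
#'
#' @param segments Classified `cna_segments` for the cohort.
#' @param events Arm-event rows from [classify_arm_span()] /
#'   [call_cna()].
#' @param truth The `cna_truth` table the signals were simulated from.
#' @param min_overlap Overlap fraction for a match (default 0.5).
#' @return List with `sensitivity`, `fdr`, `category_confusion`
#'   (fraction of recovered events whose called category differs),
#'   `whole_arm_fraction_planted`, `whole_arm_fraction_called`,
#'   `n_planted`, `n_called`.
#' @export
evaluate_calls <- function(segments, events, truth, min_overlap = 0.5) {
  n_planted <- nrow(truth)
  recovered <- logical(n_planted)
  cat_match <- logical(n_planted)
  for (i in seq_len(n_planted)) {
    segs <- segments[segments$sample_id == truth$sample_id[i] &
                       segments$chrom == truth$chrom[i], , drop = FALSE]
    if (!nrow(segs)) next
    ov <- interval_overlap(segs$start, segs$end, truth$start[i],
                           truth$end[i]) / (truth$end[i] - truth$start[i])
    j <- which.max(ov)
    if (ov[j] >= min_overlap) {
      recovered[i] <- TRUE
      cat_match[i] <- segs$category[j] == truth$category[i]
    }
  }
  n_called <- nrow(segments)
  true_call <- logical(n_called)
  for (i in seq_len(n_called)) {
    tr <- truth[truth$sample_id == segments$sample_id[i] &
                  truth$chrom == segments$chrom[i], , drop = FALSE]
    if (!nrow(tr)) next
    ov <- interval_overlap(tr$start, tr$end, segments$start[i],
                           segments$end[i]) /
      (segments$end[i] - segments$start[i])
    true_call[i] <- any(ov >= min_overlap)
  }
  list(
    sensitivity = if (n_planted) mean(recovered) else NA_real_,
    fdr = if (n_called) mean(!true_call) else 0,
    category_confusion = if (any(recovered))
      mean(!cat_match[recovered]) else NA_real_,
    whole_arm_fraction_planted = if (n_planted)
      mean(truth$planted_span == "whole-arm") else NA_real_,
    whole_arm_fraction_called = if (nrow(events))
      mean(events$event_class == "whole-arm") else NA_real_,
    n_planted = n_planted, n_called = n_called)
}
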