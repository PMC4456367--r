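#' Configuration of the allele-specific CNA caller
#'
#' Holds the ratio cut-offs and segmentation settings. The defaults are
#' the published operating point of the genome-imbalance-map approach: a
#' tumor/normal relative ratio above 1.3 (about 1.6 copies) calls an
#' allele gain and below 0.7 (about 0.4 copies) an allele loss, both
#' strict inequalities; an event longer than 98% of its chromosome arm is
#' whole-arm. Smoothing window, minimum segment size and the noise-gap
#' tolerance are segmentation choices exposed here.
#'
#' @param gain_threshold Ratio above which an allele is called gained.
#' @param loss_threshold Ratio below which an allele is called lost.
#' @param smooth_window Running-median window in probes (odd, `>= 1`).
#' @param min_probes Minimum probes for an emitted segment.
#' @param span_fraction Arm-span fraction above which a segment is
#'   whole-arm (strictly greater; in `(0, 1)`).
#' @param gap_tolerance Runs of at most this many probes in a different
#'   state are absorbed into a flanking constant run. The default is
#'   half the smoothing window: a running median cannot resolve features
#'   shorter than that, and any interruption below `min_probes` could
#'   never form a segment of its own, so absorbing it merges runs that a
#'   sub-resolution noise dip would otherwise split.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(gain_threshold = 1.3, loss_threshold = 0.7,
                          smooth_window = 15, min_probes = 10,
                          span_fraction = 0.98, gap_tolerance = 7) {
  if (!(loss_threshold < 1 && 1 < gain_threshold))
    stop("thresholds must satisfy loss < 1 < gain")
  stopifnot_scalar(smooth_window, "smooth_window", lo = 1)
  if (smooth_window %% 2 == 0) stop("smoothing window must be odd")
  stopifnot_scalar(min_probes, "min_probes", lo = 1)
  stopifnot_scalar(span_fraction, "span_fraction", lo = 0, hi = 1,
                   lo_open = TRUE, hi_open = TRUE)
  stopifnot_scalar(gap_tolerance, "gap_tolerance", lo = 0)
  structure(list(gain_threshold = gain_threshold,
                 loss_threshold = loss_threshold,
                 smooth_window = as.integer(smooth_window),
                 min_probes = as.integer(min_probes),
                 span_fraction = span_fraction,
                 gap_tolerance = as.integer(gap_tolerance)),
            class = "caller_config")
}

# median after removing one maximum and one minimum; requires >= 3 values
trimmed_median <- function(x) {
  if (length(x) < 3) stop("trimmed summary requires >= 3 replicates")
  s <- sort(x)
  stats::median(s[2:(length(s) - 1L)])
}

#' Per-SNP allele-specific tumor/normal ratios
#'
#' For each SNP and allele, the ratio of the tumor signal summary to the
#' normal signal summary. With single intensities this is the plain
#' tumor/normal ratio; when replicate probe intensities are supplied
#' (matrix columns per replicate, at least three), each side is summarised
#' by the median after omitting the highest and lowest replicate before
#' taking the ratio.
#'
#' @param table A `probe_signals` data frame (or list) with fields
#'   `snp_id`, `chrom`, `pos` and `tumorA`, `tumorB`, `normalA`,
#'   `normalB`, each a vector or a probes-by-replicates matrix.
#' @return A data frame of class `allelic_ratios`: `snp_id`, `chrom`,
#'   `pos`, `ratio_a`, `ratio_b`, in input order.
#' @export
compute_allelic_ratios <- function(table) {
  summarise <- function(x) {
    if (is.matrix(x)) {
      if (ncol(x) < 3)
        stop("replicate intensities require >= 3 replicates per SNP")
      apply(x, 1, trimmed_median)
    } else as.numeric(x)
  }
  tA <- summarise(table$tumorA); tB <- summarise(table$tumorB)
  nA <- summarise(table$normalA); nB <- summarise(table$normalB)
  bad <- which(nA <= 0 | nB <= 0)
  if (length(bad))
    stop("non-positive normal signal at SNP ",
         paste(utils::head(table$snp_id[bad], 5), collapse = ", "))
  if (any(c(tA, tB) <= 0)) stop("non-positive tumor signal")
  out <- data.frame(snp_id = table$snp_id, chrom = table$chrom,
                    pos = table$pos, ratio_a = tA / nA, ratio_b = tB / nB,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- attr(table, "sample_id")
  class(out) <- c("allelic_ratios", "data.frame")
  out
}

# running median with the window truncated at the sequence ends:
# value i is median(x[max(1, i-h) : min(n, i+h)])
running_median <- function(x, window) {
  n <- length(x)
  if (window <= 1 || n == 1) return(x)
  if (window > n) return(rep(stats::median(x), n))
  h <- (window - 1L) %/% 2L
  out <- as.numeric(stats::runmed(x, window, endrule = "keep"))
  edge <- unique(c(seq_len(min(h, n)), seq.int(max(1L, n - h + 1L), n)))
  for (i in edge)
    out[i] <- stats::median(x[max(1L, i - h):min(n, i + h)])
  out
}

#' Smooth allelic-ratio tracks with a running median
#'
#' Applies a running median to both allele tracks with the window
#' truncated at sequence ends. When a genome annotation is supplied the
#' smoothing unit is the chromosome arm (the centromere is a genomic
#' discontinuity: letting windows straddle it erodes the tips of
#' whole-arm events); otherwise the unit is the chromosome. Output has
#' the same length and order as the input. If the window exceeds a
#' unit's probe count, that unit is set to its overall median with a
#' warning.
#'
#' @param track An `allelic_ratios` data frame.
#' @param config A [caller_config()].
#' @param genome Optional `genome_annotation` matching the track's probe
#'   grid; enables per-arm smoothing.
#' @return The smoothed `allelic_ratios`.
#' @export
smooth_ratios <- function(track, config = caller_config(), genome = NULL) {
  stopifnot(inherits(config, "caller_config"))
  w <- config$smooth_window
  unit <- if (!is.null(genome)) {
    if (nrow(genome$probes) != nrow(track))
      stop("ratio track does not match the genome's probe grid")
    paste(track$chrom, genome$probes$arm)
  } else track$chrom
  for (u in unique(unit)) {
    i <- which(unit == u)
    if (w > length(i))
      warning("smoothing window (", w, ") exceeds probe count on ", u,
              "; using its overall median")
    track$ratio_a[i] <- running_median(track$ratio_a[i], w)
    track$ratio_b[i] <- running_median(track$ratio_b[i], w)
  }
  track
}

allele_state <- function(r, config) {
  ifelse(r > config$gain_threshold, 1L,
         ifelse(r < config$loss_threshold, -1L, 0L))
}

segment_category <- function(a_state, b_state) {
  lo <- sum(c(a_state, b_state) == -1L)
  hi <- sum(c(a_state, b_state) == 1L)
  if (lo == 2L) "homozygous-deletion"
  else if (lo == 1L && hi == 1L) "cnn-loh"
  else if (lo == 1L) "hemizygous-loss"
  else if (hi >= 1L) "gain"
  else NA_character_
}

# absorb interior runs of length <= gap into a flanking constant run when
# both flanks share the same state (noise tolerance inside long events)
absorb_gaps <- function(states, gap) {
  if (gap < 1) return(states)
  repeat {
    r <- rle(states)
    k <- length(r$lengths)
    if (k < 3) return(states)
    idx <- which(r$lengths[-c(1, k)] <= gap) + 1L
    idx <- idx[r$values[idx - 1L] == r$values[idx + 1L]]
    if (!length(idx)) return(states)
    i <- idx[1]
    r$values[i] <- r$values[i - 1L]
    states <- inverse.rle(r)
  }
}

#' Call copy-number segments from allelic-ratio tracks
#'
#' Thresholds each allele track per probe (gain above, loss below the
#' configured cut-offs, strict inequalities), absorbs short noise gaps,
#' and merges maximal runs of a constant (A-state, B-state) pair with at
#' least `min_probes` probes into segments. The category follows the
#' allele states: loss of both alleles is a homozygous deletion; loss of
#' one with gain of the other is copy-number-neutral LOH; loss of exactly
#' one allele with the other neutral is a hemizygous loss; gain of at
#' least one allele with none lost (total copy number three or more
#' without LOH) is a gain. Neutral/neutral runs emit nothing.
#'
#' @param track An `allelic_ratios` data frame (smoothed or raw).
#' @param genome A `genome_annotation` whose probes match the track.
#' @param config A [caller_config()].
#' @param sample_id Sample label carried into the output.
#' @return A data frame of class `cna_segments`: `sample_id`, `chrom`,
#'   `start`, `end` (0-based half-open, first to last probe + 1),
#'   `n_probes`, `a_state`, `b_state` (each "loss"/"neutral"/"gain"),
#'   `category`, `seg_mean` (mean log2 total-copy ratio).
#' @export
call_segments <- function(track, genome, config = caller_config(),
                          sample_id = NULL) {
  stopifnot(inherits(config, "caller_config"))
  if (is.null(sample_id))
    sample_id <- attr(track, "sample_id") %||% "sample"
  gp <- genome$probes
  if (nrow(track) != nrow(gp) ||
      !all(track$chrom == gp$chrom & track$pos == gp$pos))
    stop("ratio track does not match the genome's probe grid")
  state_names <- c("loss", "neutral", "gain")
  segs <- list()
  for (ch in unique(track$chrom)) {
    i <- which(track$chrom == ch)
    a <- allele_state(track$ratio_a[i], config)
    b <- allele_state(track$ratio_b[i], config)
    combo <- absorb_gaps(paste(a, b), config$gap_tolerance)
    r <- rle(combo)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      st <- as.integer(strsplit(r$values[j], " ")[[1]])
      if (all(st == 0L) || r$lengths[j] < config$min_probes) next
      cat_ <- segment_category(st[1], st[2])
      if (is.na(cat_)) next
      idx <- i[starts[j]:ends[j]]
      segs[[length(segs) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = ch,
        start = track$pos[idx[1]], end = track$pos[idx[length(idx)]] + 1,
        n_probes = length(idx),
        a_state = state_names[st[1] + 2L], b_state = state_names[st[2] + 2L],
        category = cat_,
        seg_mean = mean(log2((track$ratio_a[idx] + track$ratio_b[idx]) / 2)),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else empty_segments()
  class(out) <- c("cna_segments", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_segments <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start = numeric(), end = numeric(), n_probes = integer(),
             a_state = character(), b_state = character(),
             category = character(), seg_mean = numeric(),
             stringsAsFactors = FALSE)
}

#' Classify segments as focal or whole-arm and tabulate arm events
#'
#' Segments spanning the centromere are first split at the arm boundary.
#' A segment's span fraction is the genomic length of its probe span
#' divided by the span between its arm's first and last probe; fractions
#' strictly greater than the configured cut (default 0.98) are whole-arm,
#' everything else (including exactly 0.98) focal. Each (sample, arm)
#' carrying at least one segment contributes exactly one event,
#' whole-arm if any single segment there is whole-arm.
#'
#' @param segments A `cna_segments` data frame (one or more samples).
#' @param genome A `genome_annotation`.
#' @param config A [caller_config()].
#' @return A list with `segments` (input rows split per arm, plus `arm`,
#'   `span_fraction`, `span_class`) and `events` (one row per (sample,
#'   arm) with >= 1 segment: `sample_id`, `chrom`, `arm`, `event_class`,
#'   `categories`).
#' @export
classify_arm_span <- function(segments, genome, config = caller_config()) {
  stopifnot(inherits(config, "caller_config"))
  span <- arm_probe_span(genome)
  pieces <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    arms <- genome$arms[genome$arms$chrom == seg$chrom &
                          genome$arms$start < seg$end &
                          genome$arms$end > seg$start, , drop = FALSE]
    if (nrow(arms) == 0)
      stop("segment outside modeled arms: ", seg$chrom, ":", seg$start)
    for (j in seq_len(nrow(arms))) {
      a <- arms[j, ]
      s <- max(seg$start, a$start); e <- min(seg$end, a$end)
      ap <- genome$probes[genome$probes$chrom == seg$chrom &
                            genome$probes$arm == a$arm, ]
      inside <- ap$pos >= s & ap$pos < e
      if (!any(inside)) next
      first <- min(ap$pos[inside]); last <- max(ap$pos[inside])
      sp <- span[span$chrom == seg$chrom & span$arm == a$arm, ]
      denom <- sp$last - sp$first
      frac <- if (denom > 0) (last - first) / denom else 1
      piece <- seg
      piece$start <- first; piece$end <- last + 1
      piece$n_probes <- sum(inside)
      piece$arm <- a$arm
      piece$span_fraction <- frac
      piece$span_class <- if (frac > config$span_fraction) "whole-arm"
                          else "focal"
      pieces[[length(pieces) + 1L]] <- piece
    }
  }
  segs <- if (length(pieces)) do.call(rbind, pieces) else {
    e <- empty_segments(); e$arm <- character(0)
    e$span_fraction <- numeric(0); e$span_class <- character(0); e
  }
  rownames(segs) <- NULL
  class(segs) <- c("cna_segments", "data.frame")

  if (nrow(segs)) {
    key <- paste(segs$sample_id, segs$chrom, segs$arm)
    ev <- do.call(rbind, lapply(split(segs, key), function(g) data.frame(
      sample_id = g$sample_id[1], chrom = g$chrom[1], arm = g$arm[1],
      event_class = if (any(g$span_class == "whole-arm")) "whole-arm"
                    else "focal",
      categories = paste(sort(unique(g$category)), collapse = ","),
      stringsAsFactors = FALSE)))
    rownames(ev) <- NULL
  } else {
    ev <- data.frame(sample_id = character(), chrom = character(),
                     arm = character(), event_class = character(),
                     categories = character(), stringsAsFactors = FALSE)
  }
  list(segments = segs, events = ev)
}

#' Call allele-specific copy-number alterations for one sample
#'
#' Convenience wrapper running the full caller: tumor/normal allelic
#' ratios, running-median smoothing, threshold segmentation and
#' focal/whole-arm classification.
#'
#' @param signals A `probe_signals` table.
#' @param genome A `genome_annotation`.
#' @param config A [caller_config()].
#' @param sample_id Optional sample label.
#' @return An object of class `cna_call`: list with `segments`, `events`,
#'   `sample_id`, `config`.
#' @export
call_cna <- function(signals, genome, config = caller_config(),
                     sample_id = NULL) {
  ratios <- compute_allelic_ratios(signals)
  smoothed <- smooth_ratios(ratios, config, genome = genome)
  segs <- call_segments(smoothed, genome, config,
                        sample_id = sample_id %||%
                          attr(signals, "sample_id"))
  cls <- classify_arm_span(segs, genome, config)
  structure(list(segments = cls$segments, events = cls$events,
                 sample_id = sample_id %||% attr(signals, "sample_id"),
                 config = config),
            class = "cna_call")
}

#' @export
print.cna_call <- function(x, ...) {
  cat("CNA call for", x$sample_id %||% "sample", "-",
      nrow(x$segments), "segments on",
      length(unique(paste(x$events$chrom, x$events$arm))), "arms\n")
  if (nrow(x$segments))
    print(table(x$segments$category, x$segments$span_class))
  invisible(x)
}
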