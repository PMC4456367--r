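#' Read and write probe-signal tables
#'
#' Tab-separated, one row per SNP in genome order, columns `snp_id`,
#' `chrom`, `pos`, `tumorA`, `tumorB`, `normalA`, `normalB`.
#'
#' @param x A `probe_signals` data frame.
#' @param path File path.
#' @return `write_probe_signals` returns `path` invisibly;
#'   `read_probe_signals` a `probe_signals` data frame.
#' @export
write_probe_signals <- function(x, path) {
  utils::write.table(as.data.frame(x)[c("snp_id", "chrom", "pos", "tumorA",
                                        "tumorB", "normalA", "normalB")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_signals
#' @param sample_id Sample label attached to the loaded table.
#' @export
read_probe_signals <- function(path, sample_id = NULL) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "tumorA", "tumorB", "normalA",
            "normalB")
  if (!all(need %in% names(x)))
    stop("missing probe-signal columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  for (ch in unique(x$chrom)) {
    p <- x$pos[x$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on ", ch)
  }
  if (any(x[c("tumorA", "tumorB", "normalA", "normalB")] <= 0))
    stop("intensities must be positive")
  attr(x, "sample_id") <- sample_id
  class(x) <- c("probe_signals", "data.frame")
  x
}

#' Write called segments in IGV .seg format with an allele-state sidecar
#'
#' The `.seg` file carries sample, chromosome, start, end, probe count
#' and `seg.mean` (log2 total-copy ratio); the sidecar TSV adds the
#' per-allele states, category and focal/whole-arm span class.
#'
#' @param segments A classified `cna_segments` data frame.
#' @param path Output `.seg` path; the sidecar is `<path>.states.tsv`.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  seg <- data.frame(Sample = segments$sample_id,
                    Chromosome = segments$chrom,
                    Start = segments$start, End = segments$end,
                    Num_Probes = segments$n_probes,
                    Seg.Mean = round(segments$seg_mean, 4))
  utils::write.table(seg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side_cols <- intersect(c("sample_id", "chrom", "start", "end", "arm",
                           "a_state", "b_state", "category",
                           "span_fraction", "span_class"),
                         names(segments))
  utils::write.table(as.data.frame(segments)[side_cols],
                     paste0(path, ".states.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read segments written by [write_seg()]
#'
#' @param path The `.seg` path (sidecar expected alongside).
#' @return A `cna_segments` data frame.
#' @export
read_seg <- function(path) {
  side <- paste0(path, ".states.tsv")
  if (!file.exists(side)) stop("sidecar not found: ", side)
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  st <- utils::read.delim(side, stringsAsFactors = FALSE)
  out <- cbind(data.frame(sample_id = seg$Sample, chrom = seg$Chromosome,
                          start = seg$Start, end = seg$End,
                          n_probes = seg$Num_Probes,
                          seg_mean = seg$Seg.Mean,
                          stringsAsFactors = FALSE),
               st[setdiff(names(st), c("sample_id", "chrom", "start",
                                       "end"))])
  class(out) <- c("cna_segments", "data.frame")
  out
}

#' Read and write expression matrices
#'
#' Tab-separated probes-by-samples layout: first column `probe_id`,
#' remaining columns one per sample, linear-scale signals.
#'
#' @param x Probes-by-samples numeric matrix.
#' @param path File path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(probe_id = rownames(x) %||% seq_len(nrow(x)),
                   as.data.frame(unclass(x)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  if (anyNA(m)) stop("expression matrix contains missing values")
  m
}

#' Read and write clinical tables
#'
#' Comma-separated with header `sample_id, cluster, age, stage,
#' chemoresponse, coalteration, pfs_months, progression`.
#'
#' @param x A `clinical_table` data frame.
#' @param path File path.
#' @export
write_clinical <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pfs_months", "progression")
  if (!all(need %in% names(x)))
    stop("missing clinical columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  if (!all(x$progression %in% c(0, 1)))
    stop("progression indicator must be 0/1")
  class(x) <- c("clinical_table", "data.frame")
  x
}
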