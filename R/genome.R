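#' @title Chromosome-arm genome model
#' @description Internal table of chromosome lengths and centromere
#'   boundaries (GRCh37 coordinates, 0-based half-open). The short arms of
#'   the acrocentric chromosomes 13, 14, 15, 21 and 22 carry no SNP probes
#'   on mapping arrays and are not modeled, giving 41 analysable arms on
#'   chromosomes 1-22 plus X.
#' @keywords internal
#' @noRd
chrom_table <- function() {
  data.frame(
    chrom = paste0("chr", c(1:22, "X")),
    length = c(249250621, 243199373, 198022430, 191154276, 180915260,
               171115067, 159138663, 146364022, 141213431, 135534747,
               135006516, 133851895, 115169878, 107349540, 102531392,
               90354753, 81195210, 78077248, 59128983, 63025520,
               48129895, 51304566, 155270560),
    acen_start = c(121500000, 90500000, 87900000, 48200000, 46100000,
                   58700000, 58000000, 43100000, 47300000, 38000000,
                   51600000, 33300000, 16300000, 16100000, 15800000,
                   34600000, 22200000, 15400000, 24400000, 25600000,
                   10900000, 12200000, 58100000),
    acen_end = c(128900000, 96800000, 93900000, 52700000, 50700000,
                 63300000, 61700000, 48100000, 50700000, 42300000,
                 55700000, 38200000, 19500000, 19100000, 20700000,
                 38600000, 25800000, 19000000, 28600000, 29400000,
                 14300000, 17900000, 63000000),
    stringsAsFactors = FALSE
  )
}

acrocentric <- function() paste0("chr", c(13, 14, 15, 21, 22))

#' Build a chromosome-arm genome annotation with probe positions
#'
#' Constructs the genomic coordinate system used throughout the package: p
#' and q arms for each modeled chromosome (GRCh37 boundaries; acrocentric
#' short arms omitted) and an ordered grid of SNP probe positions per arm.
#' The default genome has 22 autosomes plus X and 41 modeled arms. Probes
#' are placed on a regular grid within each arm, so the annotation is fully
#' deterministic.
#'
#' @param config A [sim_config()] object; only its `chromosomes` and
#'   `probes_per_arm` fields are used.
#' @return An object of class `genome_annotation`: a list with elements
#'   `arms` (data frame: `chrom`, `arm`, `start`, `end`, `n_probes`;
#'   coordinates 0-based half-open) and `probes` (data frame: `snp_id`,
#'   `chrom`, `arm`, `pos`, genome-ordered).
#' @examples
#' g <- generate_genome(sim_config())
#' nrow(g$arms)  # 41 modeled arms
#' @export
generate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_probes <- config$probes_per_arm
  if (n_probes < 1) stop("at least one probe per arm is required")
  tab <- chrom_table()
  tab <- tab[tab$chrom %in% config$chromosomes, , drop = FALSE]
  if (nrow(tab) == 0) stop("no modeled chromosomes selected")

  arms <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    ch <- tab$chrom[i]
    out <- data.frame(chrom = ch, arm = c("p", "q"),
                      start = c(0, tab$acen_end[i]),
                      end = c(tab$acen_start[i], tab$length[i]),
                      stringsAsFactors = FALSE)
    if (ch %in% acrocentric()) out <- out[out$arm == "q", , drop = FALSE]
    out
  }))
  rownames(arms) <- NULL
  arms$n_probes <- n_probes

  probes <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    step <- (a$end - a$start) / n_probes
    pos <- floor(a$start + (seq_len(n_probes) - 0.5) * step)
    data.frame(
      snp_id = sprintf("%s%s_%04d", sub("chr", "", a$chrom), a$arm,
                       seq_len(n_probes)),
      chrom = a$chrom, arm = a$arm, pos = pos, stringsAsFactors = FALSE)
  }))
  rownames(probes) <- NULL

  structure(list(arms = arms, probes = probes), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("Genome annotation:", length(unique(x$arms$chrom)), "chromosomes,",
      nrow(x$arms), "arms,", nrow(x$probes), "probes\n")
  invisible(x)
}

arm_key <- function(chrom, arm) paste0(sub("chr", "", chrom), arm)

# per-arm first/last probe position (observable span at arm tips)
arm_probe_span <- function(genome) {
  sp <- do.call(rbind, lapply(split(genome$probes,
                                    arm_key(genome$probes$chrom,
                                            genome$probes$arm)),
                              function(p) data.frame(
                                chrom = p$chrom[1], arm = p$arm[1],
                                first = min(p$pos), last = max(p$pos),
                                stringsAsFactors = FALSE)))
  sp$key <- arm_key(sp$chrom, sp$arm)
  rownames(sp) <- NULL
  sp
}

#' Write or read a chromosome-arm annotation in UCSC cytoBand format
#'
#' The on-disk dialect is the UCSC `cytoBand.txt` layout (tab-separated:
#' chrom, start, end, band name, Giemsa stain; 0-based half-open). Each
#' modeled arm is written as one band (`p`/`q`, stain `gneg`) and the
#' centromere as two `acen` bands; [read_cytoband()] reconstructs the arm
#' table, treating any band whose name starts with `p`/`q` and whose stain
#' is not `acen` as arm territory.
#'
#' @param genome A `genome_annotation`.
#' @param path File path.
#' @return `write_cytoband` returns `path` invisibly; `read_cytoband`
#'   returns an arm data frame (`chrom`, `arm`, `start`, `end`).
#' @export
write_cytoband <- function(genome, path) {
  stopifnot(inherits(genome, "genome_annotation"))
  arms <- genome$arms
  rows <- lapply(unique(arms$chrom), function(ch) {
    a <- arms[arms$chrom == ch, ]
    out <- data.frame(chrom = a$chrom, start = a$start, end = a$end,
                      name = a$arm, stain = "gneg",
                      stringsAsFactors = FALSE)
    # centromere: gap between p end (or 0 for acrocentrics) and q start
    qs <- a$start[a$arm == "q"]
    pe <- if (any(a$arm == "p")) a$end[a$arm == "p"] else 0
    if (length(qs) == 1 && qs > pe) {
      mid <- floor((pe + qs) / 2)
      out <- rbind(out,
        data.frame(chrom = ch, start = pe, end = mid, name = "p11.1",
                   stain = "acen", stringsAsFactors = FALSE),
        data.frame(chrom = ch, start = mid, end = qs, name = "q11",
                   stain = "acen", stringsAsFactors = FALSE))
    }
    out[order(out$start), ]
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cytoband
#' @export
read_cytoband <- function(path) {
  tab <- utils::read.delim(path, header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "stain"),
                           stringsAsFactors = FALSE)
  tab <- tab[tab$stain != "acen" & grepl("^[pq]", tab$name), , drop = FALSE]
  tab$arm <- substr(tab$name, 1, 1)
  lo <- stats::aggregate(start ~ chrom + arm, data = tab, FUN = min)
  hi <- stats::aggregate(end ~ chrom + arm, data = tab, FUN = max)
  arms <- merge(lo, hi, by = c("chrom", "arm"))
  chrom_order <- paste0("chr", c(1:22, "X", "Y"))
  arms <- arms[order(match(arms$chrom, chrom_order), arms$arm), ]
  rownames(arms) <- NULL
  arms
}

#' Rebuild a genome annotation from an arm table
#'
#' Places a regular probe grid on arms read from a cytoBand file, producing
#' the same structure as [generate_genome()].
#'
#' @param arms Arm data frame as returned by [read_cytoband()].
#' @param probes_per_arm Probes per modeled arm.
#' @return A `genome_annotation`.
#' @export
genome_from_arms <- function(arms, probes_per_arm = 200) {
  if (probes_per_arm < 1) stop("at least one probe per arm is required")
  arms$n_probes <- probes_per_arm
  probes <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    step <- (a$end - a$start) / probes_per_arm
    pos <- floor(a$start + (seq_len(probes_per_arm) - 0.5) * step)
    data.frame(
      snp_id = sprintf("%s%s_%04d", sub("chr", "", a$chrom), a$arm,
                       seq_len(probes_per_arm)),
      chrom = a$chrom, arm = a$arm, pos = pos, stringsAsFactors = FALSE)
  }))
  rownames(probes) <- NULL
  structure(list(arms = arms, probes = probes), class = "genome_annotation")
}
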