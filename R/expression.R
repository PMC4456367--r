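#' Probe-filter and normalization settings for expression arrays
#'
#' Defaults reproduce a classic array-vintage workflow: global
#' normalization scales every array to a mean signal of 100, and probes
#' are kept when their maximum signal is at least 100, their mean at
#' least 10 and their coefficient of variation (sd/mean, linear scale) at
#' least 0.3.
#'
#' @param max_signal,mean_signal,cv Filter thresholds (all `>= 0`).
#' @param target_mean Per-array mean after global normalization.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_signal = 100, mean_signal = 10, cv = 0.3,
                          target_mean = 100) {
  for (v in c(max_signal, mean_signal, cv, target_mean))
    stopifnot_scalar(v, "threshold", lo = 0)
  structure(list(max_signal = max_signal, mean_signal = mean_signal,
                 cv = cv, target_mean = target_mean),
            class = "filter_config")
}

#' Global normalization of an expression matrix
#'
#' Scales each sample column so its mean signal equals the target
#' (default 100), preserving relative values within the column. The
#' operation is idempotent and scale-invariant.
#'
#' @param x Probes-by-samples matrix of non-negative linear signals.
#' @param config A [filter_config()].
#' @return The normalized matrix.
#' @export
global_normalize <- function(x, config = filter_config()) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("expression signals must be non-negative")
  mu <- colMeans(x)
  if (any(mu <= 0))
    stop("all-zero array column(s): ",
         paste(utils::head(colnames(x)[mu <= 0], 5), collapse = ", "))
  sweep(x, 2, mu / config$target_mean, "/")
}

#' Filter probes on maximum, mean and coefficient of variation
#'
#' Keeps probes whose maximum signal, mean signal and coefficient of
#' variation (sd/mean on the linear normalized scale) all reach their
#' thresholds, preserving probe order.
#'
#' @param x Normalized probes-by-samples matrix.
#' @param config A [filter_config()].
#' @return The row-subset matrix; warns (not errors) when nothing passes.
#' @export
filter_probes <- function(x, config = filter_config()) {
  x <- as.matrix(x)
  mx <- apply(x, 1, max)
  mu <- rowMeans(x)
  cv <- ifelse(mu > 0, apply(x, 1, stats::sd) / mu, 0)
  keep <- mx >= config$max_signal & mu >= config$mean_signal &
    cv >= config$cv
  if (!any(keep)) warning("no probes pass the filter")
  x[keep, , drop = FALSE]
}

# log2(signal + 1) of the linear matrix: clustering operates on this scale
expr_transform <- function(x, log2_transform = TRUE) {
  if (log2_transform) log2(x + 1) else x
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of samples with Euclidean distance and
#' complete linkage on log2(signal + 1) values (configurable to the
#' linear scale), cut at `k`. Deterministic given input order; distance
#' ties are resolved by stats::hclust's order-dependent rule.
#'
#' @param x Filtered probes-by-samples matrix (linear scale).
#' @param k Number of clusters (`>= 2`).
#' @param log2_transform Cluster on log2(signal + 1) (default) or linear.
#' @return List with `labels` (named integer vector) and `hclust`.
#' @export
hierarchical_clusters <- function(x, k, log2_transform = TRUE) {
  if (k < 2) stop("k must be at least 2")
  x <- as.matrix(x)
  if (k > ncol(x)) stop("k exceeds the number of samples")
  d <- stats::dist(t(expr_transform(x, log2_transform)),
                   method = "euclidean")
  hc <- stats::hclust(d, method = "complete")
  list(labels = stats::cutree(hc, k = k), hclust = hc)
}

# random-partition k-means: initial centers are the means of a random
# partition of the samples into k groups; retried on degenerate draws
kmeans_random_partition <- function(y, k, iter_max = 100) {
  n <- nrow(y)
  for (try in 1:10) {
    part <- sample(rep_len(seq_len(k), n))
    centers <- do.call(rbind, lapply(seq_len(k), function(c)
      colMeans(y[part == c, , drop = FALSE])))
    if (anyDuplicated(centers)) next
    fit <- tryCatch(
      stats::kmeans(y, centers = centers, iter.max = iter_max),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) return(fit$cluster)
  }
  # degenerate data (for example duplicated points); fall back to the
  # partition means' nearest-center assignment
  dmat <- as.matrix(stats::dist(rbind(centers, y)))[-(1:k), 1:k,
                                                    drop = FALSE]
  max.col(-dmat, ties.method = "first")
}

#' Consensus k-means over random gene subsets
#'
#' For each candidate `k`, repeats k-means `n_iter` times, each run on
#' `n_genes` genes sampled without replacement and a shuffled sample
#' order (random-partition initialization, at most 100 Lloyd iterations).
#' The consensus matrix entry (i, j) is the fraction of runs placing
#' samples i and j in the same cluster. Final labels cut an
#' average-linkage hierarchical tree of 1 - consensus at `k`. When
#' `n_genes` exceeds the available genes, all genes are used each run.
#'
#' @param x Filtered probes-by-samples matrix (linear scale).
#' @param k_range Candidate cluster numbers (default 2 to 10).
#' @param n_iter Runs per `k` (default 1000).
#' @param n_genes Genes sampled per run (default 3000, capped at the
#'   gene count).
#' @param seed Optional master seed; each run draws from one stream.
#' @param log2_transform Operate on log2(signal + 1) (default).
#' @return An object of class `consensus_result`: list with `consensus`
#'   (named list of sample x sample matrices per k), `labels` (list of
#'   final label vectors per k), `k_range`, `n_iter`, `n_genes`.
#' @export
consensus_kmeans <- function(x, k_range = 2:10, n_iter = 1000,
                             n_genes = 3000, seed = NULL,
                             log2_transform = TRUE) {
  if (n_iter < 1) stop("n_iter must be at least 1")
  x <- as.matrix(x)
  y_all <- t(expr_transform(x, log2_transform))
  n <- nrow(y_all)
  g <- ncol(y_all)
  n_genes <- min(n_genes, g)
  sample_names <- rownames(y_all) %||% sprintf("S%02d", seq_len(n))
  with_seed(seed, {
    consensus <- list(); labels <- list()
    for (k in k_range) {
      if (k > n) stop("k exceeds the number of samples")
      co <- matrix(0, n, n)
      for (it in seq_len(n_iter)) {
        genes <- if (n_genes < g) sample(g, n_genes) else seq_len(g)
        ord <- sample(n)                      # shuffled sample order
        cl_shuf <- kmeans_random_partition(
          y_all[ord, genes, drop = FALSE], k)
        cl <- integer(n); cl[ord] <- cl_shuf
        co <- co + outer(cl, cl, "==")
      }
      cm <- co / n_iter
      dimnames(cm) <- list(sample_names, sample_names)
      hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
      lab <- stats::cutree(hc, k = k)
      names(lab) <- sample_names
      consensus[[as.character(k)]] <- cm
      labels[[as.character(k)]] <- lab
    }
    structure(list(consensus = consensus, labels = labels,
                   k_range = k_range, n_iter = n_iter, n_genes = n_genes),
              class = "consensus_result")
  })
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus k-means over k =", paste(range(x$k_range), collapse = "-"),
      "(", x$n_iter, "runs,", x$n_genes, "genes per run )\n")
  if (!is.null(x$chosen_k)) cat("chosen k:", x$chosen_k, "\n")
  invisible(x)
}

# rank-r non-negative matrix factorization by multiplicative updates
# (Frobenius objective); returns the relative reconstruction error
nmf_error <- function(m, rank, max_iter = 200, tol = 1e-6) {
  n <- nrow(m); p <- ncol(m)
  w <- matrix(stats::runif(n * rank, 0.1, 1), n, rank)
  h <- matrix(stats::runif(rank * p, 0.1, 1), rank, p)
  eps <- 1e-12
  err_old <- Inf
  for (i in seq_len(max_iter)) {
    h <- h * (t(w) %*% m) / (t(w) %*% w %*% h + eps)
    w <- w * (m %*% t(h)) / (w %*% h %*% t(h) + eps)
    if (i %% 10 == 0) {
      err <- norm(m - w %*% h, "F") / max(norm(m, "F"), eps)
      if (abs(err_old - err) < tol) break
      err_old <- err
    }
  }
  norm(m - w %*% h, "F") / max(norm(m, "F"), 1e-12)
}

#' Choose the cluster number by NMF reconstruction error
#'
#' Factorizes each k's consensus matrix at rank k with multiplicative-
#' update non-negative matrix factorization and records the relative
#' Frobenius reconstruction error, minimized over random restarts. The
#' chosen k is the error minimum; exact ties go to the smallest k. A
#' clean k-block consensus factorizes at rank k with near-zero error,
#' while over- or under-clustered consensus matrices are unstable and
#' fit poorly.
#'
#' @param result A `consensus_result` (or a named list of consensus
#'   matrices keyed by k).
#' @param k_range Candidate ks; default every k in `result`.
#' @param n_restarts Random restarts per k (default 10).
#' @param seed Optional seed.
#' @return The `consensus_result` with `errors` (named numeric) and
#'   `chosen_k` added (a plain list when matrices were supplied).
#' @export
select_k_nmf <- function(result, k_range = NULL, n_restarts = 10,
                         seed = NULL) {
  mats <- if (inherits(result, "consensus_result")) result$consensus
          else result
  ks <- if (is.null(k_range)) as.integer(names(mats)) else k_range
  with_seed(seed, {
    errors <- vapply(ks, function(k) {
      m <- mats[[as.character(k)]]
      if (is.null(m)) stop("no consensus matrix for k = ", k)
      min(vapply(seq_len(n_restarts), function(r) nmf_error(m, k),
                 numeric(1)))
    }, numeric(1))
    names(errors) <- ks
    chosen <- ks[which.min(errors)]   # which.min takes the first minimum
    if (inherits(result, "consensus_result")) {
      result$errors <- errors
      result$chosen_k <- chosen
      result
    } else list(errors = errors, chosen_k = chosen)
  })
}

#' Rank genes by mean log2 fold change between two clusters
#'
#' Per gene, the log2 ratio of the two clusters' mean linear signals
#' (with a pseudocount so zero-variance and zero-signal genes stay
#' defined), ranked from most up-regulated in cluster A downward.
#' Swapping the clusters negates every log2 ratio.
#'
#' @param x Probes-by-samples matrix (linear scale).
#' @param labels Cluster assignment per sample.
#' @param cluster_a,cluster_b The two cluster labels to contrast.
#' @param pseudocount Added to both means (default 1).
#' @return Data frame `gene`, `mean_a`, `mean_b`, `log2_ratio`, `rank`,
#'   ordered by decreasing `log2_ratio`.
#' @export
rank_marker_genes <- function(x, labels, cluster_a, cluster_b,
                              pseudocount = 1) {
  x <- as.matrix(x)
  a <- labels == cluster_a; b <- labels == cluster_b
  if (!any(a) || !any(b)) stop("both clusters must be non-empty")
  ma <- rowMeans(x[, a, drop = FALSE])
  mb <- rowMeans(x[, b, drop = FALSE])
  lfc <- log2((ma + pseudocount) / (mb + pseudocount))
  out <- data.frame(gene = rownames(x) %||% seq_len(nrow(x)),
                    mean_a = ma, mean_b = mb, log2_ratio = lfc,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$log2_ratio), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
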