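#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value under the point-probability rule: the sum of
#' hypergeometric probabilities of every table with the observed margins
#' whose point probability does not exceed that of the observed table
#' (the rule of `stats::fisher.test`, which this wraps). An empty margin
#' gives p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return An object of class `assoc_test`: list with `method`,
#'   `p_value`, `estimate` (conditional odds ratio), `conf_int`, `table`.
#' @examples
#' fisher_exact_two_sided(matrix(c(7, 0, 4, 10), 2))$p_value  # 0.0039
#' @export
fisher_exact_two_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("empty margin; p = 1")
    return(structure(list(method = "Fisher exact (two-sided)",
                          p_value = 1, estimate = NA_real_,
                          conf_int = c(NA_real_, NA_real_), table = table),
                     class = "assoc_test"))
  }
  ft <- stats::fisher.test(table)
  structure(list(method = "Fisher exact (two-sided)",
                 p_value = ft$p.value,
                 estimate = unname(ft$estimate),
                 conf_int = unname(ft$conf.int), table = table),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(x$method, ": P =", format.pval(x$p_value, digits = 3), "\n")
  if (!is.na(x$estimate))
    cat(sprintf("odds ratio %.3g (95%% CI %.3g-%.3g)\n", x$estimate,
                x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival estimates per group with the k-group log-rank
#' chi-square test (k - 1 degrees of freedom).
#'
#' @param records Data frame with survival fields.
#' @param group Name of the grouping column.
#' @param time,event Names of the time (months) and event-indicator
#'   (1 = progression/relapse, 0 = censored) columns.
#' @return An object of class `km_logrank`: list with `curves` (data
#'   frame `group`, `time`, `n_risk`, `n_event`, `surv`), `statistic`,
#'   `df`, `p_value`, and the underlying `survfit`.
#' @export
km_logrank <- function(records, group = "group", time = "pfs_months",
                       event = "progression") {
  d <- data.frame(time = records[[time]], event = records[[event]],
                  group = factor(records[[group]]))
  if (any(d$time < 0)) stop("survival times must be non-negative")
  if (!all(d$event %in% c(0, 1))) stop("event indicator must be 0/1")
  if (nlevels(d$group) < 2)
    stop("at least two groups are required for a log-rank test")
  if (sum(d$event) < 1) stop("at least one event is required")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sdf <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sdf$n) - 1
  p <- stats::pchisq(sdf$chisq, df = df, lower.tail = FALSE)
  strata <- rep(names(fit$strata) %||% levels(d$group),
                fit$strata %||% length(fit$time))
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv,
                       stringsAsFactors = FALSE)
  structure(list(curves = curves, statistic = unname(sdf$chisq), df = df,
                 p_value = p, fit = fit),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("Log-rank chi-square = %.3f on %d df, P = %s\n",
              x$statistic, x$df, format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' @export
plot.km_logrank <- function(x, xlab = "Months", ylab = "Survival", ...) {
  graphics::plot(x$fit, col = seq_along(x$fit$strata), xlab = xlab,
                 ylab = ylab, ...)
  graphics::legend("bottomleft", legend = sub("^group=", "",
                                              names(x$fit$strata)),
                   col = seq_along(x$fit$strata), lty = 1, bty = "n")
  invisible(x)
}

#' Multivariate Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling; hazard ratios with
#' Wald 95% confidence intervals per covariate. A covariate that is
#' constant across samples is an error (no information); monotone
#' likelihood (complete separation) is flagged and the estimate
#' suppressed.
#'
#' @param records Data frame with survival fields and covariates.
#' @param covariates Character vector of covariate column names.
#' @param time,event Time and event column names.
#' @return A data frame of class `cox_result`: `covariate`, `hr`,
#'   `ci_lower`, `ci_upper`, `p_value`, `flagged`; attribute `fit` holds
#'   the `coxph` object.
#' @export
cox_multivariate <- function(records, covariates, time = "pfs_months",
                             event = "progression") {
  for (v in covariates) {
    x <- records[[v]]
    if (is.null(x)) stop("covariate not found: ", v)
    if (length(unique(x[!is.na(x)])) < 2)
      stop("covariate is constant across samples: ", v)
  }
  if (sum(records[[event]]) < length(covariates) + 1)
    stop("need more events than covariates")
  fml <- stats::as.formula(paste(
    "survival::Surv(", time, ",", event, ") ~",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = "efron")
  sm <- summary(fit)
  co <- sm$coefficients
  flagged <- abs(co[, "coef"]) > 10 | co[, "se(coef)"] > 100
  out <- data.frame(
    covariate = rownames(co),
    hr = ifelse(flagged, NA_real_, exp(co[, "coef"])),
    ci_lower = ifelse(flagged, NA_real_,
                      exp(co[, "coef"] - 1.96 * co[, "se(coef)"])),
    ci_upper = ifelse(flagged, NA_real_,
                      exp(co[, "coef"] + 1.96 * co[, "se(coef)"])),
    p_value = co[, "Pr(>|z|)"], flagged = flagged,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  class(out) <- c("cox_result", "data.frame")
  out
}
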