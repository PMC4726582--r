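#' 2x2 classification counts
#'
#' Counts of a binary test against a reference standard: true/false
#' positives and negatives at the patient (or lesion) level.
#'
#' @param tp,fp,fn,tn non-negative integer counts; their sum must be > 0.
#' @return An object of class `confusion2x2`.
#' @export
confusion2x2 <- function(tp, fp, fn, tn) {
  v <- c(tp = unname(tp)[1], fp = unname(fp)[1], fn = unname(fn)[1],
         tn = unname(tn)[1])
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(v) == 0) stop("at least one count must be positive", call. = FALSE)
  structure(as.list(as.integer(v)), names = names(v), class = "confusion2x2")
}

#' @export
print.confusion2x2 <- function(x, ...) {
  cat(sprintf("<confusion2x2> tp %d, fp %d, fn %d, tn %d (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a proportion via beta quantiles:
#' the lower bound is the `alpha/2` quantile of Beta(x, n - x + 1) (0 when
#' x = 0) and the upper bound the `1 - alpha/2` quantile of
#' Beta(x + 1, n - x) (1 when x = n).
#'
#' @param x number of successes, 0 <= x <= n.
#' @param n number of trials, >= 1.
#' @param alpha two-sided error rate; default 0.05 for a 95\% interval.
#' @return Numeric vector `c(lo, hi)` of proportions.
#' @examples
#' clopper_pearson(7, 11)  # 0.308 to 0.891
#' @export
clopper_pearson <- function(x, n, alpha = 0.05) {
  if (!is.finite(x) || !is.finite(n) || n < 1 || x < 0 || x > n ||
      x != round(x) || n != round(n))
    stop("need integers 0 <= x <= n, n >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)",
                                     call. = FALSE)
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo = lo, hi = hi)
}

#' Diagnostic accuracy with exact confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy from a 2x2 table, each with a Clopper-Pearson interval. A
#' metric whose denominator is zero is flagged as undefined (`NA`), never
#' silently reported as 0. The `percent` field renders each defined metric
#' as a whole percent with half-up rounding, the convention used in
#' clinical accuracy tables.
#'
#' @param x a [confusion2x2()].
#' @param alpha two-sided error rate for the intervals.
#' @return An object of class `diag_accuracy`: a list with `metrics` (data
#'   frame: metric, estimate, lo, hi, x, n, defined), `percent` (named
#'   vector of whole percents, `NA` where undefined), `n_positive_ref`,
#'   `n_negative_ref`.
#' @examples
#' diagnostic_accuracy(confusion2x2(tp = 35, fp = 0, fn = 30, tn = 11))
#' @export
diagnostic_accuracy <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "confusion2x2"))
  n <- x$tp + x$fp + x$fn + x$tn
  spec <- list(
    sensitivity = c(x$tp, x$tp + x$fn),
    specificity = c(x$tn, x$tn + x$fp),
    ppv = c(x$tp, x$tp + x$fp),
    npv = c(x$tn, x$tn + x$fn),
    accuracy = c(x$tp + x$tn, n))
  rows <- lapply(names(spec), function(m) {
    num <- spec[[m]][1]; den <- spec[[m]][2]
    if (den == 0) {
      data.frame(metric = m, estimate = NA_real_, lo = NA_real_,
                 hi = NA_real_, x = num, n = den, defined = FALSE)
    } else {
      ci <- clopper_pearson(num, den, alpha)
      data.frame(metric = m, estimate = num / den, lo = ci[["lo"]],
                 hi = ci[["hi"]], x = num, n = den, defined = TRUE)
    }
  })
  metrics <- do.call(rbind, rows)
  percent <- setNames(
    ifelse(metrics$defined, round_half_up(100 * metrics$estimate), NA),
    metrics$metric)
  structure(list(metrics = metrics, percent = percent,
                 n_positive_ref = x$tp + x$fn,
                 n_negative_ref = x$tn + x$fp),
            class = "diag_accuracy")
}

#' @export
print.diag_accuracy <- function(x, ...) {
  cat("<diag_accuracy>\n")
  for (i in seq_len(nrow(x$metrics))) {
    r <- x$metrics[i, ]
    if (r$defined) {
      cat(sprintf("  %-11s %3d%% (%d/%d; 95%%-CI %.1f-%.1f%%)\n",
                  r$metric, x$percent[[r$metric]], r$x, r$n,
                  100 * r$lo, 100 * r$hi))
    } else {
      cat(sprintf("  %-11s undefined (denominator 0)\n", r$metric))
    }
  }
  invisible(x)
}

#' Fisher's exact test (two-sided)
#'
#' Exact two-sided p-value for association in a 2x2 table, using the
#' point-probability rule: the p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table. A table with a
#' zero margin carries no information and returns p = 1 by convention.
#'
#' @param x a 2x2 matrix of non-negative integer counts, or a
#'   [confusion2x2()] (laid out as rows = test, columns = reference).
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(x) {
  if (inherits(x, "confusion2x2"))
    x <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2)
  x <- as.matrix(x)
  if (!all(dim(x) == 2L) || any(x < 0) || any(x != round(x)))
    stop("need a 2x2 table of non-negative integer counts", call. = FALSE)
  if (sum(x) == 0) stop("empty table", call. = FALSE)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) return(1)
  stats::fisher.test(x)$p.value
}

#' Cohen's kappa for two paired raters
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} where
#' \eqn{p_o} is the observed agreement and \eqn{p_e} the expected agreement
#' from the marginal products. Returns `NA` (with a warning) when
#' \eqn{p_e = 1}, where kappa is undefined.
#'
#' @param a,b equal-length categorical vectors (>= 2 ratings).
#' @return Kappa, with attributes `po` and `pe`.
#' @examples
#' cohens_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0))  # chance level: 0
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("'a' and 'b' must be paired sequences of length >= 2", call. = FALSE)
  lev <- sort(unique(c(as.character(a), as.character(b))))
  if (length(lev) < 2)
    stop("need at least 2 observed categories overall", call. = FALSE)
  ta <- factor(as.character(a), levels = lev)
  tb <- factor(as.character(b), levels = lev)
  tab <- table(ta, tb) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (isTRUE(all.equal(pe, 1))) {
    warning("expected agreement is 1: kappa undefined", call. = FALSE)
    k <- NA_real_
  } else {
    k <- (po - pe) / (1 - pe)
  }
  structure(k, po = po, pe = pe)
}

#' Bland-Altman agreement statistics
#'
#' For paired measurements, the differences `d = x - y` are summarized by
#' their mean (with a t-based confidence interval), standard deviation
#' (n - 1 denominator) and the limits of agreement
#' `mean_diff +/- 1.96 * sd_diff`.
#'
#' @param x,y equal-length numeric vectors, n >= 2.
#' @param alpha two-sided error rate for the CI of the mean difference.
#' @return An object of class `agreement_stats`: list with `mean_diff`,
#'   `sd_diff`, `ci_mean`, `loa`, `n`.
#' @export
bland_altman <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 2)
    stop("'x' and 'y' must be paired with n >= 2", call. = FALSE)
  d <- x - y
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  half <- stats::qt(1 - alpha / 2, n - 1) * s / sqrt(n)
  structure(list(mean_diff = m, sd_diff = s,
                 ci_mean = c(lo = m - half, hi = m + half),
                 loa = c(lo = m - 1.96 * s, hi = m + 1.96 * s), n = n),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats> mean diff %.3f (95%%-CI %.3f to %.3f), sd %.3f\n",
    x$mean_diff, x$ci_mean[["lo"]], x$ci_mean[["hi"]], x$sd_diff))
  cat(sprintf("  limits of agreement %.3f to %.3f (n = %d)\n",
              x$loa[["lo"]], x$loa[["hi"]], x$n))
  invisible(x)
}

#' Paired t-test
#'
#' Student's t-test on paired differences: `t = mean(d) / (sd(d)/sqrt(n))`
#' with n - 1 degrees of freedom. Zero-variance differences are an error
#' (the statistic is undefined), not a silent p-value.
#'
#' @param x,y equal-length numeric vectors, n >= 2.
#' @return List with `t`, `p` (two-sided), `mean_diff`, `df`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("'x' and 'y' must be paired with n >= 2", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0)
    stop("zero-variance differences: t statistic undefined", call. = FALSE)
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = unname(tt$estimate), df = unname(tt$parameter))
}
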