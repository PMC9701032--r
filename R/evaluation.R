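# ROC/AUC machinery and the inferential statistics used to report and
# compare classifier performance

# AUC by the Mann-Whitney identity with half-credit for ties
auc_mw <- function(scores, labels) {
  y <- as_case_factor(labels)
  n_pos <- sum(y == "case"); n_neg <- sum(y == "control")
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == "case"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ROC curve points over the unique score thresholds (call positive when
# score >= threshold), plus the endpoints
roc_points <- function(scores, labels) {
  y <- as_case_factor(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y == "case"); n_neg <- sum(y == "control")
  tpr <- vapply(thr, function(t) sum(scores >= t & y == "case") / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == "control") / n_neg, 0)
  tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney pair-counting identity with half-credit for
#' tied scores; when a cutoff is supplied, sensitivity and specificity are
#' evaluated there (`score >= cutoff` is a positive call).
#'
#' @param scores Numeric classifier scores (larger = more case-like).
#' @param labels Two-class labels (`PDAC`/`case` is the positive class).
#' @param cutoff Optional decision cutoff.
#' @return A `roc_result`: list with `auc`, the ROC `points` tibble
#'   (threshold, fpr, tpr), `sensitivity`/`specificity` (at `cutoff`, else
#'   `NA`), `cutoff`, `n_pos`, `n_neg`. Has `autoplot()`, `tidy()` and
#'   `glance()` methods.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2),
#'         c("PDAC", "PDAC", "PDAC", "Healthy", "Healthy", "Healthy"))
#' @export
roc_auc <- function(scores, labels, cutoff = NULL) {
  y <- as_case_factor(labels)
  if (length(unique(y)) < 2L) abort("both classes must be present")
  sens <- spec <- NA_real_
  if (!is.null(cutoff)) {
    sens <- sum(scores >= cutoff & y == "case") / sum(y == "case")
    spec <- sum(scores < cutoff & y == "control") / sum(y == "control")
  }
  structure(list(auc = auc_mw(scores, y), points = roc_points(scores, y),
                 sensitivity = sens, specificity = spec,
                 cutoff = cutoff %||% NA_real_,
                 n_pos = sum(y == "case"), n_neg = sum(y == "control")),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d cases / %d controls)\n",
              x$auc, x$n_pos, x$n_neg))
  if (!is.na(x$sensitivity)) {
    cat(sprintf("  at cutoff %.3f: sensitivity %.3f, specificity %.3f\n",
                x$cutoff, x$sensitivity, x$specificity))
  }
  invisible(x)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact beta-quantile bounds for a binomial proportion, the interval used
#' to report sensitivity and specificity. The lower bound is exactly 0
#' when no success is observed and the upper bound exactly 1 when every
#' trial succeeds.
#'
#' @param successes,trials Non-negative counts, `successes <= trials`,
#'   `trials >= 1`.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `point`, `lower`, `upper`, `level`,
#'   `method = "clopper_pearson"`.
#' @examples
#' clopper_pearson(20, 25)  # 0.80 (0.59-0.93)
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials < 1L) abort("trials must be >= 1")
  if (successes < 0L || successes > trials) {
    abort("successes must lie in [0, trials]")
  }
  a <- (1 - level) / 2
  lower <- if (successes == 0L) 0 else qbeta(a, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    qbeta(1 - a, successes + 1, trials - successes)
  tibble(point = successes / trials, lower = lower, upper = upper,
         level = level, method = "clopper_pearson")
}

# class-stratified bootstrap resample indices
stratified_resample <- function(y) {
  pos <- which(y == "case"); neg <- which(y == "control")
  c(sample(pos, length(pos), replace = TRUE),
    sample(neg, length(neg), replace = TRUE))
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Class-stratified resampling with replacement (prevalence preserved);
#' percentile bounds. The bootstrap variance of the AUC — the ingredient
#' of [auc_compare_T()] — is returned as attribute `variance`.
#'
#' @inheritParams roc_auc
#' @param reps Bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Seed making the resampling deterministic.
#' @return One-row tibble (`point`, `lower`, `upper`, `level`,
#'   `method = "bootstrap_percentile"`) with attributes `variance` and
#'   `aucs` (the replicate values).
#' @export
bootstrap_auc_ci <- function(scores, labels, reps = 1000L, level = 0.95,
                             seed = 1L) {
  if (reps < 100L) abort("reps must be >= 100")
  y <- as_case_factor(labels)
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(b) {
      idx <- stratified_resample(y)
      auc_mw(scores[idx], y[idx])
    }, 0)
  })
  a <- (1 - level) / 2
  ci <- unname(quantile(aucs, c(a, 1 - a), type = 7))
  out <- tibble(point = auc_mw(scores, y), lower = ci[1L], upper = ci[2L],
                level = level, method = "bootstrap_percentile")
  attr(out, "variance") <- var(aucs)
  attr(out, "aucs") <- aucs
  out
}

#' Chi-square variance-ratio test for an AUC difference
#'
#' Compares the AUCs of two score vectors on the same samples with the
#' statistic `T = (AUC_a - AUC_b)^2 / (s2_a + s2_b)`, where each `s2` is
#' the bootstrap variance of the corresponding AUC from class-stratified
#' paired resampling; under the null `T` follows a chi-square distribution
#' with one degree of freedom.
#'
#' @param a,b Score vectors for the same samples.
#' @param labels Two-class labels.
#' @param reps Bootstrap replicates for the variances (default 1000).
#' @param seed Resampling seed.
#' @return One-row tibble: `auc_a`, `auc_b`, `var_a`, `var_b`,
#'   `statistic`, `p_value`, `method = "chi2_T"`. Zero combined variance
#'   with unequal AUCs yields `p = 0` with a warning.
#' @export
auc_compare_T <- function(a, b, labels, reps = 1000L, seed = 1L) {
  if (length(a) != length(b)) abort("a and b must score the same samples")
  y <- as_case_factor(labels)
  boot <- withr::with_seed(seed, {
    t(vapply(seq_len(reps), function(r) {
      idx <- stratified_resample(y)
      c(auc_mw(a[idx], y[idx]), auc_mw(b[idx], y[idx]))
    }, c(0, 0)))
  })
  var_a <- var(boot[, 1L]); var_b <- var(boot[, 2L])
  auc_a <- auc_mw(a, y); auc_b <- auc_mw(b, y)
  denom <- var_a + var_b
  if (denom <= 0) {
    if (auc_a != auc_b) {
      warn("zero combined bootstrap variance with unequal AUCs; p = 0")
      stat <- Inf; p <- 0
    } else {
      stat <- 0; p <- 1
    }
  } else {
    stat <- (auc_a - auc_b)^2 / denom
    p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  }
  tibble(auc_a = auc_a, auc_b = auc_b, var_a = var_a, var_b = var_b,
         statistic = stat, p_value = p, method = "chi2_T")
}

# placement values: for each case, the fraction of controls it outranks
# (ties half-credit), and vice versa
placement_values <- function(scores, y) {
  pos <- scores[y == "case"]; neg <- scores[y == "control"]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp))
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two score vectors measured on
#' the same samples, using the DeLong placement-value covariance estimate
#' and a two-sided normal p-value.
#'
#' @inheritParams auc_compare_T
#' @return One-row tibble: `auc_a`, `auc_b`, `var_a`, `var_b`
#'   (variances of each AUC), `statistic` (squared z), `p_value`,
#'   `method = "delong"`.
#' @export
delong_test <- function(a, b, labels) {
  if (length(a) != length(b)) abort("a and b must score the same samples")
  y <- as_case_factor(labels)
  m <- sum(y == "case"); n <- sum(y == "control")
  if (m < 2L || n < 2L) abort("need at least two samples per class")
  pa <- placement_values(a, y); pb <- placement_values(b, y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  s <- s10 / m + s01 / n
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  v_diff <- s[1L, 1L] + s[2L, 2L] - 2 * s[1L, 2L]
  if (v_diff <= 0) {
    if (isTRUE(all.equal(auc_a, auc_b))) {
      z <- 0
    } else {
      abort("degenerate DeLong variance structure")
    }
  } else {
    z <- (auc_a - auc_b) / sqrt(v_diff)
  }
  tibble(auc_a = auc_a, auc_b = auc_b, var_a = s[1L, 1L], var_b = s[2L, 2L],
         statistic = z^2, p_value = 2 * pnorm(-abs(z)), method = "delong")
}

#' Exact McNemar test for paired sensitivity comparison
#'
#' Among true positive cases, compares two classifiers' binary calls by
#' the exact binomial test on the discordant pairs.
#'
#' @param calls_a,calls_b Logical (or 0/1) detection calls per case by
#'   each classifier.
#' @param truth Optional logical subset selector: only cases with
#'   `truth == TRUE` enter the comparison (defaults to all).
#' @return Two-sided exact p-value; 1 when there is no discordant pair.
#' @examples
#' mcnemar_test(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
mcnemar_test <- function(calls_a, calls_b, truth = NULL) {
  calls_a <- as.logical(calls_a); calls_b <- as.logical(calls_b)
  if (!is.null(truth)) {
    calls_a <- calls_a[as.logical(truth)]
    calls_b <- calls_b[as.logical(truth)]
  }
  n10 <- sum(calls_a & !calls_b)
  n01 <- sum(!calls_a & calls_b)
  if (n10 + n01 == 0L) return(1)
  binom.test(n10, n10 + n01, p = 0.5)$p.value
}

#' Hypergeometric enrichment of a marker panel in a reference set
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between a panel and a reference gene/region set drawn from a
#' common universe.
#'
#' @param panel,reference Character vectors (or sets) of identifiers, both
#'   subsets of the universe.
#' @param universe Total universe size (integer), or a character vector
#'   whose length is used.
#' @return Upper-tail p-value for overlap >= observed.
#' @export
hypergeometric_enrichment <- function(panel, reference, universe) {
  n_univ <- if (is.numeric(universe)) as.integer(universe) else
    length(unique(universe))
  panel <- unique(panel); reference <- unique(reference)
  k <- length(intersect(panel, reference))
  if (length(panel) > n_univ || length(reference) > n_univ) {
    abort("panel/reference larger than the universe")
  }
  phyper(k - 1L, length(reference), n_univ - length(reference),
         length(panel), lower.tail = FALSE)
}
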