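test_that("AUC follows the Mann-Whitney identity with tie half-credit", {
  labels <- rep(c("case", "control"), each = 3)
  # exhaustive pair counting: 8 of 9 pairs correctly ordered
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2), labels)
  expect_equal(r$auc, 8 / 9)

  expect_equal(roc_auc(c(3, 2, 1, 0.5, 0.2, 0.1), labels)$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 6), labels)$auc, 0.5)
  expect_error(roc_auc(1:3, rep("case", 3)), "class")

  # sensitivity/specificity at a supplied cutoff (score >= cutoff is a call)
  at <- roc_auc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2), labels, cutoff = 0.7)
  expect_equal(at$sensitivity, 2 / 3)
  expect_equal(at$specificity, 2 / 3)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(1)
  for (rep_i in 1:20) {
    n <- sample(5:30, 1)
    scores <- rnorm(2 * n)
    labels <- rep(c("case", "control"), each = n)
    a0 <- roc_auc(scores, labels)$auc
    expect_equal(roc_auc(exp(scores), labels)$auc, a0)
    expect_equal(roc_auc(qlogis(plogis(scores)), labels)$auc, a0,
                 tolerance = 1e-12)
    expect_equal(roc_auc(scores * 3 + 7, labels)$auc, a0)
  }
})

test_that("ROC points are monotone in both axes", {
  set.seed(2)
  r <- roc_auc(rnorm(60), rep(c("case", "control"), 30))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("Clopper-Pearson intervals agree with binom.test and hit the edges", {
  for (case in list(c(20, 25), c(33, 37), c(20, 23), c(26, 34), c(7, 12))) {
    ci <- clopper_pearson(case[1], case[2])
    bt <- binom.test(case[1], case[2])$conf.int
    expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-10)
  }
  expect_equal(clopper_pearson(0, 15)$lower, 0)
  expect_equal(clopper_pearson(15, 15)$upper, 1)
  expect_error(clopper_pearson(5, 0), "trials")
  expect_error(clopper_pearson(6, 5), "successes")
})

test_that("bootstrap AUC interval is deterministic, stratified and collapses when separable", {
  labels <- rep(c("case", "control"), each = 20)
  sep_scores <- c(runif(20, 0.8, 1), runif(20, 0, 0.2))
  ci <- bootstrap_auc_ci(sep_scores, labels, reps = 300, seed = 4)
  expect_equal(c(ci$lower, ci$upper), c(1, 1))

  set.seed(5)
  scores <- rnorm(40)
  a <- bootstrap_auc_ci(scores, labels, reps = 300, seed = 11)
  b <- bootstrap_auc_ci(scores, labels, reps = 300, seed = 11)
  expect_identical(a, b)
  c_ <- bootstrap_auc_ci(scores, labels, reps = 300, seed = 12)
  expect_false(identical(c(a$lower, a$upper), c(c_$lower, c_$upper)))
  expect_gt(attr(a, "variance"), 0)
  expect_error(bootstrap_auc_ci(scores, labels, reps = 50, seed = 1), "reps")
})

test_that("bootstrap percentile interval covers the null AUC at nominal rate", {
  set.seed(6)
  hits <- replicate(100, {
    labels <- rep(c("case", "control"), each = 50)
    scores <- rnorm(100)
    ci <- bootstrap_auc_ci(scores, labels, reps = 200,
                           seed = sample.int(1e6, 1))
    ci$lower <= 0.5 && 0.5 <= ci$upper
  })
  expect_gte(mean(hits), 0.9)
})

test_that("the variance-ratio AUC comparison behaves at the extremes", {
  labels <- rep(c("case", "control"), each = 30)
  set.seed(7)
  a <- rnorm(60)
  self <- auc_compare_T(a, a, labels, reps = 200, seed = 1)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  perfect <- c(runif(100, 0.7, 1), runif(100, 0, 0.3))
  flat <- rep(0.5, 200)
  big_labels <- rep(c("case", "control"), each = 100)
  # both bootstrap variances vanish here, triggering the degenerate branch
  expect_warning(
    cmp <- auc_compare_T(perfect, flat, big_labels, reps = 200, seed = 2),
    "zero combined"
  )
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$auc_a, 1)
  expect_equal(cmp$auc_b, 0.5)
})

test_that("the DeLong test matches pROC and hand-computed placements", {
  set.seed(8)
  n <- 40
  labels <- rep(c("case", "control"), each = n)
  base <- c(rnorm(n, 0.8), rnorm(n, 0))
  a <- base + rnorm(2 * n, 0, 0.5)
  b <- base + rnorm(2 * n, 0, 1.5)

  ours <- delong_test(a, b, labels)
  ref <- pROC::roc.test(
    pROC::roc(labels, a, levels = c("control", "case"), direction = "<",
              quiet = TRUE),
    pROC::roc(labels, b, levels = c("control", "case"), direction = "<",
              quiet = TRUE),
    method = "delong", paired = TRUE
  )
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  expect_equal(ours$auc_a, as.numeric(ref$roc1$auc))

  # self-comparison is exactly null
  expect_equal(delong_test(a, a, labels)$p_value, 1)

  # hand-computed placement values on a tiny example
  toy_scores <- c(0.9, 0.6, 0.3, 0.8, 0.4, 0.1)
  toy_labels <- rep(c("case", "control"), each = 3)
  pl <- haplomark:::placement_values(
    toy_scores, haplomark:::as_case_factor(toy_labels))
  expect_equal(pl$v10, c(1, 2 / 3, 1 / 3))
  expect_equal(pl$v01, c(1 / 3, 2 / 3, 1))
  expect_equal(mean(pl$v10), roc_auc(toy_scores, toy_labels)$auc)
  expect_equal(mean(pl$v01), roc_auc(toy_scores, toy_labels)$auc)
})

test_that("DeLong and the variance-ratio test agree on simulated alternatives", {
  set.seed(9)
  for (rep_i in 1:5) {
    n <- 50
    labels <- rep(c("case", "control"), each = n)
    a <- c(rnorm(n, 1.2), rnorm(n))    # clearly informative
    b <- c(rnorm(n, 0.2), rnorm(n))    # weakly informative
    dl <- delong_test(a, b, labels)
    vt <- auc_compare_T(a, b, labels, reps = 300, seed = rep_i)
    expect_equal(sign(dl$auc_a - dl$auc_b), sign(vt$auc_a - vt$auc_b))
    # same order of magnitude: within a factor of 100 on the log scale
    if (dl$p_value > 1e-12 && vt$p_value > 1e-12) {
      expect_lt(abs(log10(dl$p_value) - log10(vt$p_value)), 2)
    }
  }
})

test_that("exact McNemar arithmetic on discordant pairs", {
  expect_equal(mcnemar_test(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(mcnemar_test(rep(TRUE, 10), rep(FALSE, 10)), 2 * 0.5^10)
  expect_equal(mcnemar_test(c(TRUE, FALSE), c(FALSE, TRUE)), 1)
  # truth subset restricts the comparison to true positives
  expect_equal(mcnemar_test(c(TRUE, TRUE, TRUE), c(FALSE, FALSE, TRUE),
                            truth = c(TRUE, TRUE, FALSE)),
               2 * 0.5^2)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # full enumeration over all panels of size 6 from a universe of 18
  universe <- sprintf("g%02d", 1:18)
  reference <- universe[1:8]
  panel <- universe[c(1:5, 10)]          # overlap 5
  p_pkg <- hypergeometric_enrichment(panel, reference, 18)
  combos <- utils::combn(18, 6)
  overlaps <- colSums(combos <= 8)
  p_enum <- mean(overlaps >= 5)
  expect_equal(p_pkg, p_enum, tolerance = 1e-12)

  expect_equal(hypergeometric_enrichment(universe, universe, 18), 1)
  expect_gt(hypergeometric_enrichment(universe[17:18], reference, 18), 0.7)
  expect_error(hypergeometric_enrichment(sprintf("x%d", 1:30), reference, 18),
               "universe")
})
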