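make_metric_list <- function(signal, noise_template, signal_metric = "mhl3") {
  vals <- lapply(mhb_metric_names, function(m) {
    v <- noise_template()
    dimnames(v) <- dimnames(signal)
    v
  })
  names(vals) <- mhb_metric_names
  vals[[signal_metric]] <- signal
  vals
}

test_that("measurement selection finds the informative metric and matches glm", {
  set.seed(31)
  n <- 30
  samples <- c(sprintf("ca%02d", 1:n), sprintf("co%02d", 1:n))
  labels <- setNames(rep(c("case", "control"), each = n), samples)
  signal <- matrix(c(rnorm(n, 0.6, 0.15), rnorm(n, 0.42, 0.15)), 2 * n, 1,
                   dimnames = list(samples, "m1"))
  vals <- make_metric_list(signal, function() {
    matrix(runif(2 * n, 0.2, 0.8), 2 * n, 1)
  })
  mm <- mm_from_values(vals)
  sel <- select_measurement(mm, labels, "m1")
  expect_equal(sel$metric, "mhl3")
  expect_false(sel$separation)

  # independent GLM fit of the winning measurement
  fit <- glm(I(labels == "case") ~ signal[, 1], family = binomial())
  expect_equal(sel$wald_p, unname(summary(fit)$coefficients[2, 4]),
               tolerance = 1e-8)
})

test_that("identical measurements tie-break to the fixed metric order", {
  set.seed(32)
  n <- 15
  samples <- c(sprintf("ca%02d", 1:n), sprintf("co%02d", 1:n))
  labels <- setNames(rep(c("case", "control"), each = n), samples)
  base <- matrix(c(rnorm(n, 0.6, 0.15), rnorm(n, 0.4, 0.15)), 2 * n, 1,
                 dimnames = list(samples, "m1"))
  vals <- setNames(lapply(mhb_metric_names, function(m) base),
                   mhb_metric_names)
  sel <- select_measurement(mm_from_values(vals), labels, "m1")
  expect_equal(sel$metric, "amf")

  expect_error(select_measurement(mm_from_values(vals),
                                  setNames(rep("case", 2 * n), samples),
                                  "m1"),
               "2 classes|constant")
})

test_that("perfect separation is flagged and produces a finite Firth p", {
  n <- 12
  samples <- c(sprintf("ca%02d", 1:n), sprintf("co%02d", 1:n))
  labels <- setNames(rep(c("case", "control"), each = n), samples)
  sep <- matrix(c(runif(n, 0.8, 0.95), runif(n, 0.05, 0.2)), 2 * n, 1,
                dimnames = list(samples, "m1"))
  vals <- setNames(lapply(mhb_metric_names, function(m) sep), mhb_metric_names)
  sel <- select_measurement(mm_from_values(vals), labels, "m1")
  expect_true(sel$separation)
  expect_true(is.finite(sel$wald_p) && sel$wald_p > 0 && sel$wald_p < 0.05)
})

test_that("chi-square window screen reproduces hand contingency results", {
  n <- 20
  samples <- c(sprintf("ca%02d", 1:n), sprintf("co%02d", 1:n))
  labels <- haplomark:::as_case_factor(
    setNames(rep(c("case", "control"), each = n), samples))

  # identical distributions -> statistic 0, p 1
  same <- haplomark:::chi_square_windows(rep(c(0.15, 0.85), n), labels)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # groups in disjoint windows: 2x2 table 20/0 | 0/20 -> chi2 = 40, df 1
  apart <- haplomark:::chi_square_windows(c(rep(0.95, n), rep(0.05, n)),
                                          labels)
  expect_equal(apart$statistic, 40)
  expect_equal(apart$df, 1L)
  expect_lt(apart$p_value, 1e-9)
  expect_equal(apart$p_value, pchisq(40, 1, lower.tail = FALSE))

  # the closed right edge puts exactly 1.0 into the last window
  edge <- haplomark:::chi_square_windows(c(rep(1.0, n), rep(0.95, n)), labels)
  expect_equal(edge$statistic, 0)  # both land in window 10

  one_bin <- haplomark:::chi_square_windows(rep(0.5, 2 * n), labels)
  expect_equal(one_bin$p_value, 1)
})

test_that("preprocessor scaling follows the median/IQR hand arithmetic", {
  train <- tibble::tibble(sample_id = sprintf("s%d", 1:5),
                          a = c(0.1, 0.2, 0.3, 0.4, 0.5),
                          b = c(0.3, 0.1, 0.5, 0.2, 0.4))
  prep <- fit_preprocessor(train, k = 2L)
  scaled <- apply_preprocessor(prep, train)
  # column a: median 0.3, IQR 0.2 -> 0.5 maps to 1.0
  expect_equal(unname(scaled[5, "a"]), 1.0)
  expect_equal(unname(scaled[1, "a"]), -1.0)
  # no missing values: imputation is the identity (affine transform only)
  expect_equal(scaled[, "a"], (train$a - 0.3) / 0.2, ignore_attr = TRUE)

  flat <- dplyr::mutate(train, c = 0.7)
  expect_warning(prep2 <- fit_preprocessor(flat, k = 2L), "zero IQR")
  expect_false("c" %in% prep2$markers)
})

test_that("KNN imputation fills a fully missing marker from neighbours", {
  set.seed(41)
  train <- matrix(rnorm(20 * 3, 0.5, 0.2), 20, 3,
                  dimnames = list(sprintf("t%02d", 1:20), c("a", "b", "c")))
  prep <- fit_preprocessor(train, k = 5L)
  newdata <- matrix(c(NA, train[3, "b"], train[3, "c"]), 1, 3,
                    dimnames = list("new", c("a", "b", "c")))
  imp <- apply_preprocessor(prep, newdata)
  expect_true(is.finite(imp[1, "a"]))
  # nearest donors in the scaled (b, c) plane, sample 3 among them
  d <- sqrt(colMeans((t(prep$train_scaled[, c("b", "c")]) -
                        haplomark:::as_marker_matrix(
                          sweep(sweep(newdata, 2, prep$centre), 2,
                                prep$width, "/"))[1, c("b", "c")])^2))
  nb <- order(d)[1:5]
  expect_equal(unname(imp[1, "a"]), mean(prep$train_scaled[nb, "a"]))
})

test_that("incremental selection rejects redundant noise and recovers signal", {
  set.seed(51)
  n <- 50
  labels <- rep(c("case", "control"), each = n)
  strong <- c(rnorm(n, 1), rnorm(n, -1))
  accept_count <- 0L
  for (s in 1:5) {
    set.seed(100 + s)
    x <- cbind(strong = strong, dup = rnorm(2 * n))
    out <- incremental_select(x, labels, c("strong", "dup"), folds = 10L,
                              seed = s)
    if ("dup" %in% out$selected) accept_count <- accept_count + 1L
  }
  expect_lt(accept_count / 5, 0.5)

  # single candidate: trivially selected with a one-row trace
  one <- incremental_select(cbind(strong = strong), labels, "strong",
                            folds = 10L, seed = 1L)
  expect_equal(one$selected, "strong")
  expect_equal(nrow(one$trace), 1L)

  few <- c(1:4, n + (1:4))
  expect_error(incremental_select(cbind(strong = strong)[few, , drop = FALSE],
                                  labels[few], "strong", folds = 10L,
                                  seed = 1L),
               "folds")
})

test_that("informative markers are recovered among noise with high held-out AUC", {
  set.seed(61)
  n <- 50; p_noise <- 95
  make_x <- function(n_per) {
    informative <- vapply(1:5, function(j) {
      c(rnorm(n_per, 0.65, 0.2), rnorm(n_per, 0.15, 0.2))
    }, numeric(2 * n_per))
    colnames(informative) <- sprintf("inf%d", 1:5)
    noise <- matrix(rnorm(2 * n_per * p_noise, 0.4, 0.2), 2 * n_per, p_noise,
                    dimnames = list(NULL, sprintf("ns%02d", 1:p_noise)))
    cbind(informative, noise)
  }
  x <- make_x(n)
  labels <- rep(c("case", "control"), each = n)
  ranked <- c(sprintf("inf%d", 1:5), sprintf("ns%02d", 1:p_noise))
  out <- incremental_select(x, labels, ranked, folds = 10L, seed = 3L)
  expect_gte(sum(sprintf("inf%d", 1:5) %in% out$selected), 4L)

  clf <- train_classifier(x, labels, out$selected, seed = 3L)
  x_test <- make_x(40)
  test_labels <- rep(c("case", "control"), each = 40)
  auc <- roc_auc(predict(clf, x_test), test_labels)$auc
  expect_gte(auc, 0.9)
})

test_that("the final SVM separates separable data and serialises exactly", {
  set.seed(71)
  n <- 40
  x <- cbind(a = c(rnorm(n, 2), rnorm(n, -2)),
             b = c(rnorm(n, 2), rnorm(n, -2)))
  labels <- rep(c("case", "control"), each = n)
  clf <- train_classifier(x, labels, seed = 1L)
  expect_equal(clf$train_auc, 1.0)
  calls <- predict(clf, x, type = "class")
  expect_equal(as.character(calls), ifelse(labels == "case", "case", "control"))

  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(clf, path)
  reloaded <- readRDS(path)
  expect_lt(max(abs(predict(reloaded, x) - predict(clf, x))), 1e-9)

  expect_error(train_classifier(x, rep("case", 2 * n), seed = 1L),
               "2 classes|single class")
})

test_that("label permutation keeps cross-validated AUC near chance", {
  set.seed(81)
  n <- 40
  x <- matrix(rnorm(2 * n * 5), 2 * n, 5,
              dimnames = list(NULL, sprintf("m%d", 1:5)))
  labels <- sample(rep(c("case", "control"), each = n))
  y <- haplomark:::as_case_factor(labels)
  fold_id <- haplomark:::make_folds(y, 10L, seed = 2L)
  auc <- haplomark:::cv_mean_auc(x, y, fold_id)
  expect_lt(abs(auc - 0.5), 0.12)
})

test_that("fold assignment and scores are reproducible under a fixed seed", {
  labels <- rep(c("case", "control"), each = 25)
  f1 <- haplomark:::make_folds(labels, 10L, seed = 9L)
  f2 <- haplomark:::make_folds(labels, 10L, seed = 9L)
  expect_identical(f1, f2)
  expect_false(identical(f1, haplomark:::make_folds(labels, 10L, seed = 10L)))
  # stratified: every fold carries both classes
  expect_true(all(table(f1[labels == "case"]) > 0))
  expect_true(all(table(f1[labels == "control"]) > 0))
})

test_that("scaling invariance: affine re-expression of a marker is absorbed", {
  set.seed(91)
  train <- matrix(runif(30 * 2, 0, 1), 30, 2,
                  dimnames = list(sprintf("s%02d", 1:30), c("a", "b")))
  prep1 <- fit_preprocessor(train, k = 3L)
  rescaled <- train
  rescaled[, "a"] <- 10 + 5 * rescaled[, "a"]
  prep2 <- fit_preprocessor(rescaled, k = 3L)
  expect_equal(apply_preprocessor(prep1, train),
               apply_preprocessor(prep2, rescaled), tolerance = 1e-12)
})

test_that("the combined CA19-9 model degrades gracefully and gains when complementary", {
  set.seed(95)
  n <- 60
  labels <- rep(c("case", "control"), each = n)
  score <- plogis(c(rnorm(n, 1.2), rnorm(n, -1.2)))

  # uninformative CA19-9 (identical distribution): AUC equals the parent
  flat_ca <- rep(10, 2 * n)
  comb <- combine_ca199(score, flat_ca, labels)
  expect_equal(comb$terms, "score")
  expect_equal(comb$auc, roc_auc(score, labels)$auc, tolerance = 0.02)

  # complementary independent signal improves held-out AUC
  make_set <- function(n_per) {
    list(score = plogis(c(rnorm(n_per, 0.85), rnorm(n_per, -0.85))),
         ca = exp(c(rnorm(n_per, 3.5, 1), rnorm(n_per, 1.5, 1))),
         labels = rep(c("case", "control"), each = n_per))
  }
  tr <- make_set(80); te <- make_set(80)
  cm <- combine_ca199(tr$score, tr$ca, tr$labels)
  pred <- predict(cm, tibble::tibble(score = te$score, ca19_9 = te$ca))
  auc_comb <- roc_auc(pred, te$labels)$auc
  auc_parents <- c(roc_auc(te$score, te$labels)$auc,
                   roc_auc(log10(te$ca + 1), te$labels)$auc)
  expect_gt(auc_comb, max(auc_parents))

  # constant classifier score: the model reduces to CA19-9 alone
  const <- combine_ca199(rep(0.5, 2 * n), exp(c(rnorm(n, 4), rnorm(n, 1))),
                         labels)
  expect_equal(const$terms, "log_ca")

  expect_error(combine_ca199(score, rep(NA_real_, 2 * n), labels),
               "CA19-9")
})
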