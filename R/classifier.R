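# incremental 10-fold cross-validated SVM feature selection, final SVM
# classifier with probability link and decision cutoff, and the CA19-9
# combinatorial logistic model

# stratified fold assignment, deterministic under seed
make_folds <- function(labels, folds, seed) {
  labels <- as_case_factor(labels)
  if (length(labels) < folds) abort("fewer samples than folds")
  assign <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}

# linear-kernel SVM decision values oriented so larger = more case-like
svm_decision <- function(fit, newdata) {
  pr <- predict(fit, newdata, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  pos_first <- strsplit(colnames(attr(pr, "decision.values"))[1L], "/")[[1L]][1L]
  if (pos_first != "case") dv <- -dv
  dv
}

fit_svm <- function(x, y, cost = 1, kernel = "linear") {
  e1071::svm(x = x, y = y, kernel = kernel, cost = cost, scale = FALSE,
             probability = FALSE)
}

# mean over folds of the held-fold AUC of an SVM on the given columns
cv_mean_auc <- function(x, y, fold_id, cost = 1, kernel = "linear") {
  aucs <- vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
      return(NA_real_)
    }
    fit <- fit_svm(x[tr, , drop = FALSE], y[tr], cost, kernel)
    auc_mw(svm_decision(fit, x[!tr, , drop = FALSE]), y[!tr])
  }, 0)
  mean(aucs, na.rm = TRUE)
}

#' Incremental cross-validated marker selection
#'
#' Greedy forward selection over markers ranked by ascending regional
#' measurement p-value. The accepted set starts with the top-ranked
#' marker. Each further marker is added provisionally, the mean 10-fold
#' cross-validated AUC of a support vector machine on the enlarged set is
#' computed with the same stratified fold assignment throughout (fixed by
#' `seed`), and the marker is accepted when that AUC does not fall below
#' the accepted set's AUC (ties accept).
#'
#' @param x Preprocessed numeric matrix (samples x markers), as produced
#'   by [apply_preprocessor()].
#' @param labels Two-class labels aligned with the rows of `x`.
#' @param ranked_markers Marker column names in ascending p-value order.
#' @param folds Number of CV folds (default 10).
#' @param seed Seed fixing the fold assignment.
#' @param cost,kernel SVM parameters (defaults: linear kernel, C = 1).
#' @return List with `selected` (accepted markers in acceptance order) and
#'   `trace`, a tibble with one row per tested marker (`step`, `marker`,
#'   `cv_auc`, `accepted`, `n_selected`).
#' @export
incremental_select <- function(x, labels, ranked_markers, folds = 10L,
                               seed = 1L, cost = 1, kernel = "linear") {
  y <- as_case_factor(labels)
  if (nrow(x) < folds) abort("fewer samples than folds")
  ranked_markers <- ranked_markers[ranked_markers %in% colnames(x)]
  if (!length(ranked_markers)) abort("no ranked markers present in x")
  fold_id <- make_folds(y, folds, seed)

  selected <- ranked_markers[1L]
  best <- cv_mean_auc(x[, selected, drop = FALSE], y, fold_id, cost, kernel)
  trace <- list(tibble(step = 1L, marker = selected, cv_auc = best,
                       accepted = TRUE, n_selected = 1L))
  for (s in seq_along(ranked_markers)[-1L]) {
    m <- ranked_markers[s]
    cand <- c(selected, m)
    auc <- cv_mean_auc(x[, cand, drop = FALSE], y, fold_id, cost, kernel)
    accept <- !is.na(auc) && auc >= best
    if (accept) { selected <- cand; best <- auc }
    trace[[s]] <- tibble(step = s, marker = m, cv_auc = auc,
                         accepted = accept, n_selected = length(selected))
  }
  list(selected = selected, trace = bind_rows(trace))
}

#' Train the final SVM plasma classifier
#'
#' Fits the support vector machine on all training samples over the
#' selected markers, maps the signed margin through a logistic link fitted
#' on the training decision values to a probability-like score in
#' `[0, 1]`, and sets the decision cutoff on the training ROC — by
#' Youden's J by default, or at a fixed specificity.
#'
#' @param x Preprocessed training matrix (samples x markers).
#' @param labels Two-class training labels.
#' @param markers Selected marker columns (default: all columns of `x`).
#' @param seed Stored for provenance (the linear SVM fit itself is
#'   deterministic).
#' @param cost,kernel SVM parameters.
#' @param cutoff_method `"youden"` (default) or `"specificity"`.
#' @param specificity Target specificity when
#'   `cutoff_method = "specificity"` (default 0.89).
#' @return An `mhb_classifier` with the fitted SVM, link coefficients,
#'   cutoff and training scores; score new samples with `predict()`.
#' @export
train_classifier <- function(x, labels, markers = colnames(x), seed = 1L,
                             cost = 1, kernel = "linear",
                             cutoff_method = c("youden", "specificity"),
                             specificity = 0.89) {
  y <- as_case_factor(labels)
  if (length(unique(y)) < 2L) abort("training labels contain a single class")
  cutoff_method <- match.arg(cutoff_method)
  x <- x[, markers, drop = FALSE]
  fit <- fit_svm(x, y, cost, kernel)
  dv <- svm_decision(fit, x)
  link <- platt_link(dv, y)
  score <- plogis(link[1L] + link[2L] * dv)
  cutoff <- choose_cutoff(score, y, cutoff_method, specificity)
  structure(list(markers = markers, svm = fit, link = link, cutoff = cutoff,
                 cutoff_method = cutoff_method, cost = cost, kernel = kernel,
                 seed = seed, train_scores = score,
                 train_labels = y, train_auc = auc_mw(score, y)),
            class = "mhb_classifier")
}

# logistic squashing of the margin; glm may warn on separable data, where
# the squashed score saturates harmlessly
platt_link <- function(dv, y) {
  fit <- suppressWarnings(glm(I(y == "case") ~ dv, family = binomial()))
  co <- coef(fit)
  if (anyNA(co) || co[2L] <= 0) co <- c(0, 1)  # degenerate margin: identity link
  unname(co)
}

choose_cutoff <- function(score, y, method, specificity) {
  roc <- roc_points(score, y)
  if (method == "youden") {
    j <- roc$tpr - roc$fpr
    roc$threshold[which.max(j)]
  } else {
    ok <- which(1 - roc$fpr >= specificity)
    if (!length(ok)) return(max(roc$threshold))
    cand <- roc[ok, ]
    cand$threshold[which.max(cand$tpr)]
  }
}

#' Score new samples with a trained classifier
#'
#' @param object An `mhb_classifier`.
#' @param newdata Preprocessed matrix containing the classifier's marker
#'   columns.
#' @param type `"score"` (default) for the probability-like score,
#'   `"class"` for the thresholded call (`score >= cutoff` is a case
#'   call).
#' @param ... Unused.
#' @return Numeric scores or a factor of calls.
#' @export
predict.mhb_classifier <- function(object, newdata,
                                   type = c("score", "class"), ...) {
  type <- match.arg(type)
  dv <- svm_decision(object$svm, newdata[, object$markers, drop = FALSE])
  score <- plogis(object$link[1L] + object$link[2L] * dv)
  if (type == "score") return(unname(score))
  factor(ifelse(score >= object$cutoff, "case", "control"),
         levels = c("control", "case"))
}

#' @export
print.mhb_classifier <- function(x, ...) {
  cat(sprintf("<mhb_classifier> %d markers, %s SVM (C = %g)\n",
              length(x$markers), x$kernel, x$cost))
  cat(sprintf("  training AUC %.3f, cutoff %.3f (%s)\n",
              x$train_auc, x$cutoff, x$cutoff_method))
  invisible(x)
}

#' Combine the methylation classifier with serum CA19-9
#'
#' Logistic regression of the class label on the classifier score and
#' `log10(CA19-9 + 1)` (the transform tames the heavy right skew of U/ml
#' values). Samples with missing CA19-9 are excluded. A constant covariate
#' drops out of the fit, so the combined model degrades gracefully to the
#' informative parent.
#'
#' @param scores Classifier scores.
#' @param ca19_9 CA19-9 levels in U/ml (`NA` = not measured).
#' @param labels Two-class labels.
#' @return An `mhb_combined` object: the fitted `glm`, the included sample
#'   index, per-sample combined probabilities and a Youden cutoff.
#' @export
combine_ca199 <- function(scores, ca19_9, labels) {
  y <- as_case_factor(labels)
  keep <- !is.na(ca19_9)
  if (!any(keep)) abort("all samples lack CA19-9 values")
  dat <- tibble(y01 = as.integer(y[keep] == "case"),
                score = scores[keep],
                log_ca = log10(ca19_9[keep] + 1))
  terms <- c("score", "log_ca")[vapply(dat[c("score", "log_ca")],
                                       function(v) sd(v) > 0, TRUE)]
  if (!length(terms)) abort("both covariates are constant")
  fit <- suppressWarnings(
    glm(stats::reformulate(terms, response = "y01"), data = dat,
        family = binomial())
  )
  prob <- unname(predict(fit, type = "response"))
  structure(list(fit = fit, terms = terms, included = which(keep),
                 probabilities = prob,
                 cutoff = choose_cutoff(prob, y[keep], "youden", NA),
                 auc = auc_mw(prob, y[keep])),
            class = "mhb_combined")
}

#' @export
#' @rdname combine_ca199
#' @param object An `mhb_combined` model.
#' @param newdata Tibble/data frame with columns `score` and `ca19_9`.
#' @param ... Unused.
predict.mhb_combined <- function(object, newdata, ...) {
  dat <- tibble(score = newdata$score,
                log_ca = log10(newdata$ca19_9 + 1))
  unname(predict(object$fit, newdata = dat, type = "response"))
}

#' @export
print.mhb_combined <- function(x, ...) {
  cat(sprintf("<mhb_combined> terms: %s; AUC %.3f on %d samples\n",
              paste(x$terms, collapse = " + "), x$auc, length(x$included)))
  invisible(x)
}
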