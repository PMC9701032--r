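# broom-style tidiers and ggplot2 autoplot methods

#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_point
#'   geom_step labs theme_minimal coord_equal geom_tile scale_fill_viridis_c
#' @export
ggplot2::autoplot

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$points

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, sensitivity = x$sensitivity,
         specificity = x$specificity, cutoff = x$cutoff,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step(linewidth = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' @method tidy mhb_classifier
#' @export
tidy.mhb_classifier <- function(x, ...) {
  w <- if (x$kernel == "linear") {
    drop(t(x$svm$coefs) %*% x$svm$SV)
  } else {
    rep(NA_real_, length(x$markers))
  }
  tibble(marker = x$markers, weight = unname(w[x$markers]))
}

#' @method glance mhb_classifier
#' @export
glance.mhb_classifier <- function(x, ...) {
  tibble(n_markers = length(x$markers), kernel = x$kernel, cost = x$cost,
         train_auc = x$train_auc, cutoff = x$cutoff,
         cutoff_method = x$cutoff_method)
}

#' @method tidy mhb_combined
#' @export
tidy.mhb_combined <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1L], std_error = sm[, 2L],
         statistic = sm[, 3L], p_value = sm[, 4L])
}

#' @method glance mhb_combined
#' @export
glance.mhb_combined <- function(x, ...) {
  tibble(auc = x$auc, cutoff = x$cutoff, n = length(x$included),
         terms = paste(x$terms, collapse = "+"))
}

#' @method autoplot metric_matrix
#' @export
autoplot.metric_matrix <- function(object, metric = "amf", ...) {
  long <- as_tibble(object) %>% filter(.data$metric == !!metric)
  ggplot(long, aes(x = .data$region_id, y = .data$sample_id,
                   fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey85") +
    labs(x = "Region", y = "Sample", fill = metric) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot the incremental-selection CV trace
#'
#' @param trace The `trace` tibble from [incremental_select()] (or a
#'   `haplomark_run`'s `selection$trace`).
#' @return A ggplot: mean CV AUC at each tested marker, accepted markers
#'   highlighted.
#' @export
plot_selection_trace <- function(trace) {
  ggplot(trace, aes(x = .data$step, y = .data$cv_auc)) +
    geom_line(colour = "grey70") +
    geom_point(aes(colour = .data$accepted)) +
    labs(x = "Marker rank", y = "Mean CV AUC", colour = "Accepted") +
    theme_minimal()
}
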