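# regional measurement selection: pick, per marker region, the measurement
# that best separates cases from controls

#' Markers detected in a sufficient fraction of samples
#'
#' A marker counts as detected in a sample when its depth reaches the
#' matrix's `min_depth` (i.e. its measurements are not blanked by the depth
#' rule). Markers detected in fewer than `min_detect` of the samples are
#' dropped before measurement selection.
#'
#' @param matrix A `metric_matrix`.
#' @param min_detect Minimum detected fraction (default 0.9).
#' @return Character vector of retained region ids.
#' @export
markers_detected <- function(matrix, min_detect = 0.9) {
  det <- colMeans(matrix$depth >= matrix$min_depth)
  matrix$region_ids[det >= min_detect]
}

# Firth bias-reduced logistic regression for a single covariate; fallback
# under perfect separation. Newton-Raphson on the modified score
# U*(beta) = X'(y - p + h (1/2 - p)).
firth_logistic <- function(x, y, max_iter = 50L, tol = 1e-8) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    XtW <- t(X * w)
    info <- XtW %*% X
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((X %*% inv) * (X * w))
    u <- drop(t(X) %*% (y - p + h * (0.5 - p)))
    step <- drop(inv %*% u)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  info <- t(X * (p * (1 - p))) %*% X
  se <- sqrt(diag(solve(info)))
  z <- beta[2L] / se[2L]
  list(slope = beta[2L], p_value = 2 * pnorm(-abs(z)))
}

# Wald p-value of the slope of logit(label) ~ value; detects (quasi-)
# separation and refits with Firth penalisation.
logistic_slope_p <- function(x, y01) {
  sep <- FALSE
  p_val <- NA_real_
  withCallingHandlers({
    fit <- glm(y01 ~ x, family = binomial())
    sm <- summary(fit)$coefficients
    if (nrow(sm) < 2L || abs(coef(fit)[2L]) > 15) {
      sep <- TRUE
    } else {
      p_val <- unname(sm[2L, 4L])
    }
  }, warning = function(w) {
    if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
      sep <<- TRUE
    }
    invokeRestart("muffleWarning")
  })
  if (sep) {
    fr <- firth_logistic(x, y01)
    return(list(p_value = fr$p_value, separation = TRUE))
  }
  list(p_value = p_val, separation = FALSE)
}

#' Select the regional measurement for a marker by logistic regression
#'
#' For one marker region, fits an intercept-plus-slope logistic regression
#' of the class label on each of the seven measurements separately and
#' returns the measurement whose slope has the smallest two-sided Wald
#' p-value. Ties are broken by the fixed measurement order
#' [mhb_metric_names]. Under perfect separation the p-value comes from a
#' Firth-penalised refit and the record is flagged.
#'
#' @param matrix A `metric_matrix`.
#' @param labels Two-class labels aligned with (or named by) the samples.
#' @param marker Region id.
#' @param metrics Candidate measurements (default all seven).
#' @param min_per_group Minimum non-missing values per class for a
#'   measurement to enter the race (default 3).
#' @return One-row tibble: `region_id`, `metric`, `wald_p`, `separation`.
#' @export
select_measurement <- function(matrix, labels, marker,
                               metrics = mhb_metric_names,
                               min_per_group = 3L) {
  labels <- align_labels(labels, matrix$sample_ids)
  y01 <- as.integer(labels == "case")
  if (length(unique(y01)) < 2L) abort("labels are constant; nothing to regress")
  best <- tibble(region_id = marker, metric = NA_character_,
                 wald_p = Inf, separation = FALSE)
  for (met in metrics) {
    v <- metric_values(matrix, met)[, marker]
    ok <- !is.na(v)
    if (sum(ok & y01 == 1L) < min_per_group ||
        sum(ok & y01 == 0L) < min_per_group) next
    if (sd(v[ok]) == 0) next
    res <- logistic_slope_p(v[ok], y01[ok])
    if (!is.na(res$p_value) && res$p_value < best$wald_p) {
      best$metric <- met
      best$wald_p <- res$p_value
      best$separation <- res$separation
    }
  }
  if (is.na(best$metric)) {
    abort(sprintf("no measurement of marker '%s' is testable", marker))
  }
  best
}

#' @rdname select_measurement
#' @param markers Region ids to process.
#' @return For `select_measurements()`: one row per marker, sorted by
#'   `wald_p` then `region_id` (the ranking consumed by
#'   [incremental_select()]).
#' @export
select_measurements <- function(matrix, labels, markers,
                                metrics = mhb_metric_names) {
  purrr::map(markers, function(m) {
    tryCatch(select_measurement(matrix, labels, m, metrics = metrics),
             error = function(e) NULL)
  }) %>%
    bind_rows() %>%
    arrange(.data$wald_p, .data$region_id)
}

#' Chi-square window screen for a marker's measurements
#'
#' Assigns each measurement's values to 10 equal windows over `[0, 1]`
#' (`[0, 0.1), ..., [0.9, 1]`, right edge closed on the last window),
#' forms the 2 x 10 group-by-window contingency table, and computes the
#' chi-square statistic without continuity correction on the non-empty
#' windows with `df = (non-empty windows) - 1`. The measurement minimising
#' the p-value is returned. Fewer than two non-empty windows gives `p = 1`
#' for that measurement.
#'
#' @inheritParams select_measurement
#' @return One-row tibble: `region_id`, `metric`, `statistic`, `df`,
#'   `p_value`; attribute `per_metric` holds the full per-measurement
#'   table.
#' @export
chi_square_window_select <- function(matrix, labels, marker,
                                     metrics = mhb_metric_names) {
  labels <- align_labels(labels, matrix$sample_ids)
  per <- purrr::map(metrics, function(met) {
    v <- metric_values(matrix, met)[, marker]
    ok <- !is.na(v)
    cs <- chi_square_windows(v[ok], labels[ok])
    tibble(region_id = marker, metric = met, statistic = cs$statistic,
           df = cs$df, p_value = cs$p_value)
  }) %>% bind_rows()
  best <- per[order(per$p_value, match(per$metric, metrics)), ][1L, ]
  attr(best, "per_metric") <- per
  best
}

# 2 x 10 window contingency chi-square; values must lie in [0, 1]
chi_square_windows <- function(values, labels, n_windows = 10L) {
  if (any(values < 0 | values > 1)) abort("window screen needs values in [0, 1]")
  bin <- pmin(floor(values * n_windows) + 1L, n_windows)
  tab <- table(factor(labels, levels = c("control", "case")),
               factor(bin, levels = seq_len(n_windows)))
  tab <- tab[, colSums(tab) > 0L, drop = FALSE]
  k <- ncol(tab)
  if (k < 2L || any(rowSums(tab) == 0L)) {
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- k - 1L
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}
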