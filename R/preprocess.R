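# preprocessing learned on training data only: KNN imputation of missing
# marker values followed by robust (median / IQR) scaling

#' Fit the imputation-and-scaling preprocessor on training data
#'
#' Learns, per marker, the robust scaling parameters (centre = median,
#' width = 25-75\% interquartile range, quartiles by linear interpolation)
#' and stores the scaled training matrix that later serves as the donor
#' pool for k-nearest-neighbour imputation. Markers with zero IQR in
#' training carry no usable signal on this scale and are dropped with a
#' warning.
#'
#' @param train Data frame or matrix of training samples x marker values
#'   (one column per selected marker measurement; an optional `sample_id`
#'   column is used for row names).
#' @param k Number of imputation neighbours (default 5).
#' @return An `mhb_preprocessor` object.
#' @export
fit_preprocessor <- function(train, k = 5L) {
  x <- as_marker_matrix(train)
  if (nrow(x) < k + 1L) abort(sprintf("need at least k + 1 = %d training samples", k + 1L))
  centre <- apply(x, 2L, median, na.rm = TRUE)
  q <- apply(x, 2L, quantile, probs = c(0.25, 0.75), na.rm = TRUE, type = 7)
  width <- q[2L, ] - q[1L, ]
  degenerate <- !is.finite(width) | width <= 0
  if (any(degenerate)) {
    warn(sprintf("dropping marker(s) with zero IQR in training: %s",
                 paste(colnames(x)[degenerate], collapse = ", ")))
  }
  keep <- colnames(x)[!degenerate]
  if (!length(keep)) abort("no marker with positive IQR in training")
  x <- x[, keep, drop = FALSE]
  centre <- centre[keep]; width <- width[keep]
  scaled <- sweep(sweep(x, 2L, centre), 2L, width, "/")
  structure(list(markers = keep, centre = centre, width = width,
                 k = as.integer(k), train_scaled = scaled),
            class = "mhb_preprocessor")
}

#' Apply a fitted preprocessor
#'
#' Scales by the training median/IQR and imputes every remaining missing
#' cell from the `k` training samples nearest in Euclidean distance over
#' the markers observed in both the recipient and the donor (distance
#' normalised by the number of shared markers; neighbour ties broken by
#' training sample order). A donor must itself observe the marker being
#' imputed. With no usable donor or no shared marker the training median
#' (0 on the scaled axis) is used.
#'
#' @param prep An `mhb_preprocessor`.
#' @param newdata Data frame or matrix with the preprocessor's marker
#'   columns; may be the training table itself.
#' @return Numeric matrix (samples x markers), scaled, with no missing
#'   values.
#' @export
apply_preprocessor <- function(prep, newdata) {
  x <- as_marker_matrix(newdata)
  missing_cols <- setdiff(prep$markers, colnames(x))
  if (length(missing_cols)) {
    abort(sprintf("newdata lacks marker column(s): %s",
                  paste(head(missing_cols, 5L), collapse = ", ")))
  }
  x <- x[, prep$markers, drop = FALSE]
  scaled <- sweep(sweep(x, 2L, prep$centre), 2L, prep$width, "/")
  donors <- prep$train_scaled
  for (i in seq_len(nrow(scaled))) {
    miss <- which(is.na(scaled[i, ]))
    if (!length(miss)) next
    obs <- which(!is.na(scaled[i, ]))
    for (j in miss) {
      ok <- !is.na(donors[, j])
      if (!any(ok) || !length(obs)) { scaled[i, j] <- 0; next }
      d <- vapply(which(ok), function(t) {
        shared <- obs[!is.na(donors[t, obs])]
        if (!length(shared)) return(Inf)
        sqrt(mean((scaled[i, shared] - donors[t, shared])^2))
      }, 0)
      if (all(!is.finite(d))) { scaled[i, j] <- 0; next }
      nb <- which(ok)[order(d, seq_along(d))][seq_len(min(prep$k, sum(is.finite(d))))]
      scaled[i, j] <- mean(donors[nb, j])
    }
  }
  scaled
}

#' @export
print.mhb_preprocessor <- function(x, ...) {
  cat(sprintf("<mhb_preprocessor> %d markers, k = %d neighbours, %d donor samples\n",
              length(x$markers), x$k, nrow(x$train_scaled)))
  invisible(x)
}

as_marker_matrix <- function(x) {
  if (is.data.frame(x)) {
    rn <- if ("sample_id" %in% names(x)) x$sample_id else rownames(x)
    x <- x[, setdiff(names(x), "sample_id"), drop = FALSE]
    x <- as.matrix(x)
    if (!is.null(rn)) rownames(x) <- rn
  }
  storage.mode(x) <- "double"
  x
}
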