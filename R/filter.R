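#' Filter regions by missingness and variance
#'
#' Applies the two discovery-phase region filters on one chosen
#' measurement: regions whose missing-value (NA) fraction across samples
#' exceeds `max_na_rate` are removed, then regions whose sample variance of
#' the non-missing values is strictly below `min_variance` are removed
#' (a region with variance exactly equal to the threshold is kept).
#'
#' @param matrix A `metric_matrix`.
#' @param metric Measurement the filters are computed on (default `"amf"`).
#' @param max_na_rate Maximum tolerated NA fraction per region
#'   (default 0.10; the rule is strict: NA rate > 10\% drops the region).
#' @param min_variance Variance floor (default 0.02; variance < 0.02 drops
#'   the region).
#' @return List with `matrix` (the filtered `metric_matrix`) and `report`,
#'   a one-row tibble (`regions_in`, `removed_na_rate`,
#'   `removed_low_variance`, `regions_out`) accounting for every drop.
#' @export
filter_mhbs <- function(matrix, metric = "amf", max_na_rate = 0.10,
                        min_variance = 0.02) {
  vals <- metric_values(matrix, metric)
  na_rate <- colMeans(is.na(vals))
  drop_na <- na_rate > max_na_rate
  vr <- apply(vals[, !drop_na, drop = FALSE], 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) 0 else var(v)
  })
  drop_var <- vr < min_variance
  keep <- colnames(vals)[!drop_na][!drop_var]
  report <- tibble(
    regions_in = ncol(vals),
    removed_na_rate = sum(drop_na),
    removed_low_variance = sum(drop_var),
    regions_out = length(keep)
  )
  list(matrix = subset_metric_matrix(matrix, regions = keep), report = report)
}
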