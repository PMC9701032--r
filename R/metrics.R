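# block-level methylation haplotype measurements
#
# All seven measurements are computed from the pooled read-level haplotypes
# of one region in one sample:
#   amf    pooled per-CpG methylation level: methylated CpG observations /
#          all CpG observations
#   mhl    length-weighted (w_i = i) fraction of fully methylated substrings
#          of each length i, P(MH_i), normalised by the weight sum
#   mhl3   as mhl with w_i = i^3
#   umhl   as mhl for fully unmethylated substrings
#   umhl3  as umhl with w_i = i^3
#   mhfm   fraction of full-span reads carrying the fully methylated
#          haplotype
#   mhfu   fraction of full-span reads carrying the fully unmethylated
#          haplotype
#
# Substring counts pool across reads weighted by read count; lengths i with
# no spanning substring are dropped from both sums of the load quotient.

# cache of per-pattern substring statistics keyed by the pattern string
.pattern_cache <- new.env(parent = emptyenv())

# For a pattern string return L, number of methylated sites, and the
# per-length counts of all-'1' / all-'0' windows (vectors of length L).
# A run of r equal characters contributes (r - i + 1) windows of length i.
pattern_stats <- function(pattern) {
  hit <- .pattern_cache[[pattern]]
  if (!is.null(hit)) return(hit)
  bits <- strsplit(pattern, "", fixed = TRUE)[[1L]] == "1"
  L <- length(bits)
  runs <- rle(bits)
  meth <- integer(L)
  unmeth <- integer(L)
  for (k in seq_along(runs$lengths)) {
    r <- runs$lengths[k]
    contrib <- r:1L
    if (runs$values[k]) meth[1:r] <- meth[1:r] + contrib
    else unmeth[1:r] <- unmeth[1:r] + contrib
  }
  out <- list(L = L, n_meth = sum(bits), meth_win = meth, unmeth_win = unmeth)
  assign(pattern, out, envir = .pattern_cache)
  out
}

#' Compute the seven haplotype measurements for one region
#'
#' @param haps Haplotype tibble rows for one region (`first_idx`, `pattern`,
#'   `count`); may be empty.
#' @param region A single-row `region_set` slice, or an integer giving the
#'   number of CpGs in the region.
#' @param full_span_only Compute `mhfm`/`mhfu` over reads spanning all
#'   region CpGs only (default) or over all reads.
#' @return One-row tibble: `depth` (total reads) and the seven measurements,
#'   each in `[0, 1]` or `NA`. All measurements are `NA` at depth 0;
#'   `mhfm`/`mhfu` are `NA` when no read spans the whole region. A
#'   computable 0 is a value, never `NA`.
#' @examples
#' haps <- tibble::tibble(first_idx = 1L, pattern = c("11", "10"),
#'                        count = c(2L, 1L))
#' region_metrics(haps, 2L)
#' @export
region_metrics <- function(haps, region, full_span_only = TRUE) {
  m <- if (is.numeric(region)) as.integer(region) else region$n_cpgs[[1L]]
  if (is.null(haps) || nrow(haps) == 0L) {
    v <- region_metrics_core(integer(0), character(0), integer(0), m,
                             full_span_only)
  } else {
    v <- region_metrics_core(haps$first_idx, haps$pattern, haps$count, m,
                             full_span_only)
  }
  tibble(depth = as.integer(v[["depth"]]), amf = v[["amf"]],
         mhl = v[["mhl"]], mhl3 = v[["mhl3"]], umhl = v[["umhl"]],
         umhl3 = v[["umhl3"]], mhfm = v[["mhfm"]], mhfu = v[["mhfu"]])
}

# vector-in, named-numeric-out workhorse shared with build_metric_matrix
region_metrics_core <- function(first_idx, pattern, count, m,
                                full_span_only = TRUE) {
  if (!length(pattern)) {
    return(c(depth = 0, amf = NA_real_, mhl = NA_real_, mhl3 = NA_real_,
             umhl = NA_real_, umhl3 = NA_real_, mhfm = NA_real_,
             mhfu = NA_real_))
  }
  stats <- lapply(pattern, pattern_stats)
  L <- vapply(stats, `[[`, 0L, "L")
  n_meth <- vapply(stats, `[[`, 0L, "n_meth")
  if (any(first_idx + L - 1L > m)) {
    abort("haplotype pattern extends past the region's CpG ladder")
  }
  cnt <- as.numeric(count)
  depth <- sum(cnt)

  amf <- sum(cnt * n_meth) / sum(cnt * L)

  meth_i <- numeric(m); unmeth_i <- numeric(m); tot_i <- numeric(m)
  for (k in seq_along(stats)) {
    lk <- L[k]
    idx <- seq_len(lk)
    tot_i[idx] <- tot_i[idx] + cnt[k] * (lk - idx + 1)
    meth_i[idx] <- meth_i[idx] + cnt[k] * stats[[k]]$meth_win
    unmeth_i[idx] <- unmeth_i[idx] + cnt[k] * stats[[k]]$unmeth_win
  }
  sup <- tot_i > 0
  load <- function(num, w) {
    if (!any(sup)) return(NA_real_)
    sum(w[sup] * num[sup] / tot_i[sup]) / sum(w[sup])
  }
  i <- seq_len(m)
  mhl <- load(meth_i, i)
  mhl3 <- load(meth_i, i^3)
  umhl <- load(unmeth_i, i)
  umhl3 <- load(unmeth_i, i^3)

  if (full_span_only) {
    full <- first_idx == 1L & L == m
  } else {
    full <- rep(TRUE, length(L))
  }
  if (!any(full)) {
    mhfm <- NA_real_; mhfu <- NA_real_
  } else {
    nf <- sum(cnt[full])
    mhfm <- sum(cnt[full & n_meth == L]) / nf
    mhfu <- sum(cnt[full & n_meth == 0L]) / nf
  }

  c(depth = depth, amf = amf, mhl = mhl, mhl3 = mhl3, umhl = umhl,
    umhl3 = umhl3, mhfm = mhfm, mhfu = mhfu)
}

#' Build the samples-by-regions measurement matrix for a cohort
#'
#' Computes [region_metrics()] for every sample-region combination and
#' applies the depth-based missingness rule: every measurement of a region
#' whose sequencing depth in a sample is strictly below `min_depth` is set
#' to `NA`.
#'
#' @param haps Long haplotype tibble for the cohort (`sample_id`,
#'   `region_id`, `first_idx`, `pattern`, `count`).
#' @param regions A `region_set`.
#' @param min_depth Depth threshold (default 10; depth < 10 is missing).
#' @param samples Optional character vector fixing the sample set and
#'   order; every requested sample must appear in `haps` (a sample with no
#'   haplotype records at all is an error naming the sample).
#' @param full_span_only Passed to [region_metrics()].
#' @return A `metric_matrix`: list with `sample_ids`, `region_ids`,
#'   `depth` (samples x regions integer matrix), `metrics` (named list of
#'   seven samples x regions matrices) and `min_depth`. Convert to a long
#'   tibble with [tidy()] / `as_tibble()`.
#' @export
build_metric_matrix <- function(haps, regions, min_depth = 10L,
                                samples = NULL, full_span_only = TRUE) {
  if (is.null(samples)) samples <- sort(unique(haps$sample_id))
  absent <- setdiff(samples, unique(haps$sample_id))
  if (length(absent)) {
    abort(sprintf("no haplotype records for sample(s): %s",
                  paste(absent, collapse = ", ")))
  }
  region_ids <- regions$region_id
  ns <- length(samples); nr <- length(region_ids)
  depth <- matrix(0L, ns, nr, dimnames = list(samples, region_ids))
  mats <- lapply(mhb_metric_names, function(x) {
    matrix(NA_real_, ns, nr, dimnames = list(samples, region_ids))
  })
  names(mats) <- mhb_metric_names

  m_of <- setNames(regions$n_cpgs, region_ids)
  keep <- haps$sample_id %in% samples & haps$region_id %in% region_ids
  fi <- haps$first_idx[keep]; pat <- haps$pattern[keep]
  cnt <- haps$count[keep]
  si <- match(haps$sample_id[keep], samples)
  ri <- match(haps$region_id[keep], region_ids)
  if (length(fi)) {
    cell <- (ri - 1L) * ns + si  # linear index into the matrices
    groups <- split(seq_along(fi), cell)
    vals <- matrix(NA_real_, length(groups), 8L)
    idx <- as.integer(names(groups))
    for (g in seq_along(groups)) {
      rows <- groups[[g]]
      vals[g, ] <- region_metrics_core(fi[rows], pat[rows], cnt[rows],
                                       m_of[[ri[rows[1L]]]],
                                       full_span_only = full_span_only)
    }
    depth[idx] <- as.integer(vals[, 1L])
    for (j in seq_along(mhb_metric_names)) {
      mats[[mhb_metric_names[j]]][idx] <- vals[, j + 1L]
    }
  }
  low <- depth < min_depth
  for (met in mhb_metric_names) mats[[met]][low] <- NA_real_
  structure(list(sample_ids = samples, region_ids = region_ids,
                 depth = depth, metrics = mats,
                 min_depth = as.integer(min_depth)),
            class = "metric_matrix")
}

#' @export
print.metric_matrix <- function(x, ...) {
  cat(sprintf("<metric_matrix> %d samples x %d regions, min_depth = %d\n",
              length(x$sample_ids), length(x$region_ids), x$min_depth))
  pres <- mean(!is.na(x$metrics$amf))
  cat(sprintf("  measurements: %s\n", paste(names(x$metrics), collapse = ", ")))
  cat(sprintf("  non-missing: %.1f%%\n", 100 * pres))
  invisible(x)
}

#' Extract one measurement as a samples-by-regions matrix
#' @param matrix A `metric_matrix`.
#' @param metric One of [mhb_metric_names].
#' @return Numeric matrix (samples x regions) with `NA` for missing.
#' @export
metric_values <- function(matrix, metric) {
  if (!metric %in% names(matrix$metrics)) {
    abort(sprintf("unknown metric '%s'; available: %s", metric,
                  paste(names(matrix$metrics), collapse = ", ")))
  }
  matrix$metrics[[metric]]
}

#' @method as_tibble metric_matrix
#' @export
as_tibble.metric_matrix <- function(x, ...) {
  long <- purrr::imap(x$metrics, function(mat, met) {
    tibble(
      sample_id = rep(x$sample_ids, times = length(x$region_ids)),
      region_id = rep(x$region_ids, each = length(x$sample_ids)),
      metric = met,
      value = as.vector(mat),
      depth = as.vector(x$depth)
    )
  })
  bind_rows(long) %>% arrange(.data$sample_id, .data$region_id, .data$metric)
}

#' @rdname as_tibble.metric_matrix
#' @param x A `metric_matrix`.
#' @param ... Unused.
#' @method tidy metric_matrix
#' @export
tidy.metric_matrix <- function(x, ...) as_tibble.metric_matrix(x, ...)

# subset a metric_matrix by region ids and/or sample ids
subset_metric_matrix <- function(x, regions = NULL, samples = NULL) {
  r <- regions %||% x$region_ids
  s <- samples %||% x$sample_ids
  structure(list(
    sample_ids = s, region_ids = r,
    depth = x$depth[s, r, drop = FALSE],
    metrics = lapply(x$metrics, function(m) m[s, r, drop = FALSE]),
    min_depth = x$min_depth
  ), class = "metric_matrix")
}
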