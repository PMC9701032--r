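# differential-region selection: Wilcoxon contrasts with BH correction and
# the resampled case/control cross-validated selection

# Two-sided Wilcoxon rank-sum test. Exact null distribution (stats::pwilcox)
# when both groups are smaller than `exact_below` and there are no ties;
# otherwise the normal approximation with tie correction (no continuity
# correction). Returns W (rank-sum U statistic of x) and p.
wilcoxon_rs <- function(x, y, exact_below = 10L) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)
  if (nx < exact_below && ny < exact_below && !has_ties) {
    p <- 2 * min(pwilcox(u, nx, ny), pwilcox(u - 1, nx, ny, lower.tail = FALSE))
    p <- min(1, p)
  } else {
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 *
      (nx + ny + 1 - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
    if (sigma2 <= 0) return(list(statistic = u, p_value = 1))
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = u, p_value = p)
}

#' Select differentially methylated regions between two groups
#'
#' Two-sided Wilcoxon rank-sum test per region on the non-missing values of
#' one measurement, Benjamini-Hochberg adjustment across all tested
#' regions, and selection at FDR `q < alpha`.
#'
#' @param matrix A `metric_matrix` (typically after [filter_mhbs()]).
#' @param labels Group label per sample (two classes), aligned with
#'   `matrix$sample_ids` or a named vector.
#' @param metric Measurement tested (default `"amf"`).
#' @param alpha FDR threshold (default 0.05).
#' @param min_per_group Minimum non-missing values required in each group
#'   for a region to be tested (default 3); regions failing this are
#'   skipped and counted in attribute `n_skipped`.
#' @param source Tag recorded in the `source` column (one of
#'   `"T2T"`, `"T2P"`, `"P2P"`, `"literature"` in the standard workflow).
#' @return Marker tibble (`region_id`, `source`, `statistic`, `p_value`,
#'   `fdr_q`) with `fdr_q < alpha`, sorted by `fdr_q` then `region_id`.
#'   Attribute `all_tested` holds the unfiltered table.
#' @export
differential_mhbs <- function(matrix, labels, metric = "amf", alpha = 0.05,
                              min_per_group = 3L, source = "T2P") {
  labels <- align_labels(labels, matrix$sample_ids)
  vals <- metric_values(matrix, metric)
  is_case <- labels == "case"
  res <- purrr::map(seq_len(ncol(vals)), function(j) {
    v <- vals[, j]
    x <- v[is_case & !is.na(v)]
    y <- v[!is_case & !is.na(v)]
    if (length(x) < min_per_group || length(y) < min_per_group) return(NULL)
    w <- wilcoxon_rs(x, y)
    tibble(region_id = colnames(vals)[j], statistic = w$statistic,
           p_value = w$p_value)
  })
  n_skipped <- sum(vapply(res, is.null, TRUE))
  res <- bind_rows(res)
  if (!nrow(res)) {
    out <- tibble(region_id = character(), source = character(),
                  statistic = double(), p_value = double(), fdr_q = double())
    attr(out, "all_tested") <- out
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  res$fdr_q <- stats::p.adjust(res$p_value, method = "BH")
  res$source <- source
  res <- res[, c("region_id", "source", "statistic", "p_value", "fdr_q")]
  out <- res %>% filter(.data$fdr_q < alpha) %>%
    arrange(.data$fdr_q, .data$region_id)
  attr(out, "all_tested") <- arrange(res, .data$p_value, .data$region_id)
  attr(out, "n_skipped") <- n_skipped
  out
}

align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing)) {
      abort(sprintf("labels missing for sample(s): %s",
                    paste(head(missing, 5L), collapse = ", ")))
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    abort("labels must be named or aligned with the matrix samples")
  }
  as_case_factor(labels)
}

#' Resampled case/control marker selection with cross-validated screening
#'
#' Balanced repeated subsampling for plasma-vs-plasma marker discovery.
#' Each iteration draws `n_balance` cases and `n_balance` controls without
#' replacement, splits each group into a discovery set (`n_split[1]` per
#' group) and a validation set (`n_split[2]` per group), selects
#' differential regions in the discovery split (Wilcoxon, BH `q < alpha`),
#' trains a random forest on those regions in the discovery split and
#' scores the validation split. When the validation AUC reaches `auc_min`,
#' every selected region's tally is incremented. Regions tallied strictly
#' more than `count_min` times over `iters` iterations are returned.
#'
#' Iterations whose discovery split yields no differential region are
#' counted as failed (attribute `n_failed`) and tally nothing. Missing
#' values inside the forest's feature matrix are imputed with the
#' discovery-split median of the region. Fully deterministic given `seed`.
#'
#' @param matrix A `metric_matrix`.
#' @param cases,controls Sample ids of the two groups (at least
#'   `n_balance` each).
#' @param iters Number of resampling iterations (default 500).
#' @param n_balance Cases and controls drawn per iteration (default 20).
#' @param n_split Per-group discovery/validation sizes (default `c(15, 5)`).
#' @param auc_min Validation AUC needed to keep an iteration's regions
#'   (default 0.75).
#' @param count_min Selection-count threshold; regions with
#'   `selection_count > count_min` are returned (default 300, strict).
#' @param alpha Discovery FDR threshold (default 0.05).
#' @param metric Measurement used (default `"amf"`).
#' @param num_trees Random forest size (default 500, sqrt(p) features per
#'   split).
#' @param seed Master seed; per-iteration seeds are derived from it.
#' @return Marker tibble (`region_id`, `source = "P2P"`, `statistic`,
#'   `p_value`, `fdr_q` all `NA`, `selection_count`), sorted by decreasing
#'   count. Attributes: `counts` (named tally over all regions ever
#'   selected), `n_failed`, `n_kept` (iterations reaching `auc_min`).
#' @export
p2p_selection <- function(matrix, cases, controls, iters = 500L,
                          n_balance = 20L, n_split = c(15L, 5L),
                          auc_min = 0.75, count_min = 300L, alpha = 0.05,
                          metric = "amf", num_trees = 500L, seed = 1L) {
  if (length(cases) < n_balance || length(controls) < n_balance) {
    abort(sprintf("need >= %d cases and controls; got %d / %d",
                  n_balance, length(cases), length(controls)))
  }
  if (sum(n_split) != n_balance) {
    abort("n_split must sum to n_balance per group")
  }
  vals <- metric_values(matrix, metric)
  counts <- integer(0)
  n_failed <- 0L; n_kept <- 0L
  for (it in seq_len(as.integer(iters))) {
    it_seed <- derive_seed(seed, paste0("p2p-", it))
    sel <- withr::with_seed(it_seed, {
      ca <- sample(cases, n_balance)
      co <- sample(controls, n_balance)
      list(
        disc = c(sample(ca, n_split[1L]), sample(co, n_split[1L])),
        ca = ca, co = co
      )
    })
    disc <- sel$disc
    valid <- c(setdiff(sel$ca, disc), setdiff(sel$co, disc))
    y_disc <- factor(ifelse(disc %in% cases, "case", "control"),
                     levels = c("control", "case"))
    y_valid <- disc_valid_labels(valid, cases)

    markers <- iteration_markers(vals, disc, y_disc, alpha)
    if (!length(markers)) { n_failed <- n_failed + 1L; next }

    x_disc <- vals[disc, markers, drop = FALSE]
    med <- apply(x_disc, 2L, median, na.rm = TRUE)
    med[is.na(med)] <- 0.5
    x_disc <- impute_with(x_disc, med)
    x_valid <- impute_with(vals[valid, markers, drop = FALSE], med)

    fit <- ranger::ranger(
      x = as.data.frame(x_disc), y = y_disc,
      num.trees = num_trees, mtry = max(1L, floor(sqrt(length(markers)))),
      probability = TRUE, seed = it_seed, num.threads = 1L
    )
    score <- predict(fit, data = as.data.frame(x_valid),
                     num.threads = 1L)$predictions[, "case"]
    auc <- auc_mw(score, y_valid)
    if (!is.na(auc) && auc >= auc_min) {
      n_kept <- n_kept + 1L
      for (mk in markers) {
        counts[mk] <- (if (mk %in% names(counts)) counts[[mk]] else 0L) + 1L
      }
    }
  }
  keep <- as.character(names(counts)[counts > count_min])
  out <- tibble(region_id = sort(keep), source = "P2P",
                statistic = NA_real_, p_value = NA_real_, fdr_q = NA_real_,
                selection_count = as.integer(counts[sort(keep)]))
  out <- arrange(out, dplyr::desc(.data$selection_count), .data$region_id)
  attr(out, "counts") <- counts
  attr(out, "n_failed") <- n_failed
  attr(out, "n_kept") <- n_kept
  out
}

disc_valid_labels <- function(ids, cases) {
  factor(ifelse(ids %in% cases, "case", "control"),
         levels = c("control", "case"))
}

iteration_markers <- function(vals, disc, y_disc, alpha) {
  is_case <- y_disc == "case"
  p <- vapply(seq_len(ncol(vals)), function(j) {
    v <- vals[disc, j]
    x <- v[is_case & !is.na(v)]
    y <- v[!is_case & !is.na(v)]
    if (length(x) < 3L || length(y) < 3L) return(NA_real_)
    wilcoxon_rs(x, y)$p_value
  }, 0)
  q <- stats::p.adjust(p, method = "BH")
  colnames(vals)[!is.na(q) & q < alpha]
}

impute_with <- function(x, med) {
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  x
}

#' Literature marker set from TSS windows
#'
#' Selects regions overlapping the strand-aware promoter window of any gene
#' in a supplied list: `[TSS - upstream, TSS + downstream]` on the plus
#' strand, reflected for minus-strand genes (upstream means higher
#' coordinates there).
#'
#' @param regions A `region_set`.
#' @param tss_bed BED6 file of gene bodies (chrom, start, end, gene, score,
#'   strand); the TSS is `start` for `+` genes and `end - 1` for `-` genes.
#' @param gene_list File with one gene symbol per line, or a character
#'   vector of symbols.
#' @param upstream,downstream Window extent around the TSS in bp
#'   (defaults 1500 and 1000).
#' @return Marker tibble with `source = "literature"` and a `genes` column
#'   listing the matched genes per region. Genes in the list absent from
#'   `tss_bed` are reported via a message and skipped.
#' @export
tss_markers <- function(regions, tss_bed, gene_list, upstream = 1500L,
                        downstream = 1000L) {
  tss <- readr::read_tsv(
    tss_bed, col_names = c("chrom", "start", "end", "gene", "score", "strand"),
    col_types = "ciiccc", na = character(), progress = FALSE
  )
  if (is.character(gene_list) && length(gene_list) == 1L &&
      file.exists(gene_list)) {
    gene_list <- readLines(gene_list)
  }
  gene_list <- unique(gene_list[nzchar(gene_list)])
  absent <- setdiff(gene_list, tss$gene)
  if (length(absent)) {
    inform(sprintf("%d listed gene(s) absent from TSS bed (skipped)",
                   length(absent)))
  }
  tss <- tss[tss$gene %in% gene_list, , drop = FALSE]
  win_lo <- ifelse(tss$strand == "-", (tss$end - 1L) - downstream,
                   tss$start - upstream)
  win_hi <- ifelse(tss$strand == "-", (tss$end - 1L) + upstream,
                   tss$start + downstream)
  hits <- purrr::map(seq_len(nrow(regions)), function(i) {
    ov <- tss$chrom == regions$chrom[i] &
      regions$start[i] <= win_hi & regions$end[i] > win_lo
    if (!any(ov)) NULL else tibble(region_id = regions$region_id[i],
                                   genes = paste(sort(unique(tss$gene[ov])),
                                                 collapse = ","))
  })
  hits <- bind_rows(hits)
  if (!nrow(hits)) {
    return(tibble(region_id = character(), source = character(),
                  statistic = double(), p_value = double(),
                  fdr_q = double(), genes = character()))
  }
  tibble(region_id = hits$region_id, source = "literature",
         statistic = NA_real_, p_value = NA_real_, fdr_q = NA_real_,
         genes = hits$genes) %>% arrange(.data$region_id)
}

#' Assemble the combined marker panel
#'
#' Combines the discovery contrasts into one panel:
#' `(T2T intersect T2P) union (T2T intersect literature) union P2P`,
#' de-duplicated by region, each region retaining every source that
#' contributed it.
#'
#' @param t2t,t2p,p2p,literature Marker tibbles (need a `region_id`
#'   column); any may be empty or `NULL`.
#' @return Tibble (`region_id`, `sources`, `n_sources`) in stable
#'   `region_id` order.
#' @export
assemble_panel <- function(t2t = NULL, t2p = NULL, p2p = NULL,
                           literature = NULL) {
  ids <- function(x) if (is.null(x)) character() else unique(x$region_id)
  s1 <- intersect(ids(t2t), ids(t2p))
  s2 <- intersect(ids(t2t), ids(literature))
  s3 <- ids(p2p)
  panel <- sort(unique(c(s1, s2, s3)))
  src <- purrr::map_chr(panel, function(r) {
    tags <- c(if (r %in% ids(t2t)) "T2T", if (r %in% ids(t2p)) "T2P",
              if (r %in% ids(p2p)) "P2P",
              if (r %in% ids(literature)) "literature")
    paste(tags, collapse = "+")
  })
  tibble(region_id = panel, sources = src,
         n_sources = lengths(strsplit(src, "+", fixed = TRUE)))
}
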