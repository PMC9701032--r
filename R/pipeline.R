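# end-to-end orchestration: simulate -> metrics -> discover -> train ->
# predict -> evaluate, under one config and one master seed

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with the standard
#' defaults: depth < 10 is missing, NA rate > 10\% and variance < 0.02
#' drop a region, discovery FDR 0.05, resampled selection with 500
#' iterations / AUC gate 0.75 / count threshold 300, detection rate 90\%,
#' 10 CV folds, 5 imputation neighbours, 1000 bootstrap replicates.
#'
#' @param design A [cohort_design()] describing the synthetic cohort (or
#'   `NULL` when supplying real inputs to [run_pipeline()]).
#' @param min_depth,max_na_rate,min_variance,alpha Filtering and
#'   discovery thresholds.
#' @param discovery_metric Measurement used by discovery-phase tests.
#' @param run_p2p Run the resampled selection stage (off by default:
#'   expensive, and the Wilcoxon contrast already yields candidates on a
#'   single-cohort design).
#' @param p2p_iters,p2p_auc_min,p2p_count_min Resampled selection
#'   parameters.
#' @param min_detect Training detection-rate threshold for candidate
#'   markers.
#' @param n_fallback When no region passes the FDR gate, the pipeline
#'   falls back to the top `n_fallback` regions by unadjusted p-value so
#'   that a classifier can always be built (the null-cohort guard relies
#'   on this path staying honest on held-out data).
#' @param folds,k CV folds and imputation neighbours.
#' @param bootstrap_reps Bootstrap replicates for AUC intervals.
#' @param cutoff_method,specificity Decision cutoff rule.
#' @param use_ca199 Fit the combined methylation + CA19-9 model.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(design = cohort_design(), min_depth = 10L,
                            max_na_rate = 0.10, min_variance = 0.02,
                            alpha = 0.05, discovery_metric = "amf",
                            run_p2p = FALSE, p2p_iters = 500L,
                            p2p_auc_min = 0.75, p2p_count_min = 300L,
                            min_detect = 0.9, n_fallback = 20L,
                            folds = 10L, k = 5L, bootstrap_reps = 1000L,
                            cutoff_method = "youden", specificity = 0.89,
                            use_ca199 = TRUE, seed = 1L) {
  structure(list(design = design, min_depth = as.integer(min_depth),
                 max_na_rate = max_na_rate, min_variance = min_variance,
                 alpha = alpha, discovery_metric = discovery_metric,
                 run_p2p = run_p2p, p2p_iters = as.integer(p2p_iters),
                 p2p_auc_min = p2p_auc_min,
                 p2p_count_min = as.integer(p2p_count_min),
                 min_detect = min_detect, n_fallback = as.integer(n_fallback),
                 folds = as.integer(folds), k = as.integer(k),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 cutoff_method = cutoff_method, specificity = specificity,
                 use_ca199 = use_ca199, seed = as.integer(seed)),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate, metrics, discover, train, predict and evaluate in
#' order. The training cohort is the only one whose labels are consumed
#' before prediction; held-out labels enter only at the evaluation stage.
#' Re-running with an identical config produces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as TSVs (`metrics.tsv`, `markers.tsv`, `measurements.tsv`,
#'   `predictions.tsv`, `report.tsv`) plus a `run.json` audit log of every
#'   effective threshold and seed.
#' @return A `haplomark_run` list: `config`, `regions`, `cohort`,
#'   `metric_matrix`, `filter_report`, `markers`, `measurements`,
#'   `preprocessor`, `selection` (incremental trace), `classifier`,
#'   `predictions`, `report` (per-cohort evaluation tibble) and, when
#'   CA19-9 is used, `combined` and `auc_comparison`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  seed <- config$seed

  regions <- with_stage("simulate",
                        simulate_regions(config$design, derive_seed(seed, "sim")))
  cohort <- with_stage("simulate",
                       simulate_cohort(config$design, regions,
                                       derive_seed(seed, "sim")))
  meta <- cohort$meta

  mm <- with_stage("metrics",
                   build_metric_matrix(cohort$haplotypes, regions,
                                       min_depth = config$min_depth,
                                       samples = meta$sample_id))

  train_ids <- meta$sample_id[meta$cohort == "train"]
  heldout <- setdiff(unique(meta$cohort), "train")
  y_train <- setNames(meta$group[match(train_ids, meta$sample_id)], train_ids)

  disc <- with_stage("discover", {
    mm_train <- subset_metric_matrix(mm, samples = train_ids)
    flt <- filter_mhbs(mm_train, metric = config$discovery_metric,
                       max_na_rate = config$max_na_rate,
                       min_variance = config$min_variance)
    markers <- differential_mhbs(flt$matrix, y_train,
                                 metric = config$discovery_metric,
                                 alpha = config$alpha, source = "P2P")
    if (config$run_p2p) {
      cases <- train_ids[y_train == "PDAC"]
      controls <- train_ids[y_train != "PDAC"]
      p2p <- p2p_selection(flt$matrix, cases, controls,
                           iters = config$p2p_iters,
                           auc_min = config$p2p_auc_min,
                           count_min = config$p2p_count_min,
                           alpha = config$alpha,
                           metric = config$discovery_metric,
                           seed = derive_seed(seed, "p2p"))
      markers <- bind_rows(markers, p2p) %>%
        distinct(.data$region_id, .keep_all = TRUE)
    }
    candidates <- markers$region_id
    if (!length(candidates)) {
      ranked <- attr(markers, "all_tested") %||%
        attr(differential_mhbs(flt$matrix, y_train,
                               metric = config$discovery_metric,
                               alpha = 1.01), "all_tested")
      candidates <- head(ranked$region_id, config$n_fallback)
    }
    detected <- markers_detected(mm_train, config$min_detect)
    list(matrix_train = mm_train, filter_report = flt$report,
         markers = markers, candidates = intersect(candidates, detected))
  })
  if (!length(disc$candidates)) {
    abort("pipeline stage 'discover' failed: no candidate marker survives the detection filter")
  }

  model <- with_stage("train", {
    meas <- select_measurements(disc$matrix_train, y_train, disc$candidates)
    train_tbl <- measurement_table(mm, meas, train_ids)
    prep <- fit_preprocessor(train_tbl, k = config$k)
    meas <- meas[meas$region_id %in% prep$markers, ]
    x_train <- apply_preprocessor(prep, train_tbl)
    inc <- incremental_select(x_train, y_train, meas$region_id,
                              folds = config$folds,
                              seed = derive_seed(seed, "folds"))
    clf <- train_classifier(x_train, y_train, inc$selected,
                            seed = derive_seed(seed, "svm"),
                            cutoff_method = config$cutoff_method,
                            specificity = config$specificity)
    list(measurements = meas, prep = prep, x_train = x_train,
         selection = inc, classifier = clf)
  })

  predictions <- with_stage("predict", {
    purrr::map(heldout, function(co) {
      ids <- meta$sample_id[meta$cohort == co]
      x <- apply_preprocessor(model$prep,
                              measurement_table(mm, model$measurements, ids))
      score <- predict(model$classifier, x, type = "score")
      tibble(sample_id = ids, cohort = co, score = score,
             call = ifelse(score >= model$classifier$cutoff,
                           "PDAC", "Healthy"))
    }) %>% bind_rows()
  })

  evaluation <- with_stage("evaluate", {
    evaluate_predictions(predictions, meta, model, config, seed)
  })

  run <- structure(c(
    list(config = config, regions = regions, cohort = cohort,
         metric_matrix = mm, filter_report = disc$filter_report,
         markers = disc$markers, measurements = model$measurements,
         preprocessor = model$prep, selection = model$selection,
         classifier = model$classifier, predictions = predictions),
    evaluation
  ), class = "haplomark_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

evaluate_predictions <- function(predictions, meta, model, config, seed) {
  truth <- meta$group[match(predictions$sample_id, meta$sample_id)]
  rows <- list(); combined <- NULL; comparison <- NULL
  train_scores <- model$classifier$train_scores
  y_train <- model$classifier$train_labels
  for (co in unique(predictions$cohort)) {
    sel <- predictions$cohort == co
    y <- truth[sel]
    if (length(unique(y)) < 2L) next
    roc <- roc_auc(predictions$score[sel], y,
                   cutoff = model$classifier$cutoff)
    ci <- bootstrap_auc_ci(predictions$score[sel], y,
                           reps = config$bootstrap_reps,
                           seed = derive_seed(seed, paste0("boot-", co)))
    yb <- as_case_factor(y)
    sens_ci <- clopper_pearson(round(roc$sensitivity * sum(yb == "case")),
                               sum(yb == "case"))
    spec_ci <- clopper_pearson(round(roc$specificity * sum(yb == "control")),
                               sum(yb == "control"))
    rows[[co]] <- tibble(
      cohort = co, n_pos = roc$n_pos, n_neg = roc$n_neg, auc = roc$auc,
      auc_lower = ci$lower, auc_upper = ci$upper,
      sensitivity = roc$sensitivity, sens_lower = sens_ci$lower,
      sens_upper = sens_ci$upper, specificity = roc$specificity,
      spec_lower = spec_ci$lower, spec_upper = spec_ci$upper
    )
  }
  report <- bind_rows(rows)

  out <- list(report = report)
  if (isTRUE(config$use_ca199)) {
    meta_train <- meta[meta$cohort == "train", ]
    ca_train <- meta_train$ca19_9[match(names(y_train), meta_train$sample_id)]
    if (any(!is.na(ca_train))) {
      combined <- combine_ca199(train_scores, ca_train, y_train)
      first_co <- unique(predictions$cohort)[1L]
      sel <- predictions$cohort == first_co
      ca_h <- meta$ca19_9[match(predictions$sample_id[sel], meta$sample_id)]
      ok <- !is.na(ca_h)
      if (sum(ok) > 3L && length(unique(truth[sel][ok])) == 2L) {
        comb_scores <- predict(combined,
                               tibble(score = predictions$score[sel][ok],
                                      ca19_9 = ca_h[ok]))
        ca_alone <- log10(ca_h[ok] + 1)
        comparison <- list(
          combined_roc = roc_auc(comb_scores, truth[sel][ok],
                                 cutoff = combined$cutoff),
          t_test = auc_compare_T(ca_alone, comb_scores, truth[sel][ok],
                                 reps = config$bootstrap_reps,
                                 seed = derive_seed(seed, "cmpT")),
          delong = delong_test(ca_alone, comb_scores, truth[sel][ok])
        )
      }
      out$combined <- combined
      out$auc_comparison <- comparison
    }
  }
  out
}

# samples x selected-marker table; each marker contributes its chosen
# regional measurement
measurement_table <- function(mm, measurements, sample_ids) {
  cols <- purrr::map2(measurements$region_id, measurements$metric,
                      function(r, met) metric_values(mm, met)[sample_ids, r])
  names(cols) <- measurements$region_id
  out <- tibble(sample_id = sample_ids)
  bind_cols(out, as_tibble(cols))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(as_tibble(run$metric_matrix),
                   file.path(out_dir, "metrics.tsv"), progress = FALSE)
  readr::write_tsv(run$markers, file.path(out_dir, "markers.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$measurements, file.path(out_dir, "measurements.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$predictions, file.path(out_dir, "predictions.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$report, file.path(out_dir, "report.tsv"),
                   progress = FALSE)
  cfg <- run$config
  cfg$design <- unclass(cfg$design)
  jsonlite::write_json(
    list(config = unclass(cfg),
         selected_markers = run$classifier$markers,
         cutoff = run$classifier$cutoff,
         train_auc = run$classifier$train_auc),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA
  )
  invisible(run)
}

#' @export
print.haplomark_run <- function(x, ...) {
  cat(sprintf("<haplomark_run> %d regions, %d candidate markers, %d selected\n",
              length(x$metric_matrix$region_ids), nrow(x$measurements),
              length(x$classifier$markers)))
  cat(sprintf("  training AUC %.3f (cutoff %.3f)\n",
              x$classifier$train_auc, x$classifier$cutoff))
  if (!is.null(x$report) && nrow(x$report)) {
    for (i in seq_len(nrow(x$report))) {
      r <- x$report[i, ]
      cat(sprintf("  %s: AUC %.3f (%.2f-%.2f), sens %.2f, spec %.2f\n",
                  r$cohort, r$auc, r$auc_lower, r$auc_upper,
                  r$sensitivity, r$specificity))
    }
  }
  invisible(x)
}

#' Precision of the selected markers against the planted truth
#'
#' @param run A `haplomark_run` from a simulated design.
#' @return Fraction of the classifier's markers that are planted true
#'   markers.
#' @export
marker_precision <- function(run) {
  truth <- run$cohort$truth$markers
  sel <- run$classifier$markers
  mean(sel %in% truth$region_id[truth$is_true_marker])
}
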