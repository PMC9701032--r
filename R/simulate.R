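# synthetic plasma cohort generator
#
# Emulates the statistical structure the pipeline assumes: per-region
# bimodal background methylation with beta-distributed sample-to-sample
# latent levels, within-read co-methylation, case-specific shifts at
# designated true-marker regions diluted by a read-level tumour fraction
# (the ctDNA dilution mechanism), negative-binomial coverage, region-level
# missingness, and group-wise lognormal CA19-9 with a Lewis-negative case
# fraction forced below the 37 U/ml positivity threshold.

#' Parameterise a synthetic plasma cohort
#'
#' All defaults define the reference study conditions used by the
#' package's benchmarks: 200 regions of 3-8 CpGs, 20 true markers with a
#' methylation shift of 0.4 diluted to read fraction 0.2, 50x
#' negative-binomial coverage, bimodal background (modes 0.15/0.85,
#' beta concentration 4), within-read co-methylation 0.7, 2\% region
#' dropout, and train 60/60 plus validation 30/30 samples.
#'
#' @param n_regions Number of regions.
#' @param n_true_markers Number of planted true markers.
#' @param cpg_range Inclusive range of CpGs per region.
#' @param splits Named list of per-cohort `c(cases, controls)` sizes.
#' @param mu_low,mu_high,p_high Background methylation modes and the
#'   probability a region sits at the high mode.
#' @param kappa Beta concentration of the latent per-sample level.
#' @param delta Case methylation shift at true markers (applied away from
#'   the background mode, clipped to `[0.02, 0.98]`).
#' @param tumour_fraction Fraction of a case's reads drawn from the
#'   tumour level at true markers.
#' @param rho Within-read co-methylation: probability that a read's CpGs
#'   share a single Bernoulli draw.
#' @param coverage_mean,coverage_dispersion Negative-binomial read count
#'   per region (mean and size).
#' @param p_full_span Probability a read spans the full CpG ladder;
#'   otherwise it covers a random contiguous sub-window.
#' @param missing_rate Probability a sample-region yields no reads.
#' @param ca19_9 List of CA19-9 lognormal parameters: `ctrl_median`,
#'   `ctrl_sdlog`, `case_median`, `case_sdlog`, `cp_median`, `cp_sdlog`,
#'   `lewis_negative_fraction` (case fraction forced below 37 U/ml).
#' @param seed Master seed recorded in the design.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_regions = 200L, n_true_markers = 20L,
                          cpg_range = c(3L, 8L),
                          splits = list(train = c(cases = 60L, controls = 60L),
                                        validation = c(cases = 30L,
                                                       controls = 30L)),
                          mu_low = 0.15, mu_high = 0.85, p_high = 0.5,
                          kappa = 4, delta = 0.4, tumour_fraction = 0.2,
                          rho = 0.7, coverage_mean = 50,
                          coverage_dispersion = 5, p_full_span = 0.7,
                          missing_rate = 0.02,
                          ca19_9 = list(ctrl_median = 4, ctrl_sdlog = 0.8,
                                        case_median = 400, case_sdlog = 1.2,
                                        cp_median = 110, cp_sdlog = 1.2,
                                        lewis_negative_fraction = 0.1),
                          seed = 1L) {
  design <- list(n_regions = as.integer(n_regions),
                 n_true_markers = as.integer(n_true_markers),
                 cpg_range = as.integer(cpg_range), splits = splits,
                 mu_low = mu_low, mu_high = mu_high, p_high = p_high,
                 kappa = kappa, delta = delta,
                 tumour_fraction = tumour_fraction, rho = rho,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 p_full_span = p_full_span, missing_rate = missing_rate,
                 ca19_9 = ca19_9, seed = as.integer(seed))
  fracs <- c(design$p_high, design$rho, design$tumour_fraction,
             design$p_full_span, design$missing_rate, design$mu_low,
             design$mu_high, ca19_9$lewis_negative_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("all fractions must lie in [0, 1]")
  if (design$n_true_markers > design$n_regions) {
    abort("n_true_markers must not exceed n_regions")
  }
  structure(design, class = "cohort_design")
}

#' Simulate region definitions on a synthetic chromosome
#'
#' Places non-overlapping regions on chromosome `chrS`, each with a CpG
#' count drawn uniformly from the design's range and CpG gaps of 10-40 bp.
#'
#' @param design A `cohort_design`.
#' @param seed Seed (defaults to the design's).
#' @return A `region_set`; empty when `n_regions = 0`.
#' @export
simulate_regions <- function(design, seed = design$seed) {
  if (design$n_regions == 0L) {
    return(new_region_set(tibble(region_id = character(), chrom = character(),
                                 start = double(), end = double(),
                                 n_cpgs = integer(), cpgs = list())))
  }
  withr::with_seed(derive_seed(seed, "regions"), {
    n_cpgs <- sample(seq(design$cpg_range[1L], design$cpg_range[2L]),
                     design$n_regions, replace = TRUE)
    offset <- 1000
    cpgs <- vector("list", design$n_regions)
    start <- end <- numeric(design$n_regions)
    for (i in seq_len(design$n_regions)) {
      gaps <- sample(10:40, n_cpgs[i] - 1L, replace = TRUE)
      pos <- offset + cumsum(c(0, gaps))
      cpgs[[i]] <- pos
      start[i] <- pos[1L] - 5
      end[i] <- pos[length(pos)] + 5
      offset <- end[i] + sample(500:1500, 1L)
    }
    new_region_set(tibble(
      region_id = sprintf("mhb_%03d", seq_len(design$n_regions)),
      chrom = "chrS", start = start, end = end, n_cpgs = n_cpgs, cpgs = cpgs
    ))
  })
}

#' Simulate a full plasma cohort with planted truth
#'
#' Draws, for every sample and region, a latent methylation level from a
#' beta distribution centred on the region's background mode; cases at
#' true-marker regions replace a `tumour_fraction` of reads with reads at
#' the shifted tumour level. Read counts are negative-binomial, each read
#' covers a contiguous CpG window, and within a read all CpGs share one
#' Bernoulli draw with probability `rho` (otherwise CpGs are independent).
#' Region-sample pairs drop out at `missing_rate`. CA19-9 values come
#' from [simulate_ca199()].
#'
#' @param design A `cohort_design`.
#' @param regions Regions from [simulate_regions()].
#' @param seed Seed (defaults to the design's).
#' @return List with `haplotypes` (long tibble: `sample_id`, `region_id`,
#'   `first_idx`, `pattern`, `count`), `meta` (sample metadata tibble) and
#'   `truth` (list: `markers` tibble with per-region background/tumour
#'   levels and direction, `tumour_fraction` per sample, `theta`
#'   samples x regions latent background levels).
#' @export
simulate_cohort <- function(design, regions, seed = design$seed) {
  meta <- simulate_meta(design, seed)
  truth_markers <- withr::with_seed(derive_seed(seed, "truth"), {
    is_high <- runif(design$n_regions) < design$p_high
    mu_bg <- ifelse(is_high, design$mu_high, design$mu_low)
    true_idx <- sample(design$n_regions, design$n_true_markers)
    direction <- ifelse(is_high, -1L, 1L)
    tibble(region_id = regions$region_id,
           is_true_marker = seq_len(design$n_regions) %in% true_idx,
           direction = ifelse(seq_len(design$n_regions) %in% true_idx,
                              direction, 0L),
           mu_bg = mu_bg,
           mu_tum = clip01(mu_bg + direction * design$delta))
  })
  meta$ca19_9 <- simulate_ca199(design, meta$group, seed)

  n_s <- nrow(meta); n_r <- nrow(regions)
  theta <- matrix(NA_real_, n_s, n_r,
                  dimnames = list(meta$sample_id, regions$region_id))
  is_case <- meta$group == "PDAC"
  f <- ifelse(is_case, design$tumour_fraction, 0)

  chunks <- vector("list", n_s)
  withr::with_seed(derive_seed(seed, "reads"), {
    for (s in seq_len(n_s)) {
      theta[s, ] <- rbeta(n_r, truth_markers$mu_bg * design$kappa,
                          (1 - truth_markers$mu_bg) * design$kappa)
      theta_tum <- rbeta(n_r, truth_markers$mu_tum * design$kappa,
                         (1 - truth_markers$mu_tum) * design$kappa)
      silenced <- runif(n_r) < design$missing_rate
      n_reads <- rnbinom(n_r, size = design$coverage_dispersion,
                         mu = design$coverage_mean)
      n_reads[silenced] <- 0L
      per_region <- vector("list", n_r)
      for (r in which(n_reads > 0L)) {
        th_read <- rep(theta[s, r], n_reads[r])
        if (f[s] > 0 && truth_markers$is_true_marker[r]) {
          from_tum <- runif(n_reads[r]) < f[s]
          th_read[from_tum] <- theta_tum[r]
        }
        per_region[[r]] <- simulate_region_reads(
          regions$n_cpgs[r], th_read, design$rho, design$p_full_span
        )
      }
      keep <- which(!vapply(per_region, is.null, TRUE))
      if (!length(keep)) next
      n_per <- vapply(per_region[keep], function(x) length(x$first), 0L)
      chunks[[s]] <- tibble(
        sample_id = meta$sample_id[s],
        region_id = rep(regions$region_id[keep], n_per),
        first_idx = unlist(lapply(per_region[keep], `[[`, "first")),
        pattern = unlist(lapply(per_region[keep], `[[`, "pattern")),
        count = 1L
      )
    }
  })
  haps <- bind_rows(chunks)
  if (nrow(haps)) {
    haps <- aggregate_haplotypes(
      haps[, c("sample_id", "region_id", "first_idx", "pattern", "count")]
    )
  } else {
    haps <- tibble(sample_id = character(), region_id = character(),
                   first_idx = integer(), pattern = character(),
                   count = integer())
  }
  list(
    haplotypes = haps,
    meta = meta,
    truth = list(markers = truth_markers,
                 tumour_fraction = tibble(sample_id = meta$sample_id,
                                          tumour_fraction = f),
                 theta = theta)
  )
}

# one sample-region batch of reads: spans, co-methylation switch, pattern
# strings; returns list(first, pattern) vectors
simulate_region_reads <- function(m, th_read, rho, p_full_span) {
  n <- length(th_read)
  full <- runif(n) < p_full_span
  len <- ifelse(full, m, sample.int(m, n, replace = TRUE))
  first <- ifelse(len == m, 1L, floor(runif(n) * (m - len + 1L)) + 1L)
  comet <- runif(n) < rho
  th_pos <- rep(th_read, len)
  bits <- runif(sum(len)) < th_pos
  if (any(comet)) {
    shared <- runif(n) < th_read
    bits[rep(comet, len)] <- rep(shared, len)[rep(comet, len)]
  }
  big <- paste(c("0", "1")[bits + 1L], collapse = "")
  ends <- cumsum(len)
  list(first = as.integer(first),
       pattern = substring(big, ends - len + 1L, ends))
}

simulate_meta <- function(design, seed) {
  stage_levels <- c("I", "II", "III", "IV")
  stage_probs <- c(43, 119, 38, 23) / 223
  rows <- list()
  for (cohort in names(design$splits)) {
    n_ca <- design$splits[[cohort]][["cases"]]
    n_co <- design$splits[[cohort]][["controls"]]
    rows[[cohort]] <- tibble(
      sample_id = c(sprintf("%s_case_%03d", cohort, seq_len(n_ca)),
                    sprintf("%s_ctrl_%03d", cohort, seq_len(n_co))),
      group = c(rep("PDAC", n_ca), rep("Healthy", n_co)),
      cohort = cohort
    )
  }
  meta <- bind_rows(rows)
  withr::with_seed(derive_seed(seed, "meta"), {
    is_case <- meta$group == "PDAC"
    meta$stage <- NA_character_
    meta$stage[is_case] <- sample(stage_levels, sum(is_case), replace = TRUE,
                                  prob = stage_probs)
    meta$age <- round(ifelse(is_case, rnorm(nrow(meta), 62, 9),
                             rnorm(nrow(meta), 55, 12)))
    meta$age <- pmin(pmax(meta$age, 18), 90)
    meta$sex <- sample(c("M", "F"), nrow(meta), replace = TRUE)
  })
  meta$ca19_9 <- NA_real_
  meta
}

#' Simulate CA19-9 serum levels
#'
#' Group-wise lognormal draws (medians and log-sd from the design), with
#' exactly `ceiling(lewis_negative_fraction * n_cases)` randomly chosen
#' PDAC cases redrawn from the case distribution truncated below the
#' 37 U/ml positivity threshold, emulating Lewis-negative individuals.
#'
#' @param design A `cohort_design`.
#' @param groups Character vector of group labels (PDAC / CP / Healthy).
#' @param seed Seed (defaults to the design's).
#' @return Numeric vector of CA19-9 values in U/ml.
#' @export
simulate_ca199 <- function(design, groups, seed = design$seed) {
  p <- design$ca19_9
  withr::with_seed(derive_seed(seed, "ca199"), {
    vals <- numeric(length(groups))
    is_case <- groups == "PDAC"
    vals[is_case] <- rlnorm(sum(is_case), log(p$case_median), p$case_sdlog)
    vals[groups == "Healthy"] <- rlnorm(sum(groups == "Healthy"),
                                        log(p$ctrl_median), p$ctrl_sdlog)
    vals[groups == "CP"] <- rlnorm(sum(groups == "CP"),
                                   log(p$cp_median), p$cp_sdlog)
    n_neg <- ceiling(p$lewis_negative_fraction * sum(is_case))
    if (n_neg > 0L && sum(is_case) > 0L) {
      neg_idx <- sample(which(is_case), n_neg)
      cap <- plnorm(37, log(p$case_median), p$case_sdlog)
      vals[neg_idx] <- qlnorm(runif(n_neg, 0, cap),
                              log(p$case_median), p$case_sdlog)
    }
    vals
  })
}

#' @export
print.cohort_design <- function(x, ...) {
  sizes <- vapply(x$splits, function(s) sprintf("%d/%d", s[["cases"]],
                                                s[["controls"]]), "")
  cat(sprintf("<cohort_design> %d regions (%d true markers), delta %.2f, tumour fraction %.2f\n",
              x$n_regions, x$n_true_markers, x$delta, x$tumour_fraction))
  cat(sprintf("  splits: %s; coverage %gx; rho %.2f; seed %d\n",
              paste(names(sizes), sizes, sep = " ", collapse = ", "),
              x$coverage_mean, x$rho, x$seed))
  invisible(x)
}
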