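# shared fixtures and independent oracles

# Brute-force oracle for the seven measurements: expands every record into
# count replicates and enumerates every substring of every read literally.
# Intentionally naive and independent of the package implementation.
oracle_metrics <- function(first_idx, pattern, count, m) {
  reads <- list()
  for (r in seq_along(pattern)) {
    for (c in seq_len(count[r])) {
      reads[[length(reads) + 1L]] <- list(first = first_idx[r],
                                          bits = strsplit(pattern[r], "")[[1L]])
    }
  }
  if (!length(reads)) {
    return(c(depth = 0, amf = NA, mhl = NA, mhl3 = NA, umhl = NA,
             umhl3 = NA, mhfm = NA, mhfu = NA))
  }
  all_bits <- unlist(lapply(reads, `[[`, "bits"))
  amf <- mean(all_bits == "1")

  p_meth <- p_unmeth <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    n_tot <- 0; n_meth <- 0; n_unmeth <- 0
    for (rd in reads) {
      L <- length(rd$bits)
      if (L < i) next
      for (s in 1:(L - i + 1)) {
        sub <- rd$bits[s:(s + i - 1)]
        n_tot <- n_tot + 1
        if (all(sub == "1")) n_meth <- n_meth + 1
        if (all(sub == "0")) n_unmeth <- n_unmeth + 1
      }
    }
    if (n_tot > 0) {
      p_meth[i] <- n_meth / n_tot
      p_unmeth[i] <- n_unmeth / n_tot
    }
  }
  wload <- function(p, w) {
    ok <- !is.na(p)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * p[ok]) / sum(w[ok])
  }
  i <- seq_len(m)
  full <- vapply(reads, function(rd) rd$first == 1 && length(rd$bits) == m, TRUE)
  if (!any(full)) {
    mhfm <- NA_real_; mhfu <- NA_real_
  } else {
    fr <- reads[full]
    mhfm <- mean(vapply(fr, function(rd) all(rd$bits == "1"), TRUE))
    mhfu <- mean(vapply(fr, function(rd) all(rd$bits == "0"), TRUE))
  }
  c(depth = length(reads), amf = amf,
    mhl = wload(p_meth, i), mhl3 = wload(p_meth, i^3),
    umhl = wload(p_unmeth, i), umhl3 = wload(p_unmeth, i^3),
    mhfm = mhfm, mhfu = mhfu)
}

# random haplotype set over a region with m CpGs
random_haps <- function(m, n_reads) {
  first <- integer(n_reads); pat <- character(n_reads)
  for (r in seq_len(n_reads)) {
    len <- sample.int(m, 1L)
    first[r] <- sample.int(m - len + 1L, 1L)
    pat[r] <- paste(sample(c("0", "1"), len, replace = TRUE), collapse = "")
  }
  tibble::tibble(first_idx = first, pattern = pat,
                 count = sample.int(3L, n_reads, replace = TRUE))
}

flip_pattern <- function(p) chartr("01", "10", p)

# metric_matrix directly from a samples x regions value matrix (same values
# for every measurement unless a named list of matrices is given)
mm_from_values <- function(vals, depth = NULL, min_depth = 10L) {
  if (is.matrix(vals)) {
    vals <- stats::setNames(lapply(mhb_metric_names, function(m) vals),
                            mhb_metric_names)
  }
  template <- vals[[1L]]
  if (is.null(depth)) {
    depth <- matrix(100L, nrow(template), ncol(template),
                    dimnames = dimnames(template))
  }
  structure(list(sample_ids = rownames(template),
                 region_ids = colnames(template),
                 depth = depth, metrics = vals,
                 min_depth = as.integer(min_depth)),
            class = "metric_matrix")
}

# labelled value matrix with planted case/control shifts in some columns
shifted_matrix <- function(n_per_group, n_regions, n_true, delta,
                           noise_sd = 0.15, base = 0.3) {
  samples <- c(sprintf("case_%03d", seq_len(n_per_group)),
               sprintf("ctrl_%03d", seq_len(n_per_group)))
  vals <- matrix(pmin(pmax(stats::rnorm(2 * n_per_group * n_regions, base,
                                        noise_sd), 0), 1),
                 2 * n_per_group, n_regions,
                 dimnames = list(samples, sprintf("r%03d", seq_len(n_regions))))
  if (n_true > 0) {
    vals[seq_len(n_per_group), seq_len(n_true)] <-
      pmin(pmax(stats::rnorm(n_per_group * n_true, base + delta, noise_sd),
                0), 1)
  }
  labels <- stats::setNames(rep(c("case", "control"), each = n_per_group),
                            samples)
  list(vals = vals, labels = labels,
       true_regions = if (n_true > 0) sprintf("r%03d", seq_len(n_true))
       else character())
}

write_region_fixture <- function(dir = withr::local_tempdir(.local_envir =
                                                              parent.frame())) {
  bed <- file.path(dir, "regions.bed")
  cpg <- file.path(dir, "cpgs.tsv")
  writeLines(c("chr1\t100\t200\tr1", "chr1\t300\t400\tr2"), bed)
  writeLines(c("chr1\t110", "chr1\t130", "chr1\t150",
               "chr1\t310", "chr1\t330", "chr1\t350", "chr1\t370"), cpg)
  list(bed = bed, cpg = cpg, dir = dir)
}
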