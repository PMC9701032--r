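#' Read a sample's read-level methylation haplotype counts
#'
#' Parses an mHap-style 6-column TSV (chrom, start, end, pattern, count,
#' strand) of collapsed read-level methylation haplotypes. `start` is the
#' forward-strand coordinate of the first CpG covered by the pattern;
#' `pattern` is a string over `1` (methylated) / `0` (unmethylated), one
#' character per consecutive CpG of the containing block. Strand is carried
#' by the format but ignored by all downstream measurements (reads are
#' assumed pre-collapsed to forward CpG units by the aligner).
#'
#' Records whose first CpG does not sit on any block's CpG ladder are
#' skipped (their number is kept in attribute `n_skipped` and reported via a
#' message). Patterns running past the end of a block are truncated to the
#' in-block CpGs. Identical (region, offset, pattern) records are
#' aggregated by summing counts.
#'
#' @param hap_path Path to the TSV (may be gzip-compressed).
#' @param regions A `region_set` from [read_regions()].
#' @param sample_id Sample identifier attached to the output; defaults to
#'   the file name without extension.
#' @return Tibble with columns `sample_id`, `region_id`, `first_idx`
#'   (1-based index into the block's CpG ladder), `pattern`, `count`,
#'   with attribute `n_skipped`.
#' @export
read_haplotypes <- function(hap_path, regions, sample_id = NULL) {
  assert_file(hap_path, "haplotype")
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(hap\\.)?tsv(\\.gz)?$", "", basename(hap_path))
  }
  raw <- readr::read_tsv(
    hap_path,
    col_names = c("chrom", "start", "end", "pattern", "count", "strand"),
    col_types = "ciicic", na = character(), progress = FALSE
  )
  if (nrow(raw) == 0L) {
    out <- tibble(sample_id = character(), region_id = character(),
                  first_idx = integer(), pattern = character(),
                  count = integer())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  bad <- which(grepl("[^01]", raw$pattern) | !nzchar(raw$pattern))
  if (length(bad)) {
    abort(sprintf("invalid haplotype pattern at line %d of %s: '%s'",
                  bad[1L], hap_path, raw$pattern[bad[1L]]))
  }
  if (any(is.na(raw$count)) || any(raw$count < 1L)) {
    abort(sprintf("haplotype counts must be positive integers in %s", hap_path))
  }
  haps <- map_haplotypes(raw, regions)
  n_skipped <- attr(haps, "n_skipped")
  if (n_skipped > 0L) {
    inform(sprintf("%s: skipped %d record(s) overlapping no region",
                   sample_id, n_skipped))
  }
  haps$sample_id <- sample_id
  out <- aggregate_haplotypes(haps[, c("sample_id", "region_id", "first_idx",
                                       "pattern", "count")])
  attr(out, "n_skipped") <- n_skipped
  out
}

# map raw records onto region CpG ladders; truncate patterns at region ends
map_haplotypes <- function(raw, regions) {
  key_chrom <- rep(regions$chrom, lengths(regions$cpgs))
  key_pos <- unlist(regions$cpgs)
  key_region <- rep(regions$region_id, lengths(regions$cpgs))
  key_idx <- unlist(lapply(lengths(regions$cpgs), seq_len))
  key_m <- rep(lengths(regions$cpgs), lengths(regions$cpgs))
  lookup <- match(paste0(raw$chrom, ":", raw$start),
                  paste0(key_chrom, ":", key_pos))
  keep <- !is.na(lookup)
  out <- tibble(
    region_id = key_region[lookup[keep]],
    first_idx = key_idx[lookup[keep]],
    pattern = raw$pattern[keep],
    count = as.integer(raw$count[keep])
  )
  room <- key_m[lookup[keep]] - out$first_idx + 1L
  out$pattern <- substr(out$pattern, 1L, room)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

# sum counts of identical (sample, region, offset, pattern) records;
# returns rows sorted on those keys
aggregate_haplotypes <- function(haps) {
  keys <- intersect(c("sample_id", "region_id", "first_idx", "pattern"),
                    names(haps))
  n <- nrow(haps)
  if (n == 0L) return(haps)
  o <- do.call(order, unname(as.list(haps[keys])))
  h <- haps[o, , drop = FALSE]
  boundary <- rep(TRUE, n)
  if (n > 1L) {
    same <- rep(TRUE, n - 1L)
    for (kcol in keys) {
      v <- h[[kcol]]
      same <- same & v[-1L] == v[-n]
    }
    boundary[-1L] <- !same
  }
  gid <- cumsum(boundary)
  total <- rowsum(as.numeric(h$count), gid, reorder = FALSE)
  out <- h[boundary, , drop = FALSE]
  out$count <- as.integer(total[, 1L])
  out
}

#' Write read-level haplotype counts to an mHap-style TSV
#'
#' Inverse of [read_haplotypes()] for a single sample.
#'
#' @param haps Haplotype tibble (`region_id`, `first_idx`, `pattern`,
#'   `count`).
#' @param regions A `region_set` used to restore genomic coordinates.
#' @param path Output path.
#' @return Invisibly, `haps`.
#' @export
write_haplotypes <- function(haps, regions, path) {
  i <- match(haps$region_id, regions$region_id)
  if (anyNA(i)) abort("haplotypes reference unknown region_id(s)")
  first_pos <- purrr::map2_dbl(regions$cpgs[i], haps$first_idx, ~ .x[.y])
  last_pos <- purrr::map2_dbl(regions$cpgs[i],
                              haps$first_idx + nchar(haps$pattern) - 1L,
                              ~ .x[.y])
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t+",
                   regions$chrom[i], as.integer(first_pos),
                   as.integer(last_pos) + 1L, haps$pattern,
                   as.integer(haps$count))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(haps)
}

#' Partition regions into methylation haplotype blocks by methylation LD
#'
#' Pools read-level haplotypes across samples and, within each input
#' region, computes the linkage-disequilibrium r-squared of the joint
#' methylated/unmethylated state for every adjacent CpG pair from the 2x2
#' counts of reads covering both sites. Maximal runs of at least
#' `min_cpgs` consecutive CpGs whose every adjacent pair has
#' r-squared >= `r2_min` are emitted as blocks.
#'
#' An adjacent pair with no co-covering reads is a block boundary. A pair
#' where one site is monomorphic among co-covering reads has undefined
#' r-squared; it is treated as linked when the observed haplotypes are
#' fully concordant (no read discordant at the pair) and as a boundary
#' otherwise.
#'
#' @param haps Haplotype tibble pooled over samples (as returned by
#'   [read_haplotypes()] or [simulate_cohort()]).
#' @param regions A `region_set`.
#' @param r2_min Minimum adjacent-pair r-squared (default 0.5).
#' @param min_cpgs Minimum CpGs per emitted block (default 3).
#' @return A `region_set` of blocks named `<region_id>.k`, each nested
#'   within its source region; deterministic.
#' @export
partition_mhbs <- function(haps, regions, r2_min = 0.5, min_cpgs = 3L) {
  out <- purrr::pmap(regions, function(region_id, chrom, start, end, n_cpgs,
                                       cpgs, ...) {
    h <- haps[haps$region_id == region_id, , drop = FALSE]
    if (n_cpgs < min_cpgs) return(NULL)
    r2 <- adjacent_r2(h, n_cpgs)
    linked <- !is.na(r2) & r2 >= r2_min
    blocks <- linked_runs(linked, min_cpgs)
    if (!nrow(blocks)) return(NULL)
    tibble(
      region_id = sprintf("%s.%d", region_id, seq_len(nrow(blocks))),
      chrom = chrom,
      start = vapply(blocks$from, function(j) cpgs[j], 0),
      end = vapply(blocks$to, function(j) cpgs[j], 0) + 1,
      n_cpgs = blocks$to - blocks$from + 1L,
      cpgs = purrr::map2(blocks$from, blocks$to, ~ cpgs[.x:.y])
    )
  })
  out <- bind_rows(out)
  if (!nrow(out)) {
    out <- tibble(region_id = character(), chrom = character(),
                  start = double(), end = double(), n_cpgs = integer(),
                  cpgs = list())
  }
  new_region_set(out)
}

# r^2 of methylation state for each adjacent CpG pair (j, j+1); NA when
# undefined. Concordant-monomorphic pairs score 1, discordant ones NA.
adjacent_r2 <- function(h, m) {
  if (m < 2L) return(numeric(0))
  r2 <- rep(NA_real_, m - 1L)
  if (!nrow(h)) return(r2)
  last_idx <- h$first_idx + nchar(h$pattern) - 1L
  for (j in seq_len(m - 1L)) {
    cover <- h$first_idx <= j & last_idx >= j + 1L
    if (!any(cover)) next
    a <- substr(h$pattern[cover], j - h$first_idx[cover] + 1L,
                j - h$first_idx[cover] + 1L) == "1"
    b <- substr(h$pattern[cover], j - h$first_idx[cover] + 2L,
                j - h$first_idx[cover] + 2L) == "1"
    w <- h$count[cover]
    n <- sum(w)
    p_a <- sum(w[a]) / n
    p_b <- sum(w[b]) / n
    p_ab <- sum(w[a & b]) / n
    den <- p_a * (1 - p_a) * p_b * (1 - p_b)
    if (den > 0) {
      r2[j] <- (p_ab - p_a * p_b)^2 / den
    } else if (sum(w[a != b]) == 0) {
      r2[j] <- 1
    }
  }
  r2
}

# maximal runs of consecutive CpGs (length >= min_cpgs) whose every
# internal adjacency is linked
linked_runs <- function(linked, min_cpgs) {
  from <- integer(0); to <- integer(0)
  j <- 1L
  m <- length(linked) + 1L
  while (j <= length(linked)) {
    if (!linked[j]) { j <- j + 1L; next }
    k <- j
    while (k < length(linked) && linked[k + 1L]) k <- k + 1L
    if (k - j + 2L >= min_cpgs) { from <- c(from, j); to <- c(to, k + 1L) }
    j <- k + 1L
  }
  tibble(from = from, to = to)
}
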