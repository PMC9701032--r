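test_that("read_regions attaches in-interval CpGs with half-open semantics", {
  fx <- write_region_fixture()
  regions <- read_regions(fx$bed, fx$cpg)
  expect_s3_class(regions, "region_set")
  expect_equal(regions$region_id, c("r1", "r2"))
  expect_equal(regions$cpgs[[1]], c(110, 130, 150))
  expect_equal(regions$n_cpgs, c(3L, 4L))

  # a CpG exactly at end is outside the half-open interval
  writeLines("chr1\t100\t200\tr1", fx$bed)
  writeLines("chr1\t200", fx$cpg)
  expect_error(read_regions(fx$bed, fx$cpg), "no CpGs")
})

test_that("read_regions rejects malformed and duplicate input", {
  fx <- write_region_fixture()
  writeLines(c("chr1\t100\t200\tr1", "chr1\t100\t200\tr1"), fx$bed)
  expect_error(read_regions(fx$bed, fx$cpg), "duplicate region_id")

  writeLines(c("chr1\t100\t200\tr1", "chr1\t300"), fx$bed)
  expect_error(read_regions(fx$bed, fx$cpg), "line 2")
})

test_that("read_haplotypes maps, truncates, aggregates and validates", {
  fx <- write_region_fixture()
  regions <- read_regions(fx$bed, fx$cpg)
  hap <- file.path(fx$dir, "s1.hap.tsv")

  writeLines(c("chr1\t110\t131\t11\t3\t+",
               "chr1\t130\t151\t10\t2\t+",
               "chr1\t130\t151\t10\t1\t+",
               "chr1\t900\t920\t11\t5\t+"), hap)
  haps <- read_haplotypes(hap, regions, sample_id = "s1")
  expect_equal(attr(haps, "n_skipped"), 1L)
  expect_equal(nrow(haps), 2L)
  expect_equal(haps$count[haps$first_idx == 2L], 3L)  # 2 + 1 aggregated
  expect_equal(haps$first_idx[haps$pattern == "11"], 1L)

  # pattern running past the ladder is truncated to in-region CpGs
  writeLines("chr1\t130\t400\t10111\t1\t+", hap)
  haps <- read_haplotypes(hap, regions, sample_id = "s1")
  expect_equal(haps$pattern, "10")

  writeLines("chr1\t110\t131\t1X1\t1\t+", hap)
  expect_error(read_haplotypes(hap, regions), "pattern")
})

test_that("region and haplotype round-trips preserve content and counts", {
  design <- cohort_design(n_regions = 12L, n_true_markers = 2L,
                          splits = list(train = c(cases = 2L, controls = 2L)),
                          coverage_mean = 20, seed = 11L)
  regions <- simulate_regions(design)
  cohort <- simulate_cohort(design, regions)

  dir <- withr::local_tempdir()
  write_regions(regions, file.path(dir, "r.bed"), file.path(dir, "c.tsv"))
  back <- read_regions(file.path(dir, "r.bed"), file.path(dir, "c.tsv"))
  expect_equal(back$region_id, regions$region_id)
  expect_equal(back$cpgs, regions$cpgs)

  sid <- cohort$meta$sample_id[1]
  haps <- dplyr::filter(cohort$haplotypes, sample_id == sid)
  write_haplotypes(haps, regions, file.path(dir, "s.hap.tsv"))
  back_h <- read_haplotypes(file.path(dir, "s.hap.tsv"), regions,
                            sample_id = sid)
  expect_equal(back_h$region_id, haps$region_id)
  expect_equal(back_h$first_idx, haps$first_idx)
  expect_equal(back_h$pattern, haps$pattern)
  expect_equal(back_h$count, haps$count)
  # aggregation conserves the per-region total read count
  expect_equal(sum(back_h$count), sum(haps$count))
})

test_that("metadata round-trips through the TSV format", {
  meta <- tibble::tibble(sample_id = c("a", "b"), group = c("PDAC", "Healthy"),
                         cohort = c("train", "train"),
                         stage = c("II", NA), ca19_9 = c(421.6, NA),
                         age = c(63, 55), sex = c("M", "F"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_meta(meta, path)
  expect_equal(as.data.frame(read_sample_meta(path)), as.data.frame(meta))
})

test_that("partition_mhbs keeps perfectly linked ladders and splits by r2", {
  regions <- haplomark:::new_region_set(tibble::tibble(
    region_id = "r1", chrom = "chr1", start = 100, end = 200,
    n_cpgs = 4L, cpgs = list(c(110, 130, 150, 170))
  ))
  # perfect LD: reads are all-1 or all-0 across all four CpGs
  haps <- tibble::tibble(sample_id = "s", region_id = "r1", first_idx = 1L,
                         pattern = c("1111", "0000"), count = c(10L, 10L))
  blocks <- partition_mhbs(haps, regions, r2_min = 0.5, min_cpgs = 3L)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$n_cpgs, 4L)
  expect_equal(blocks$cpgs[[1]], c(110, 130, 150, 170))

  # independent CpGs: no 3-CpG block survives
  set.seed(5)
  pats <- apply(matrix(sample(c("0", "1"), 400 * 4, replace = TRUE), 400), 1,
                paste, collapse = "")
  haps_ind <- tibble::tibble(sample_id = "s", region_id = "r1",
                             first_idx = 1L, pattern = pats, count = 1L)
  expect_equal(nrow(partition_mhbs(haps_ind, regions, min_cpgs = 3L)), 0L)
})

test_that("partition_mhbs splits at the pair whose r2 falls below threshold", {
  regions <- haplomark:::new_region_set(tibble::tibble(
    region_id = "r1", chrom = "chr1", start = 100, end = 200,
    n_cpgs = 3L, cpgs = list(c(110, 130, 150))
  ))
  # pair (1,2): counts 45/5/5/45 -> r2 = 0.64; pair (2,3): 30/20/20/30 -> 0.04
  pair_counts <- function(first, n11, n10, n01, n00) {
    tibble::tibble(sample_id = "s", region_id = "r1", first_idx = first,
                   pattern = c("11", "10", "01", "00"),
                   count = c(n11, n10, n01, n00))
  }
  haps <- dplyr::bind_rows(pair_counts(1L, 45L, 5L, 5L, 45L),
                           pair_counts(2L, 30L, 20L, 20L, 30L))
  # independent hand computation of LD r2 from the 2x2 table
  r2_hand <- function(n11, n10, n01, n00) {
    n <- n11 + n10 + n01 + n00
    pa <- (n11 + n10) / n; pb <- (n11 + n01) / n
    (n11 / n - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
  }
  expect_equal(r2_hand(45, 5, 5, 45), 0.64)
  expect_equal(r2_hand(30, 20, 20, 30), 0.04)

  blocks <- partition_mhbs(haps, regions, r2_min = 0.5, min_cpgs = 2L)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$cpgs[[1]], c(110, 130))  # CpGs 1-2 only

  # blocks nest within the parent region
  expect_true(all(blocks$start >= regions$start & blocks$end <= regions$end))
})
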