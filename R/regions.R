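#' Read methylation haplotype block (MHB) definitions
#'
#' Reads a BED4 file of block intervals and a two-column TSV of CpG
#' coordinates and attaches to every block the ordered CpG positions falling
#' inside it. Coordinates are BED-style: 0-based, half-open `[start, end)`;
#' a CpG position refers to the C of the CpG dinucleotide on the forward
#' strand.
#'
#' @param region_path Path to a BED file with at least 4 columns
#'   (chrom, start, end, region_id). Extra columns are ignored.
#' @param cpg_path Path to a TSV with two columns (chrom, pos), no header.
#' @return A `region_set`: a tibble with columns `region_id`, `chrom`,
#'   `start`, `end`, `n_cpgs` and a list-column `cpgs` of sorted CpG
#'   positions. Blocks containing no CpG are an error — a block is defined
#'   by its CpG content.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tr1", bed)
#' cpg <- tempfile(fileext = ".tsv")
#' writeLines(c("chr1\t110", "chr1\t150"), cpg)
#' read_regions(bed, cpg)
#' @export
read_regions <- function(region_path, cpg_path) {
  assert_file(region_path, "region BED")
  assert_file(cpg_path, "CpG table")

  bed_lines <- readLines(region_path)
  bed_lines <- bed_lines[nzchar(trimws(bed_lines))]
  rows <- strsplit(bed_lines, "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, 1L) < 4L)
  if (length(bad)) {
    abort(sprintf("malformed BED line %d in %s: expected >= 4 tab-separated fields",
                  bad[1L], region_path))
  }
  chrom <- vapply(rows, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 3L)))
  region_id <- vapply(rows, `[[`, "", 4L)
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) {
    abort(sprintf("malformed BED line %d in %s: bad interval", bad[1L], region_path))
  }
  dup <- region_id[duplicated(region_id)]
  if (length(dup)) {
    abort(sprintf("duplicate region_id in %s: %s", region_path,
                  paste(unique(dup), collapse = ", ")))
  }

  cpg <- read_cpgs(cpg_path)

  cpgs <- purrr::pmap(list(chrom, start, end), function(ch, s, e) {
    p <- cpg$pos[cpg$chrom == ch]
    sort(p[p >= s & p < e])
  })
  empty <- which(lengths(cpgs) == 0L)
  if (length(empty)) {
    abort(sprintf("region(s) with no CpGs: %s",
                  paste(region_id[empty], collapse = ", ")))
  }

  new_region_set(tibble(
    region_id = region_id, chrom = chrom, start = start, end = end,
    n_cpgs = lengths(cpgs), cpgs = cpgs
  ))
}

#' Read a CpG coordinate table
#'
#' @param cpg_path TSV with columns chrom, pos (0-based C coordinate), no
#'   header.
#' @return Tibble with columns `chrom`, `pos`, sorted within chromosome.
#' @export
read_cpgs <- function(cpg_path) {
  lines <- readLines(cpg_path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, 1L) < 2L)
  if (length(bad)) {
    abort(sprintf("malformed CpG line %d in %s", bad[1L], cpg_path))
  }
  chrom <- vapply(rows, `[[`, "", 1L)
  pos <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 2L)))
  bad <- which(is.na(pos))
  if (length(bad)) {
    abort(sprintf("malformed CpG line %d in %s: non-numeric position",
                  bad[1L], cpg_path))
  }
  out <- tibble(chrom = chrom, pos = pos) %>% arrange(.data$chrom, .data$pos)
  if (anyDuplicated(out)) abort("duplicate (chrom, pos) entries in CpG table")
  out
}

new_region_set <- function(tbl) {
  stopifnot(all(c("region_id", "chrom", "start", "end", "cpgs") %in% names(tbl)))
  if (anyDuplicated(tbl$region_id)) abort("region_ids must be unique")
  ok <- purrr::pmap_lgl(list(tbl$cpgs, tbl$start, tbl$end), function(p, s, e) {
    length(p) >= 1L && !is.unsorted(p, strictly = TRUE) && all(p >= s & p < e)
  })
  if (!all(ok)) {
    abort(sprintf("invalid CpG ladder for region(s): %s",
                  paste(tbl$region_id[!ok], collapse = ", ")))
  }
  tbl$n_cpgs <- lengths(tbl$cpgs)
  structure(tbl, class = c("region_set", class(tibble())))
}

#' Write region definitions back to BED + CpG TSV
#'
#' Inverse of [read_regions()]; writing then reading reproduces the same
#' region set.
#'
#' @param regions A `region_set`.
#' @param region_path,cpg_path Output paths.
#' @return Invisibly, `regions`.
#' @export
write_regions <- function(regions, region_path, cpg_path) {
  bed <- sprintf("%s\t%d\t%d\t%s", regions$chrom, as.integer(regions$start),
                 as.integer(regions$end), regions$region_id)
  writeLines(bed, region_path)
  cpg <- tibble(
    chrom = rep(regions$chrom, lengths(regions$cpgs)),
    pos = unlist(regions$cpgs)
  ) %>% distinct() %>% arrange(.data$chrom, .data$pos)
  writeLines(sprintf("%s\t%d", cpg$chrom, as.integer(cpg$pos)), cpg_path)
  invisible(regions)
}

#' Read the sample metadata table
#'
#' @param path TSV with header columns `sample_id`, `group`, `cohort`,
#'   `stage`, `ca19_9`, `age`, `sex`; empty strings mark missing values.
#'   `group` is one of PDAC, CP, Healthy; `cohort` one of train, validation,
#'   test, discovery; `ca19_9` in U/ml.
#' @return Tibble with those columns and proper types.
#' @export
read_sample_meta <- function(path) {
  assert_file(path, "sample metadata")
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    cohort = readr::col_character(),
    stage = readr::col_character(),
    ca19_9 = readr::col_double(),
    age = readr::col_double(),
    sex = readr::col_character()
  ), na = c("", "NA"), progress = FALSE)
  required <- c("sample_id", "group", "cohort", "stage", "ca19_9", "age", "sex")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort(sprintf("metadata missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) abort("sample_ids must be unique")
  if (any(!is.na(meta$ca19_9) & meta$ca19_9 < 0)) abort("ca19_9 must be >= 0")
  bad_group <- setdiff(unique(meta$group), c("PDAC", "CP", "Healthy"))
  if (length(bad_group)) {
    abort(sprintf("unknown group(s): %s", paste(bad_group, collapse = ", ")))
  }
  meta
}

#' Write a sample metadata table
#' @param meta Tibble as returned by [read_sample_meta()].
#' @param path Output TSV path.
#' @return Invisibly, `meta`.
#' @export
write_sample_meta <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(meta)
}
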