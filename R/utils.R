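# internal helpers shared across modules

# Derive a reproducible child seed (< 2^31) from a master seed and a tag.
# Linear congruential mix over the tag characters; avoids any dependency on
# the global RNG state.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

clip01 <- function(x, lo = 0.02, hi = 0.98) pmin(pmax(x, lo), hi)

# binary label vector -> factor with levels control, case
as_case_factor <- function(labels, positive = NULL) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "case", "control")
  u <- sort(unique(labels))
  if (length(u) != 2L) {
    abort(sprintf("labels must contain exactly 2 classes, got %d", length(u)))
  }
  if (is.null(positive)) {
    positive <- if ("PDAC" %in% u) "PDAC" else if ("case" %in% u) "case" else u[2L]
  }
  factor(ifelse(labels == positive, "case", "control"),
         levels = c("control", "case"))
}

`%+%` <- function(a, b) paste0(a, b)

assert_file <- function(path, what) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  invisible(path)
}
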