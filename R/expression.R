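# Count tables are tibbles with a `feature_id` column followed by one
# numeric column per sample.

.count_matrix <- function(counts) {
  if (!"feature_id" %in% names(counts)) abort("count table needs a feature_id column")
  m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
  if (!is.numeric(m)) abort("sample columns must be numeric")
  if (any(m < 0)) abort("counts must be non-negative")
  rownames(m) <- counts$feature_id
  m
}

.matrix_to_tbl <- function(m) {
  dplyr::bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
}

#' Read a counts TSV (features x samples)
#'
#' First column is the feature id, remaining header columns are sample ids.
#'
#' @param path Path to a tab-separated count table.
#' @return A count tibble with a `feature_id` column.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  names(df)[1] <- "feature_id"
  df$feature_id <- as.character(df$feature_id)
  df
}

#' Read a sample sheet TSV
#'
#' Expected columns: `sample_id`, `tissue` and `timepoint`.
#'
#' @param path Path to a tab-separated sample sheet.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "tissue", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort(paste0("sample sheet missing: ", paste(miss, collapse = ", ")))
  df
}

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over features (with a
#' positive geometric mean across samples) of `count_ij / geomean_i` —
#' the normalization used to correct for library size and RNA composition.
#'
#' @param counts A count tibble (`feature_id` + sample columns).
#' @return A tibble (`sample_id`, `size_factor`), all factors positive.
#' @export
size_factors <- function(counts) {
  m <- .count_matrix(counts)
  loggeo <- rowMeans(log(m))
  use <- is.finite(loggeo)
  if (!any(use)) {
    abort(paste0(
      "no feature has positive counts in every sample; ",
      "supply a pseudo-reference or filter samples first"
    ))
  }
  lr <- log(m[use, , drop = FALSE]) - loggeo[use]
  sf <- exp(apply(lr, 2, stats::median))
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Normalize counts by size factors
#'
#' @param counts A count tibble.
#' @param sf A size-factor tibble from [size_factors()] (computed from
#'   `counts` when omitted).
#' @return A tibble of normalized counts `count_ij / s_j`.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  m <- .count_matrix(counts)
  s <- sf$size_factor[match(colnames(m), sf$sample_id)]
  if (anyNA(s)) abort("size factors missing for some samples")
  .matrix_to_tbl(sweep(m, 2, s, "/"))
}

#' Expression filter: truly expressed features
#'
#' A feature is retained iff its normalized count exceeds `min_count`
#' (strictly) in at least `ceiling(min_fraction * n_samples)` libraries —
#' the "normalized counts >5 in at least 10% of libraries" rule.
#'
#' @param counts A count tibble.
#' @param sf Size factors (computed from `counts` when omitted).
#' @param min_count Normalized-count threshold (default 5, strict `>`).
#' @param min_fraction Minimum fraction of libraries (default 0.10).
#' @return Character vector of retained feature ids.
#' @export
filter_expressed <- function(counts, sf = size_factors(counts),
                             min_count = 5, min_fraction = 0.10) {
  norm <- .count_matrix(normalize_counts(counts, sf))
  need <- ceiling(min_fraction * ncol(norm))
  keep <- rowSums(norm > min_count) >= need
  rownames(norm)[keep]
}
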