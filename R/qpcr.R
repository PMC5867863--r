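#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Technical replicate Ct values are collapsed by mean per sample and
#' gene; per sample, `dCt = Ct_target - Ct_housekeeper`; `ddCt` subtracts
#' the mean dCt of the reference condition; the relative quantity is
#' `RQ = 2^-ddCt`, and the condition fold change is the mean RQ of each
#' test condition.
#'
#' @param ct A long Ct tibble with columns `sample_id`, `condition`,
#'   `gene`, `ct` (one row per technical replicate; Ct > 0).
#' @param target,housekeeper Gene names in `ct`; the housekeeper must be
#'   measured in every sample of the target.
#' @param reference_condition The baseline condition (e.g. `"D33"`).
#' @return A tibble with one row per sample (`sample_id`, `condition`,
#'   `dct`, `ddct`, `rq`) and a `fold_change` attribute tibble (mean RQ
#'   per non-reference condition).
#' @export
ddct <- function(ct, target, housekeeper, reference_condition) {
  need <- c("sample_id", "condition", "gene", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0) abort(paste0("Ct table missing: ", paste(miss, collapse = ", ")))
  if (any(ct$ct <= 0)) abort("Ct values must be positive")
  mean_ct <- ct %>%
    filter(.data$gene %in% c(target, housekeeper)) %>%
    group_by(.data$sample_id, .data$condition, .data$gene) %>%
    summarise(ct = mean(.data$ct), .groups = "drop")
  wide <- tidyr::pivot_wider(mean_ct, names_from = "gene", values_from = "ct")
  if (!housekeeper %in% names(wide) || anyNA(wide[[housekeeper]])) {
    bad <- wide$sample_id[is.na(wide[[housekeeper]] %||% rep(NA, nrow(wide)))]
    abort(paste0(
      "housekeeper ", housekeeper, " missing for sample(s): ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  if (!target %in% names(wide)) abort(paste0("target ", target, " not in Ct table"))
  wide <- filter(wide, !is.na(.data[[target]]))
  if (!reference_condition %in% wide$condition) {
    abort(paste0("reference condition ", reference_condition, " absent"))
  }
  out <- wide %>%
    mutate(dct = .data[[target]] - .data[[housekeeper]]) %>%
    mutate(ddct = .data$dct - mean(.data$dct[.data$condition == reference_condition])) %>%
    mutate(rq = 2^(-.data$ddct)) %>%
    select("sample_id", "condition", "dct", "ddct", "rq")
  fc <- out %>%
    filter(.data$condition != reference_condition) %>%
    group_by(.data$condition) %>%
    summarise(fold_change = mean(.data$rq), .groups = "drop")
  attr(out, "fold_change") <- fc
  attr(out, "reference_condition") <- reference_condition
  out
}

#' Pooled-variance two-sample t-test on relative quantities
#'
#' Student's t-test with homogeneous variances, as used for qPCR
#' validation of DE calls.
#'
#' @param rq_a,rq_b Numeric vectors (n >= 2 each).
#' @return A one-row tibble (`t`, `df`, `p`, `mean_a`, `mean_b`).
#' @export
qpcr_t_test <- function(rq_a, rq_b) {
  if (length(rq_a) < 2 || length(rq_b) < 2) abort("need n >= 2 per group")
  if (stats::sd(c(rq_a - mean(rq_a), rq_b - mean(rq_b))) == 0) {
    abort("zero pooled variance")
  }
  tt <- stats::t.test(rq_a, rq_b, var.equal = TRUE)
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    mean_a = mean(rq_a), mean_b = mean(rq_b)
  )
}
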