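#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order (`p_bh >= p`, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Signed fold change from a log2 fold change
#'
#' `sign(log2FC) * 2^|log2FC|`: down-regulation is reported as a negative
#' fold change, matching the paired log2FC / FC reporting convention of
#' two-timepoint DE tables. `fc_from_log2fc(0)` is 1.
#'
#' @param log2fc Finite numeric vector of log2 fold changes.
#' @return Signed fold changes.
#' @export
fc_from_log2fc <- function(log2fc) {
  ifelse(log2fc == 0, 1, sign(log2fc) * 2^abs(log2fc))
}

#' Inverse of [fc_from_log2fc()]
#'
#' @param fc Signed fold change (|fc| >= 1 or negative).
#' @return The log2 fold change.
#' @export
log2fc_from_fc <- function(fc) {
  ifelse(fc == 1, 0, sign(fc) * log2(abs(fc)))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-feature dispersion `alpha = max(0, (v - mu) / mu^2)` where `v` is
#' the within-group pooled variance of normalized counts and `mu` their
#' overall mean. Poisson-like features (variance <= mean) get 0.
#'
#' @param norm Numeric matrix of normalized counts (features x samples).
#' @param group_a,group_b Column indices (or names) of the two groups.
#' @return Numeric vector of dispersions (NA where the mean is zero).
#' @export
estimate_dispersion <- function(norm, group_a, group_b) {
  ya <- norm[, group_a, drop = FALSE]
  yb <- norm[, group_b, drop = FALSE]
  na <- ncol(ya)
  nb <- ncol(yb)
  if (na < 2 || nb < 2) abort("need at least 2 samples per group")
  ssa <- rowSums((ya - rowMeans(ya))^2)
  ssb <- rowSums((yb - rowMeans(yb))^2)
  v <- (ssa + ssb) / (na + nb - 2)
  mu <- rowMeans(cbind(ya, yb))
  alpha <- pmax(0, (v - mu) / mu^2)
  alpha[mu == 0] <- NA_real_
  alpha
}

#' Two-group negative-binomial Wald differential expression
#'
#' A deliberately transparent simplification of shrinkage-based NB DE:
#' counts are normalized by median-of-ratios size factors, group means are
#' fitted on the normalized scale (pseudocount 0.5 substituted for a zero
#' group mean), dispersion is method-of-moments ([estimate_dispersion()]),
#' and the Wald statistic `log2FC / SE` uses the delta-method standard
#' error from the NB variance `mu/s_j + alpha * mu^2` of normalized counts.
#' P-values are two-sided from a t reference with `nA + nB - 2` degrees of
#' freedom (the dispersion is estimated from the same small samples, so a
#' t reference keeps the null rejection rate at its nominal level; a
#' normal reference is anticonservative at n of order 16 per group).
#' No dispersion shrinkage, independent filtering or outlier handling is
#' performed.
#'
#' @param counts A count tibble (`feature_id` + sample columns).
#' @param sample_sheet A tibble with `sample_id` and `timepoint` columns
#'   covering the count columns.
#' @param group_a,group_b Timepoint labels; `log2FC` is
#'   `log2(mean_B / mean_A)` (e.g. D96 vs D33).
#' @param sf Size factors (computed from `counts` when omitted).
#' @param alpha Significance level on `p_bh` (default 0.05).
#' @return A `wean_de` tibble: `feature_id`, `baseMean`, `log2FC`, `FC`,
#'   `dispersion`, `stat`, `p`, `p_bh`, `significant`, plus a `skipped`
#'   attribute listing zero-mean features.
#' @export
de_test <- function(counts, sample_sheet, group_a = "D33", group_b = "D96",
                    sf = size_factors(counts), alpha = 0.05) {
  m <- .count_matrix(counts)
  ids_a <- sample_sheet$sample_id[sample_sheet$timepoint == group_a]
  ids_b <- sample_sheet$sample_id[sample_sheet$timepoint == group_b]
  ids_a <- intersect(colnames(m), ids_a)
  ids_b <- intersect(colnames(m), ids_b)
  if (length(ids_a) == 0 || length(ids_b) == 0) abort("both groups must be non-empty")
  s <- sf$size_factor[match(colnames(m), sf$sample_id)]
  norm <- sweep(m, 2, s, "/")
  ya <- norm[, ids_a, drop = FALSE]
  yb <- norm[, ids_b, drop = FALSE]
  na <- length(ids_a)
  nb <- length(ids_b)
  base_mean <- rowMeans(cbind(ya, yb))
  skipped <- rownames(m)[base_mean == 0]
  disp <- estimate_dispersion(norm, ids_a, ids_b)
  qa <- rowMeans(ya)
  qb <- rowMeans(yb)
  zero_flag <- qa == 0 | qb == 0
  qa_f <- pmax(qa, 0.5)
  qb_f <- pmax(qb, 0.5)
  log2fc <- log2(qb_f / qa_f)
  inv_s_a <- sum(1 / s[match(ids_a, colnames(m))])
  inv_s_b <- sum(1 / s[match(ids_b, colnames(m))])
  var_qa <- (qa_f * inv_s_a + na * disp * qa_f^2) / na^2
  var_qb <- (qb_f * inv_s_b + nb * disp * qb_f^2) / nb^2
  se <- sqrt(var_qa / qa_f^2 + var_qb / qb_f^2) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pt(-abs(stat), df = na + nb - 2)
  keep <- base_mean > 0
  out <- tibble(
    feature_id = rownames(m)[keep],
    baseMean = unname(base_mean[keep]),
    log2FC = unname(log2fc[keep]),
    FC = unname(fc_from_log2fc(log2fc[keep])),
    dispersion = unname(disp[keep]),
    stat = unname(stat[keep]),
    p = unname(p[keep]),
    zero_group_mean = unname(zero_flag[keep])
  )
  out$p_bh <- bh_adjust(out$p)
  out$significant <- out$p_bh < alpha
  attr(out, "skipped") <- skipped
  attr(out, "groups") <- c(a = group_a, b = group_b)
  attr(out, "n_per_group") <- c(a = na, b = nb)
  attr(out, "alpha") <- alpha
  class(out) <- c("wean_de", class(out))
  out
}

#' @export
print.wean_de <- function(x, ...) {
  g <- attr(x, "groups")
  cat(
    "<wean_de> ", nrow(x), " features, ", sum(x$significant),
    " significant (p.BH < ", attr(x, "alpha"), "), ",
    g["b"], " vs ", g["a"], "\n",
    sep = ""
  )
  NextMethod()
}
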