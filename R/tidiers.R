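#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a DE result
#'
#' @param x A `wean_de` object.
#' @param ... Unused.
#' @return A plain tibble of the per-feature results.
#' @export
tidy.wean_de <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a DE result
#'
#' @param x A `wean_de` object.
#' @param ... Unused.
#' @return A tibble with feature counts, significance counts and design.
#' @export
glance.wean_de <- function(x, ...) {
  g <- attr(x, "groups")
  n <- attr(x, "n_per_group")
  tibble(
    n_features = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$log2FC > 0),
    n_down = sum(x$significant & x$log2FC < 0),
    alpha = attr(x, "alpha"),
    group_a = unname(g["a"]), group_b = unname(g["b"]),
    n_a = unname(n["a"]), n_b = unname(n["b"])
  )
}

#' Tidy a cis-target result
#'
#' @param x A `wean_cis` object.
#' @param ... Unused.
#' @return A plain tibble of tested pairs.
#' @export
tidy.wean_cis <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a cis-target result
#'
#' @param x A `wean_cis` object.
#' @param ... Unused.
#' @return A tibble with pair, target and degree-summary counts.
#' @export
glance.wean_cis <- function(x, ...) {
  tibble(
    n_pairs_tested = nrow(x),
    n_cis_targets = sum(x$is_cis_target),
    n_lncrnas_with_target = nrow(attr(x, "targets_per_lncrna")),
    n_genes_targeted = nrow(attr(x, "lncrnas_per_gene")),
    n_dropped = nrow(attr(x, "dropped")),
    alpha = attr(x, "alpha"),
    n_samples = attr(x, "n_samples")
  )
}

#' Tidy an enrichment result
#'
#' @param x A `wean_enrich` object.
#' @param ... Unused.
#' @return A plain tibble of per-set results.
#' @export
tidy.wean_enrich <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of an enrichment result
#'
#' @param x A `wean_enrich` object.
#' @param ... Unused.
#' @return A tibble with set counts and the correction regime.
#' @export
glance.wean_enrich <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_significant = sum(x$significant),
    correction = attr(x, "correction"),
    alpha = attr(x, "alpha")
  )
}

#' Tidy a coding model
#'
#' @param x A `coding_model` object.
#' @param ... Passed on.
#' @return Coefficient table of the logistic combiner.
#' @export
tidy.coding_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s), estimate = unname(x$coefficients[rownames(s)]),
    std_error = s[, 2], statistic = s[, 3], p_value = s[, 4]
  )
}

#' One-row summary of a coding model
#'
#' @param x A `coding_model` object.
#' @param ... Unused.
#' @return Deviance-based fit summary.
#' @export
glance.coding_model <- function(x, ...) {
  f <- x$fit
  tibble(
    null_deviance = f$null.deviance, deviance = f$deviance,
    aic = f$aic, n = length(f$y), converged = f$converged
  )
}
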