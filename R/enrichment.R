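#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   member genes...).
#' @return A named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(
    lapply(parts, function(p) unique(p[-(1:2)])),
    vapply(parts, `[[`, character(1), 1)
  )
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(
    names(sets),
    function(nm) paste(c(nm, description, sets[[nm]]), collapse = "\t"),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a gene list
#'
#' For each set, the p-value is the upper tail `P[X >= k]` of the
#' hypergeometric distribution with universe size N, set size K and query
#' size n, where k is the query/set overlap. Two significance regimes are
#' supported: `correction = "bh"` adjusts across sets
#' (ontology-style reporting) and `correction = "none"` reports raw
#' p-values (pathway-style reporting at uncorrected p < 0.05).
#'
#' @param query Character vector of gene ids; members outside the universe
#'   are dropped with a warning.
#' @param sets Named list of gene sets (as from [read_gmt()]); members
#'   outside the universe are ignored.
#' @param universe Character vector of background gene ids (typically the
#'   expressed genes of the tissue).
#' @param correction `"bh"` or `"none"`.
#' @param alpha Significance level (default 0.05).
#' @return A `wean_enrich` tibble: `set_name`, `overlap` (k), `set_size`
#'   (K), `query_size` (n), `universe_size` (N), `p`, `p_adj`,
#'   `significant`, sorted by p.
#' @export
enrich_hypergeom <- function(query, sets, universe,
                             correction = c("bh", "none"), alpha = 0.05) {
  correction <- match.arg(correction)
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(paste0(length(outside), " query gene(s) outside the universe dropped"))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) abort("empty query after universe restriction")
  if (any(lengths(sets) == 0)) abort("empty gene set")
  N <- length(universe)
  n <- length(query)
  res <- purrr::imap_dfr(sets, function(members, nm) {
    members <- intersect(unique(members), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(
      set_name = nm, overlap = k, set_size = K,
      query_size = n, universe_size = N, p = p
    )
  })
  res$p_adj <- if (correction == "bh") bh_adjust(res$p) else res$p
  res$significant <- res$p_adj < alpha
  res <- arrange(res, .data$p, .data$set_name)
  attr(res, "correction") <- correction
  attr(res, "alpha") <- alpha
  class(res) <- c("wean_enrich", class(res))
  res
}

#' @export
print.wean_enrich <- function(x, ...) {
  cat(
    "<wean_enrich> ", nrow(x), " sets, ", sum(x$significant),
    " significant (", attr(x, "correction"), " regime, alpha ",
    attr(x, "alpha"), ")\n",
    sep = ""
  )
  NextMethod()
}
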