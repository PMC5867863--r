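#' Candidate lncRNA-mRNA pairs within a flanking window
#'
#' A (lncRNA, gene) pair is a candidate iff the gene span intersects the
#' window `[lnc_start - window, lnc_end + window]` on the same chromosome,
#' either strand. The reported distance is the gap in bp between the two
#' spans (0 when they overlap), so `distance_bp < window` for every pair.
#'
#' @param lncrnas Annotation tibble of lncRNA transcripts (paired by
#'   `transcript_id`).
#' @param mrnas Annotation tibble of protein-coding genes (paired by
#'   `gene_id`; only `protein_coding` rows are used when biotypes are
#'   present).
#' @param window Flank size in bp (default 50,000).
#' @return A tibble (`lncrna_id`, `gene_id`, `distance_bp`).
#' @export
find_cis_pairs <- function(lncrnas, mrnas, window = 50000) {
  validate_annotation(lncrnas)
  validate_annotation(mrnas)
  if (any(mrnas$biotype == "protein_coding")) {
    mrnas <- filter(mrnas, .data$biotype == "protein_coding")
  }
  ltx <- transcript_table(lncrnas)
  gt <- gene_table(mrnas)
  if (nrow(ltx) == 0 || nrow(gt) == 0) {
    return(tibble(lncrna_id = character(), gene_id = character(), distance_bp = integer()))
  }
  lgr <- GenomicRanges::GRanges(
    ltx$chrom,
    IRanges::IRanges(pmax(1L, ltx$tx_start - window), ltx$tx_end + window)
  )
  ggr <- .gene_granges(gt)
  hits <- GenomicRanges::findOverlaps(lgr, ggr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(
    GenomicRanges::GRanges(ltx$chrom[qi], IRanges::IRanges(ltx$tx_start[qi], ltx$tx_end[qi])),
    ggr[si],
    ignore.strand = TRUE
  )
  tibble(
    lncrna_id = ltx$transcript_id[qi],
    gene_id = gt$gene_id[si],
    distance_bp = as.integer(dist)
  ) %>% arrange(.data$lncrna_id, .data$gene_id)
}

#' Pearson correlation with a two-sided t test
#'
#' Sample Pearson r with the two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom
#' (identical to `stats::cor.test`).
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return A one-row tibble (`r`, `p`, `n`).
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) abort("need equal-length vectors with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("constant_expression")
  r <- stats::cor(x, y)
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  tibble(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

.pair_cor <- function(xm, ym) {
  # row-wise Pearson r between paired rows of two matrices
  xc <- xm - rowMeans(xm)
  yc <- ym - rowMeans(ym)
  num <- rowSums(xc * yc)
  den <- sqrt(rowSums(xc^2) * rowSums(yc^2))
  num / den
}

#' Call cis target genes by windowed co-expression
#'
#' Computes the Pearson correlation between each candidate pair's
#' expression profiles across all samples of a tissue (both timepoints
#' pooled), applies Benjamini-Hochberg across all tested pairs, and calls
#' a gene a cis target of its lncRNA at `p_bh < alpha`. By default
#' expression is taken as `log2(normalized count + 1)`.
#'
#' @param pairs Candidate pairs from [find_cis_pairs()].
#' @param expr Normalized-count tibble (`feature_id` + sample columns)
#'   containing both lncRNA and gene features.
#' @param scale `"log2p1"` (default) or `"raw"`.
#' @param alpha FDR level (default 0.05).
#' @return A `wean_cis` tibble: the pairs with `r`, `p`, `p_bh`,
#'   `is_cis_target`, plus attributes `dropped` (pairs with missing or
#'   constant features, with reasons) and degree summaries
#'   `targets_per_lncrna` / `lncrnas_per_gene` over significant pairs.
#' @export
call_cis_targets <- function(pairs, expr, scale = c("log2p1", "raw"), alpha = 0.05) {
  scale <- match.arg(scale)
  if (!"feature_id" %in% names(expr)) abort("expression table needs a feature_id column")
  m <- as.matrix(expr[setdiff(names(expr), "feature_id")])
  rownames(m) <- expr$feature_id
  if (scale == "log2p1") {
    if (any(m < 0)) abort("log2p1 scaling needs non-negative expression values")
    m <- log2(m + 1)
  }
  present <- pairs$lncrna_id %in% rownames(m) & pairs$gene_id %in% rownames(m)
  dropped <- pairs[!present, , drop = FALSE]
  dropped$reason <- "not_expressed"
  p2 <- pairs[present, , drop = FALSE]
  if (nrow(p2) > 0) {
    xm <- m[p2$lncrna_id, , drop = FALSE]
    ym <- m[p2$gene_id, , drop = FALSE]
    const <- apply(xm, 1, stats::sd) == 0 | apply(ym, 1, stats::sd) == 0
    if (any(const)) {
      dc <- p2[const, , drop = FALSE]
      dc$reason <- "constant_expression"
      dropped <- bind_rows(dropped, dc)
      p2 <- p2[!const, , drop = FALSE]
      xm <- xm[!const, , drop = FALSE]
      ym <- ym[!const, , drop = FALSE]
    }
  }
  n <- ncol(m)
  if (nrow(p2) == 0) {
    out <- p2 %>% mutate(r = numeric(0), p = numeric(0), p_bh = numeric(0), is_cis_target = logical(0))
  } else {
    r <- .pair_cor(xm, ym)
    tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    out <- p2 %>% mutate(r = r, p = p, p_bh = bh_adjust(p), is_cis_target = .data$p_bh < alpha)
  }
  sig <- filter(out, .data$is_cis_target)
  attr(out, "dropped") <- dropped
  attr(out, "targets_per_lncrna") <- count(sig, .data$lncrna_id, name = "n_targets")
  attr(out, "lncrnas_per_gene") <- count(sig, .data$gene_id, name = "n_lncrnas")
  attr(out, "alpha") <- alpha
  attr(out, "n_samples") <- n
  class(out) <- c("wean_cis", class(out))
  out
}

#' @export
print.wean_cis <- function(x, ...) {
  cat(
    "<wean_cis> ", nrow(x), " tested pairs, ", sum(x$is_cis_target),
    " cis targets (p.BH < ", attr(x, "alpha"), ") over ",
    attr(x, "n_samples"), " samples\n",
    sep = ""
  )
  NextMethod()
}

#' Export significant cis pairs as a network edge list
#'
#' Writes a (source, interaction, target) TSV importable by network
#' visualization tools.
#'
#' @param cis A `wean_cis` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(cis, path) {
  sig <- filter(cis, .data$is_cis_target)
  readr::write_tsv(
    tibble(source = sig$lncrna_id, interaction = "cis", target = sig$gene_id),
    path
  )
  invisible(path)
}
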