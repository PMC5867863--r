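test_that("window boundary is inclusive and chromosomes separate pairs", {
  lnc <- mk_tx("L1", "chr1", "+", ex(10000, 11000))
  genes <- dplyr::bind_rows(
    mk_tx("Ga_t", "chr1", "+", ex(61000, 62000), gene = "Ga", biotype = "protein_coding"),
    mk_tx("Gb_t", "chr1", "+", ex(61001, 62000), gene = "Gb", biotype = "protein_coding"),
    mk_tx("Gc_t", "chr2", "+", ex(10500, 11500), gene = "Gc", biotype = "protein_coding")
  )
  # Ga starts exactly 50,000 bp after the lncRNA end -> included
  pairs <- find_cis_pairs(lnc, genes, window = 50000)
  expect_setequal(pairs$gene_id, "Ga")
  expect_equal(pairs$distance_bp, 49999L)
  # overlapping spans have distance 0
  ov <- find_cis_pairs(lnc, mk_tx("Gd_t", "chr1", "-", ex(10500, 12000),
    gene = "Gd", biotype = "protein_coding"
  ))
  expect_equal(ov$distance_bp, 0L)
})

test_that("candidate pairs equal the all-pairs brute-force oracle", {
  set.seed(801)
  for (rep in 1:20) {
    n_l <- sample(3:8, 1)
    n_g <- sample(3:10, 1)
    lnc_spans <- data.frame(
      id = sprintf("L%02d", 1:n_l),
      chrom = sample(c("c1", "c2"), n_l, TRUE),
      start = sample(1:200000, n_l)
    )
    lnc_spans$end <- lnc_spans$start + sample(200:5000, n_l, TRUE)
    gene_spans <- data.frame(
      id = sprintf("G%02d", 1:n_g),
      chrom = sample(c("c1", "c2"), n_g, TRUE),
      start = sample(1:200000, n_g)
    )
    gene_spans$end <- gene_spans$start + sample(500:20000, n_g, TRUE)
    w <- sample(c(10000L, 50000L), 1)
    lnc_ann <- purrr::map_dfr(seq_len(n_l), function(i) {
      mk_tx(
        lnc_spans$id[i], lnc_spans$chrom[i], "+",
        ex(lnc_spans$start[i], lnc_spans$end[i])
      )
    })
    gene_ann <- purrr::map_dfr(seq_len(n_g), function(i) {
      mk_tx(paste0(gene_spans$id[i], "_t"), gene_spans$chrom[i], "+",
        ex(gene_spans$start[i], gene_spans$end[i]),
        gene = gene_spans$id[i], biotype = "protein_coding"
      )
    })
    got <- find_cis_pairs(lnc_ann, gene_ann, window = w)
    want <- oracle_cis_pairs(lnc_spans, gene_spans, w)
    want <- want[order(want$lncrna_id, want$gene_id), ]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$lncrna_id, want$lncrna_id)
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$distance_bp, want$distance_bp)
    expect_true(all(got$distance_bp < w))
    # widening the window never removes pairs
    wider <- find_cis_pairs(lnc_ann, gene_ann, window = w + 20000L)
    expect_true(all(paste(got$lncrna_id, got$gene_id) %in%
      paste(wider$lncrna_id, wider$gene_id)))
  }
})

test_that("Pearson test matches hand arithmetic and cor.test", {
  pt1 <- pearson_test(1:10, 1:10)
  expect_equal(pt1$r, 1)
  pt2 <- pearson_test(c(1, 2, 3), c(1, 2, 4))
  expect_equal(round(pt2$r, 4), 0.9820)
  set.seed(802)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1))
    y <- rnorm(length(x)) + 0.3 * x
    ours <- pearson_test(x, y)
    ref <- stats::cor.test(x, y)
    expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    # symmetry and positive-affine invariance
    expect_equal(pearson_test(y, x)$r, ours$r)
    expect_equal(pearson_test(2.5 * x + 7, y)$r, ours$r, tolerance = 1e-12)
  }
  expect_error(pearson_test(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_test(1:2, 1:2), "n >= 3")
})

test_that("null Pearson correlations reject at the nominal rate", {
  set.seed(803)
  B <- 10000
  x <- matrix(rnorm(32 * B), ncol = 32)
  y <- matrix(rnorm(32 * B), ncol = 32)
  ids <- c(sprintf("x%05d", 1:B), sprintf("y%05d", 1:B))
  expr <- dplyr::bind_cols(
    tibble::tibble(feature_id = ids),
    tibble::as_tibble(as.data.frame(rbind(x, y)),
      .name_repair = ~ sprintf("s%02d", 1:32)
    )
  )
  pairs <- tibble::tibble(
    lncrna_id = sprintf("x%05d", 1:B), gene_id = sprintf("y%05d", 1:B),
    distance_bp = 0L
  )
  cis <- call_cis_targets(pairs, expr, scale = "raw")
  rate <- mean(cis$p < 0.05)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("cis-target calls: m = 1 case, BH sharing, degree conservation", {
  set.seed(804)
  expr <- dplyr::bind_cols(
    tibble::tibble(feature_id = c("L1", "G1")),
    tibble::as_tibble(
      as.data.frame(rbind(rnorm(20), rnorm(20))),
      .name_repair = ~ sprintf("s%02d", 1:20)
    )
  )
  one <- call_cis_targets(
    tibble::tibble(lncrna_id = "L1", gene_id = "G1", distance_bp = 5L),
    expr,
    scale = "raw"
  )
  expect_equal(one$p_bh, one$p) # m = 1: unchanged
  expect_identical(one$is_cis_target, one$p_bh < 0.05)
  # shared BH implementation across the pooled p vector
  sim <- simulate_counts(sprintf("f%03d", 1:40),
    group_sizes = c(8, 8), mu = 200,
    dispersion = 0.05, seed = 805
  )
  norm <- normalize_counts(sim$counts)
  pairs <- tibble::tibble(
    lncrna_id = sprintf("f%03d", 1:20),
    gene_id = sprintf("f%03d", 21:40), distance_bp = 0L
  )
  cis <- call_cis_targets(pairs, norm)
  expect_equal(cis$p_bh, bh_adjust(cis$p))
  # degree summaries conserve edges
  tpl <- attr(cis, "targets_per_lncrna")
  lpg <- attr(cis, "lncrnas_per_gene")
  expect_equal(sum(tpl$n_targets), sum(cis$is_cis_target))
  expect_equal(sum(lpg$n_lncrnas), sum(cis$is_cis_target))
  # pairs touching unknown features are dropped with a reason
  pairs2 <- dplyr::bind_rows(
    pairs,
    tibble::tibble(lncrna_id = "nope", gene_id = "f021", distance_bp = 0L)
  )
  cis2 <- call_cis_targets(pairs2, norm)
  expect_equal(nrow(cis2), nrow(pairs))
  expect_equal(attr(cis2, "dropped")$reason, "not_expressed")
})

test_that("planted correlated pairs are recalled with controlled FDR", {
  n_planted <- 200
  n_null <- 2000
  lnc <- sprintf("L%04d", seq_len(n_planted + n_null))
  mr <- sprintf("M%04d", seq_len(n_planted + n_null))
  planted <- tibble::tibble(id_a = lnc[1:n_planted], id_b = mr[1:n_planted])
  cm <- simulate_counts(c(lnc, mr),
    group_sizes = c(16, 16), dispersion = 0.1,
    cis_pairs = planted, rho = 0.8, seed = 806
  )
  pairs <- tibble::tibble(lncrna_id = lnc, gene_id = mr, distance_bp = 1000L)
  cis <- call_cis_targets(pairs, normalize_counts(cm$counts))
  isp <- cis$lncrna_id %in% planted$id_a
  # the generator's loading correction hits the target correlation
  expect_lt(abs(mean(cis$r[isp]) - 0.8), 0.05)
  recall <- mean(cis$is_cis_target[isp])
  fdr <- sum(cis$is_cis_target & !isp) / max(1, sum(cis$is_cis_target))
  expect_gte(recall, 0.9)
  expect_lte(fdr, 0.1)
  g <- glance(cis)
  expect_equal(g$n_pairs_tested, nrow(pairs))
})
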