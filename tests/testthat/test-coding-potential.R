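test_that("ORF finder handles boundary cases", {
  expect_equal(find_longest_orf("ATGTAA")$peptide_len, 1L)
  expect_equal(find_longest_orf("CCCCCCCC")$peptide_len, 0L)
  expect_equal(find_longest_orf("")$peptide_len, 0L)
  # open-ended ORF: codons counted to the sequence end
  expect_equal(find_longest_orf("ATGAAAAAA")$peptide_len, 3L)
  expect_false(find_longest_orf("ATGAAAAAA")$has_stop)
  # tie broken by smaller start offset
  orf <- find_longest_orf("ATGTAAGATGTAAG")
  expect_equal(orf$start_offset, 0L)
  # unstranded: reverse complement of ATG AAA TAA embedded
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("ATGAAAAAATAA")))
  expect_equal(find_longest_orf(rc, strand = ".")$peptide_len, 3L)
  expect_equal(find_longest_orf(rc, strand = "+")$peptide_len, 0L)
})

test_that("ORF finder equals the brute-force all-starts oracle", {
  set.seed(501)
  for (i in 1:200) {
    len <- sample(60:1000, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    got <- find_longest_orf(seq)
    want <- oracle_orf(seq)
    expect_equal(got$peptide_len, want$peptide_len)
    if (want$peptide_len > 0) expect_equal(got$start_offset, want$start_offset)
  }
})

test_that("Fickett TESTCODE matches a hand-evaluated fixture and is bounded", {
  # poly-A 300-mer, worked through the lookup tables by hand:
  # position values 100/101 (A) and 0 (C,G,T) -> last bin; content 1 (A,
  # first bin) and 0 (C,G,T, last bin):
  # 0.22*0.26 + 0.23*0.18 + 0.08*0.31 + 0.09*0.33
  # + 0.28*0.11 + 0.31*0.12 + 0.29*0.15 + 0.58*0.14 = 0.3458
  expect_equal(fickett_score(strrep("A", 300)), 0.3458, tolerance = 1e-12)
  seq <- paste(rep(c("A", "C", "G", "T"), 75), collapse = "")
  expect_identical(fickett_score(seq), fickett_score(seq))
  expect_error(fickett_score("ACGTA"), "length")
  # range bound from the table extrema
  lo <- sum(c(0.08, 0.23, 0.08, 0.09) * c(0.26, 0.18, 0.31, 0.33)) +
    sum(c(0.21, 0.31, 0.29, 0.24) * c(0.11, 0.12, 0.15, 0.14))
  hi <- sum(c(0.94, 0.81, 0.90, 0.97) * c(0.26, 0.18, 0.31, 0.33)) +
    sum(c(0.81, 0.82, 0.73, 0.75) * c(0.11, 0.12, 0.15, 0.14))
  set.seed(502)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    v <- fickett_score(s)
    expect_gte(v, lo)
    expect_lte(v, hi)
  }
})

test_that("hexamer LLR: identity tables give zero, toy tables match hand arithmetic", {
  sim_tab <- hexamer_table(c("ACGTACGTAAACCC"))
  expect_equal(hexamer_llr("ACGTACGTACGT", sim_tab, sim_tab), 0)
  # 9-nt sequence has two in-frame hexamers (offsets 0 and 3)
  h1 <- "AAACCCG"
  seq9 <- "AAACCCGGG"
  tab_c <- toy_hexamer_table(c(AAACCC = 0.6, CCCGGG = 0.4))
  tab_n <- toy_hexamer_table(c(AAACCC = 0.2, CCCGGG = 0.8))
  expect_equal(
    hexamer_llr(seq9, tab_c, tab_n),
    mean(c(log(0.6 / 0.2), log(0.4 / 0.8)))
  )
  expect_equal(hexamer_llr("ACGTA", tab_c, tab_n), 0) # < 6 nt
  bad <- tab_c
  bad[1] <- bad[1] + 0.01
  expect_error(hexamer_llr(seq9, bad, tab_n), "sum to 1")
})

test_that("sequences from the coding model outscore background sequences", {
  corpus <- simulate_coding_corpus(100, seed = 77)
  ct <- hexamer_table(corpus$seq[corpus$label == 1])
  nt <- hexamer_table(corpus$seq[corpus$label == 0])
  llr_c <- vapply(corpus$seq[corpus$label == 1][1:50], hexamer_llr, numeric(1), ct, nt)
  llr_n <- vapply(corpus$seq[corpus$label == 0][1:50], hexamer_llr, numeric(1), ct, nt)
  expect_gt(mean(llr_c), mean(llr_n))
})

test_that("zero-coefficient combiner scores 0.5; separable data fits perfectly", {
  tab <- hexamer_table("ACGTACGTA")
  zero_model <- structure(
    list(
      coefficients = c(
        `(Intercept)` = 0, peptide_len = 0, orf_coverage = 0,
        fickett = 0, hexamer = 0
      ),
      coding_table = tab, noncoding_table = tab
    ),
    class = "coding_model"
  )
  sc <- score_coding_potential(
    tibble::tibble(transcript_id = "t", seq = "ATGAAACCCGGGTTTTAA"), zero_model
  )
  expect_equal(sc$combined_prob, 0.5)
  # linearly separable toy set -> 100% training accuracy (capped coefficients)
  feats <- tibble::tibble(
    peptide_len = c(rep(200, 20), rep(10, 20)),
    orf_coverage = c(rep(0.9, 20), rep(0.1, 20)),
    fickett = 0.5, hexamer = 0,
    label = rep(c(1L, 0L), each = 20)
  )
  expect_warning(m <- train_coding_model(feats, tab, tab), "separated")
  pred <- stats::plogis(
    m$coefficients[1] + m$coefficients["peptide_len"] * feats$peptide_len +
      m$coefficients["orf_coverage"] * feats$orf_coverage +
      m$coefficients["fickett"] * feats$fickett +
      m$coefficients["hexamer"] * feats$hexamer
  )
  expect_equal(as.integer(pred > 0.5), feats$label)
  expect_error(train_coding_model(dplyr::mutate(feats, label = 1L), tab, tab), "class")
})

test_that("logistic fit recovers planted coefficients within 2 SE", {
  set.seed(503)
  n <- 2000
  feats <- tibble::tibble(
    peptide_len = rnorm(n), orf_coverage = rnorm(n),
    fickett = rnorm(n), hexamer = rnorm(n)
  )
  beta <- c(-0.3, 0.8, -0.5, 0.6, 1.0)
  eta <- beta[1] + beta[2] * feats$peptide_len + beta[3] * feats$orf_coverage +
    beta[4] * feats$fickett + beta[5] * feats$hexamer
  feats$label <- rbinom(n, 1, stats::plogis(eta))
  tab <- hexamer_table("ACGTACGTA")
  m <- train_coding_model(feats, tab, tab)
  td <- tidy(m)
  expect_true(all(abs(td$estimate - beta) <= 2 * td$std_error))
})

test_that("held-out accuracy of the combiner reaches 0.9 on the synthetic corpus", {
  train <- simulate_coding_corpus(500, seed = 11)
  test <- simulate_coding_corpus(150, seed = 12)
  ct <- hexamer_table(train$seq[train$label == 1])
  nt <- hexamer_table(train$seq[train$label == 0])
  f <- coding_features(train, ct, nt)
  f$label <- train$label
  m <- suppressWarnings(train_coding_model(f, ct, nt))
  sc <- score_coding_potential(test, m)
  acc <- mean((sc$combined_prob > 0.5) == (test$label == 1))
  expect_gte(acc, 0.9)
})

test_that("coding gate: boundaries, conjunction oracle and monotonicity", {
  base <- tibble::tibble(
    transcript_id = "t", peptide_len = 10L, cnci_score = -1,
    cpat_score = 0.1, min_evalue = 1, combined_prob = NA_real_
  )
  # peptide length 100 with everything else noncoding -> discard
  expect_false(coding_gate(dplyr::mutate(base, peptide_len = 100L))$retain)
  expect_true(coding_gate(dplyr::mutate(base, peptide_len = 99L))$retain)
  # single-criterion boundary with all external evidence absent
  only_comb <- tibble::tibble(
    transcript_id = "t", peptide_len = 10L, combined_prob = 0.49
  )
  expect_true(coding_gate(only_comb)$retain)
  expect_false(coding_gate(dplyr::mutate(only_comb, combined_prob = 0.5))$retain)
  # external CPAT governs over the built-in probability when present
  both <- dplyr::mutate(base, cpat_score = 0.6, combined_prob = 0.1)
  expect_false(coding_gate(both)$retain)

  set.seed(504)
  n <- 1000
  rnd <- tibble::tibble(
    transcript_id = sprintf("t%04d", 1:n),
    peptide_len = sample(0:200, n, TRUE),
    cnci_score = ifelse(runif(n) < 0.3, NA, rnorm(n)),
    cpat_score = ifelse(runif(n) < 0.3, NA, runif(n)),
    combined_prob = runif(n),
    min_evalue = ifelse(runif(n) < 0.5, NA, 10^runif(n, -10, 1))
  )
  got <- coding_gate(rnd)$retain
  th <- default_gate_thresholds()
  want <- purrr::map_lgl(seq_len(n), function(i) {
    ok <- rnd$peptide_len[i] < th$peptide
    if (!is.na(rnd$cnci_score[i])) ok <- ok && rnd$cnci_score[i] < th$cnci
    prob <- if (!is.na(rnd$cpat_score[i])) rnd$cpat_score[i] else rnd$combined_prob[i]
    if (!is.na(prob)) ok <- ok && prob < th$cpat
    if (!is.na(rnd$min_evalue[i])) ok <- ok && rnd$min_evalue[i] >= th$evalue
    ok
  })
  expect_identical(got, want)
  # monotonicity: increasing coding evidence never flips discard -> retain
  harder <- dplyr::mutate(rnd,
    peptide_len = peptide_len + 50L,
    cnci_score = cnci_score + 1,
    combined_prob = pmin(1, combined_prob + 0.2),
    min_evalue = min_evalue / 100
  )
  got2 <- coding_gate(harder)$retain
  expect_false(any(got2 & !got))
})

test_that("BLAST tabular ingestion keeps the minimum e-value per query", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_equal(nrow(read_blast_tab(f)), 0L)
  rows <- c(
    paste(c("t1", "s1", 99, 100, 1, 0, 1, 100, 1, 100, "1e-3", 180), collapse = "\t"),
    paste(c("t1", "s2", 98, 100, 1, 0, 1, 100, 1, 100, "1e-7", 200), collapse = "\t"),
    paste(c("t2", "s1", 97, 100, 1, 0, 1, 100, 1, 100, "0.2", 60), collapse = "\t")
  )
  writeLines(rows, f)
  bt <- read_blast_tab(f)
  expect_equal(bt$min_evalue[bt$transcript_id == "t1"], 1e-7)
  expect_equal(bt$min_evalue[bt$transcript_id == "t2"], 0.2)
  writeLines(sub("1e-7", "not_a_number", rows), f)
  expect_error(read_blast_tab(f), "line")
})
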