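# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

mk_tx <- function(id, chrom, strand, exons, gene = id, biotype = "unknown") {
  tibble::tibble(
    chrom = chrom, start = as.integer(exons[, 1]), end = as.integer(exons[, 2]),
    strand = strand, gene_id = gene, transcript_id = id, biotype = biotype
  )
}

ex <- function(...) {
  v <- c(...)
  matrix(as.integer(v), ncol = 2, byrow = TRUE)
}

# random multi-exon transcript on a short coordinate range
random_tx_exons <- function(max_exons = 4, region = c(1L, 5000L)) {
  n <- sample(seq_len(max_exons), 1)
  len <- sample(50:400, n, replace = TRUE)
  gap <- sample(30:400, n, replace = TRUE)
  start <- sample(region[1]:region[2], 1)
  s <- integer(n)
  e <- integer(n)
  pos <- start
  for (k in seq_len(n)) {
    s[k] <- pos
    e[k] <- pos + len[k] - 1L
    pos <- e[k] + 1L + gap[k]
  }
  cbind(s, e)
}

random_annotation <- function(n_tx = 5, chroms = c("c1", "c2"), biotype = "unknown") {
  purrr::map_dfr(seq_len(n_tx), function(i) {
    mk_tx(
      sprintf("t%03d", i), sample(chroms, 1), sample(c("+", "-"), 1),
      random_tx_exons(),
      gene = sprintf("g%03d", i), biotype = biotype
    )
  })
}

# small simulation artifacts, built once per test run
shared_small_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- simulate_annotation(sim_config("small", seed = 42))
    }
    val
  }
})

shared_coding_model <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      corpus <- simulate_coding_corpus(300, seed = 7)
      ct <- hexamer_table(corpus$seq[corpus$label == 1])
      nt <- hexamer_table(corpus$seq[corpus$label == 0])
      f <- coding_features(corpus, ct, nt)
      f$label <- corpus$label
      val <<- suppressWarnings(train_coding_model(f, ct, nt))
    }
    val
  }
})

# hexamer tables with all mass on listed hexamers
toy_hexamer_table <- function(probs) {
  hx <- all_hexamers()
  tab <- stats::setNames(rep(0, length(hx)), hx)
  tab[names(probs)] <- probs
  tab
}
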