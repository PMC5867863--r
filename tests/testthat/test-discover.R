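simple_inputs <- function() {
  reference <- mk_tx("ref_t", "chr1", "+", ex(100000, 100500, 101000, 101500),
    gene = "ref_g", biotype = "protein_coding"
  )
  known <- mk_tx("known_t", "chr1", "+", ex(500000, 500300, 501000, 501400),
    gene = "known_g", biotype = "known_lncRNA"
  )
  list(reference = reference, known = known)
}

test_that("length filter is strict: 201 bp passes, 200 bp fails", {
  inp <- simple_inputs()
  asm <- dplyr::bind_rows(
    mk_tx("pass201", "chr1", "+", ex(1000, 1200)), # 201 bp, intergenic
    mk_tx("fail200", "chr1", "+", ex(5000, 5199)) # exactly 200 bp
  )
  seqs <- tibble::tibble(
    transcript_id = c("pass201", "fail200"),
    seq = c(strrep("ACGT", 51)[1], paste(rep("ACGT", 50), collapse = ""))
  )
  seqs$seq[1] <- substr(strrep("ACGT", 60), 1, 201)
  disc <- discover_lncrnas(asm, inp$reference, inp$known, seqs,
    coding_model = shared_coding_model()
  )
  p <- disc[disc$transcript_id == "pass201", ]
  f <- disc[disc$transcript_id == "fail200", ]
  expect_equal(p$filter_length, "pass")
  expect_true(p$retained)
  expect_false(p$known) # intergenic vs known lncRNAs too -> novel
  expect_equal(f$filter_length, "fail")
  expect_equal(f$filter_class, "not_evaluated")
  expect_equal(f$filter_coding, "not_evaluated")
  expect_false(f$retained)
})

test_that("candidates without a sequence fail the gate with reason no_sequence", {
  inp <- simple_inputs()
  asm <- mk_tx("noseq", "chr1", "+", ex(1000, 1400))
  disc <- discover_lncrnas(asm, inp$reference, inp$known,
    seqs = tibble::tibble(transcript_id = character(), seq = character()),
    coding_model = shared_coding_model()
  )
  expect_false(disc$retained)
  expect_equal(disc$gate_reason, "no_sequence")
})

test_that("the cascade reproduces the generator manifest exactly", {
  sim <- shared_small_sim()
  disc <- discover_lncrnas(sim$assembled, sim$reference, sim$known_lnc, sim$seqs,
    coding_model = shared_coding_model(), blast = sim$blast
  )
  man <- sim$manifest
  m <- match(man$transcript_id, disc$transcript_id)
  expect_equal(disc$filter_length[m] == "pass", man$expect_length_pass)
  evaluated <- man$expect_length_pass
  expect_equal(
    (disc$filter_class[m] == "pass")[evaluated],
    man$expect_class_pass[evaluated]
  )
  expect_equal(disc$retained[m], man$expect_retained)
  # known/novel split among survivors follows the planted labels and is a
  # partition
  surv <- man$expect_retained
  expect_equal(disc$known[m][surv], man$planted_known[surv])
  expect_true(all(disc$known[m][surv] %in% c(TRUE, FALSE)))
  # cascade order-faithfulness: later filters of failed transcripts are
  # not evaluated
  failed_len <- disc$filter_length == "fail"
  expect_true(all(disc$filter_class[failed_len] == "not_evaluated"))
  failed_class <- disc$filter_class == "fail"
  expect_true(all(disc$filter_coding[failed_class] == "not_evaluated"))
})

test_that("survivor count is monotone in the thresholds", {
  sim <- shared_small_sim()
  base_args <- list(
    assembled = sim$assembled, reference = sim$reference,
    known_lnc = sim$known_lnc, seqs = sim$seqs,
    coding_model = shared_coding_model(), blast = sim$blast
  )
  n_def <- sum(do.call(discover_lncrnas, base_args)$retained)
  n_len <- sum(do.call(discover_lncrnas, c(base_args, list(min_length = 500)))$retained)
  expect_lte(n_len, n_def)
  th <- default_gate_thresholds()
  th$peptide <- 30
  n_pep <- sum(do.call(discover_lncrnas, c(base_args, list(thresholds = th)))$retained)
  expect_lte(n_pep, n_def)
  th2 <- default_gate_thresholds()
  th2$evalue <- 1 # any hit discards
  n_ev <- sum(do.call(discover_lncrnas, c(base_args, list(thresholds = th2)))$retained)
  expect_lte(n_ev, n_def)
})

test_that("positional classification follows its stated rules", {
  genes <- mk_tx("g_t", "chr1", "+", ex(10000, 10500, 12000, 12500),
    gene = "g", biotype = "protein_coding"
  )
  # nearest gene 1,001 bp away, no overlap -> distal intergenic
  far <- mk_tx("lnc", "chr1", "+", ex(13502, 13900))
  pc <- classify_position(far, genes)
  expect_equal(pc$nearest_gene_distance, 1001L)
  expect_equal(pc$positional_class, "intergenic_same")
  # inside an intron, same strand -> sense_intronic
  intr <- mk_tx("lnc", "chr1", "+", ex(10600, 11000))
  expect_equal(classify_position(intr, genes)$positional_class, "sense_intronic")
  # inside an intron, opposite strand
  intr2 <- mk_tx("lnc", "chr1", "-", ex(10600, 11000))
  expect_equal(classify_position(intr2, genes)$positional_class, "antisense_intronic")
  # exonic overlap, opposite strand
  anti <- mk_tx("lnc", "chr1", "-", ex(10400, 10700))
  expect_equal(classify_position(anti, genes)$positional_class, "antisense_exonic")
  # head-to-head within 1 kb -> bidirectional promoter
  bidir <- mk_tx("lnc", "chr1", "-", ex(9000, 9500))
  expect_equal(classify_position(bidir, genes)$positional_class, "bidirectional_promoter")
  # same strand just upstream
  up <- mk_tx("lnc", "chr1", "+", ex(9000, 9500))
  expect_equal(classify_position(up, genes)$positional_class, "upstream_proximal")
  # gene contained in the lncRNA span (inside a lncRNA intron, no exon
  # overlap) -> containing_gene
  cont <- mk_tx("lnc", "chr1", "+", ex(9000, 9400, 12800, 13000))
  expect_equal(classify_position(cont, genes)$positional_class, "containing_gene")
})

test_that("positional classes match the rule oracle on random placements", {
  set.seed(1101)
  genes_ann <- dplyr::bind_rows(
    mk_tx("gA_t", "c1", "+", ex(20000, 21000, 25000, 26000), gene = "gA", biotype = "protein_coding"),
    mk_tx("gB_t", "c1", "-", ex(60000, 64000), gene = "gB", biotype = "protein_coding"),
    mk_tx("gC_t", "c1", "+", ex(90000, 90400, 92000, 92600), gene = "gC", biotype = "protein_coding")
  )
  gt <- gene_table(genes_ann)
  genes_df <- data.frame(
    id = gt$gene_id, start = gt$gene_start, end = gt$gene_end,
    strand = gt$strand
  )
  gene_exons <- lapply(
    split(seq_len(nrow(genes_ann)), genes_ann$gene_id),
    function(ix) cbind(genes_ann$start[ix], genes_ann$end[ix])
  )
  for (i in 1:300) {
    s <- sample(1:110000, 1)
    if (i %% 3 == 0) {
      # two exons with a wide intron: containment classes become reachable
      w1 <- sample(100:600, 1)
      gap <- sample(1000:9000, 1)
      w2 <- sample(100:600, 1)
      exm <- ex(s, s + w1, s + w1 + gap, s + w1 + gap + w2)
    } else {
      exm <- ex(s, s + sample(100:6000, 1))
    }
    strand <- sample(c("+", "-"), 1)
    lnc <- mk_tx("L", "c1", strand, exm)
    got <- classify_position(lnc, genes_ann)$positional_class
    want <- oracle_positional(list(ex = exm, strand = strand), genes_df, gene_exons)
    expect_identical(got, want)
  }
})

test_that("characterization bins partition the retained set", {
  sim <- shared_small_sim()
  disc <- discover_lncrnas(sim$assembled, sim$reference, sim$known_lnc, sim$seqs,
    coding_model = shared_coding_model(), blast = sim$blast
  )
  ch <- characterize_lncrnas(disc)
  expect_equal(sum(ch$length_bins$n), ch$n_transcripts)
  expect_equal(sum(ch$transcripts_per_gene$n_genes * ch$transcripts_per_gene$n_transcripts), ch$n_transcripts)
  expect_equal(sum(ch$exons_per_transcript$n), ch$n_transcripts)
  expect_equal(sum(ch$per_chromosome$n), ch$n_transcripts)
  # a single 500 bp transcript lands in the 200-999 bin
  one <- tibble::tibble(
    tx_length = 500L, gene_id = "g", n_exons = 1L, chrom = "c1"
  )
  b <- characterize_lncrnas(one)$length_bins
  expect_equal(b$n[b$bin == "200-999"], 1L)
  expect_equal(characterize_lncrnas(disc[0, ])$n_transcripts, 0L)
})

test_that("generated lncRNA lengths follow the configured bin fractions", {
  cfg <- sim_config("small", seed = 5, n_lnc_intergenic = 2000)
  sim <- simulate_annotation(cfg)
  lnc_ids <- sim$manifest$transcript_id[
    is.na(sim$manifest$cis_gene) & sim$manifest$planted_code == "u" &
      sim$manifest$expect_length_pass & sim$manifest$coding_label == "noncoding" &
      !sim$manifest$planted_known
  ]
  tx <- transcript_table(sim$assembled)
  lens <- tx$tx_length[match(lnc_ids, tx$transcript_id)]
  frac <- as.numeric(table(cut(lens, c(-Inf, 999, 2499, 4999, 9999, Inf))) / length(lens))
  expect_lt(abs(frac[1] - 0.447), 0.03)
  expect_lt(abs(frac[2] - 0.2925), 0.03)
})
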