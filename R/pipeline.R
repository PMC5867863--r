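#' Run the full synthetic-to-results pipeline
#'
#' Orchestrates simulate -> discover -> normalize/filter -> differential
#' expression -> cis targets -> enrichment with one configuration. All
#' inputs are written under `out_dir/inputs` and re-read through the
#' package's own readers (so the run exercises the file formats), all
#' stage outputs go to `out_dir/results`, and a machine-readable JSON run
#' report with per-stage record counts and the effective configuration is
#' written to `out_dir/report.json`. Outputs carry no timestamps: the same
#' config and seed give byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param fdr FDR level for DE and cis calls (default 0.05).
#' @return The run report, invisibly (a nested list).
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir, fdr = 0.05) {
  ind <- file.path(out_dir, "inputs")
  res <- file.path(out_dir, "results")
  dir.create(ind, recursive = TRUE, showWarnings = FALSE)
  dir.create(res, recursive = TRUE, showWarnings = FALSE)

  # --- stage 1: simulate and write inputs
  sim <- simulate_annotation(cfg)
  write_gtf(sim$reference, file.path(ind, "reference.gtf"))
  write_gtf(sim$known_lnc, file.path(ind, "known_lnc.gtf"))
  write_gtf(sim$assembled, file.path(ind, "assembled.gtf"))
  write_fasta(sim$seqs, file.path(ind, "assembled.fa"))
  readr::write_tsv(sim$manifest, file.path(ind, "manifest.tsv"))
  blast_out <- tibble(
    qseqid = sim$blast$transcript_id, sseqid = "SP_HIT", pident = 98.0,
    length = 100L, mismatch = 2L, gapopen = 0L, qstart = 1L, qend = 300L,
    sstart = 1L, send = 100L, evalue = sim$blast$min_evalue, bitscore = 200.0
  )
  readr::write_tsv(blast_out, file.path(ind, "blast.tsv"), col_names = FALSE)

  # --- stage 2: read inputs back and discover lncRNAs
  reference <- read_gtf(file.path(ind, "reference.gtf"))
  known_lnc <- read_gtf(file.path(ind, "known_lnc.gtf"))
  assembled <- read_gtf(file.path(ind, "assembled.gtf"))
  seqs <- read_fasta(file.path(ind, "assembled.fa"))
  blast <- read_blast_tab(file.path(ind, "blast.tsv"))
  corpus <- simulate_coding_corpus(cfg$corpus_per_class,
    seed = cfg$seed + 202L,
    max_pep = cfg$max_noncoding_peptide
  )
  cod_tab <- hexamer_table(corpus$seq[corpus$label == 1])
  non_tab <- hexamer_table(corpus$seq[corpus$label == 0])
  feats <- coding_features(corpus, cod_tab, non_tab)
  feats$label <- corpus$label
  model <- train_coding_model(feats, cod_tab, non_tab)
  disc <- discover_lncrnas(assembled, reference, known_lnc, seqs,
    coding_model = model, blast = blast
  )
  readr::write_tsv(disc, file.path(res, "lncrna_candidates.tsv"))
  retained_ids <- disc$transcript_id[disc$retained]
  lnc_ann <- filter(assembled, .data$transcript_id %in% retained_ids)
  if (nrow(lnc_ann) > 0) write_gtf(lnc_ann, file.path(res, "lncrna.gtf"))
  chars <- characterize_lncrnas(disc)

  # --- stage 3: per-tissue counts, DE, cis, enrichment
  mrna_genes <- unique(gene_table(filter(
    reference, .data$biotype == "protein_coding"
  ))$gene_id)
  feature_ids <- c(mrna_genes, retained_ids)
  cis_man <- filter(sim$manifest, !is.na(.data$cis_gene), .data$transcript_id %in% retained_ids)
  tissue_reports <- list()
  for (tis in names(cfg$tissues)) {
    gsz <- cfg$tissues[[tis]]
    tseed <- cfg$seed + 303L + match(tis, names(cfg$tissues))
    de_pool <- mrna_genes
    n_de <- round(cfg$de_fraction * length(feature_ids))
    de_ids <- .with_seed(tseed, sample(de_pool, min(n_de, length(de_pool))))
    cis_pairs_truth <- tibble(
      id_a = cis_man$transcript_id, id_b = cis_man$cis_gene,
      rho = cfg$cis_rho
    ) %>% filter(!.data$id_a %in% de_ids, !.data$id_b %in% de_ids)
    cm <- simulate_counts(feature_ids,
      group_sizes = unname(gsz),
      dispersion = cfg$dispersion, de_ids = de_ids,
      de_log2fc = cfg$de_log2fc, cis_pairs = cis_pairs_truth,
      lib_range = cfg$lib_range, mu_meanlog = cfg$mu_meanlog,
      mu_sdlog = cfg$mu_sdlog, sample_prefix = tis, seed = tseed + 7L
    )
    counts_path <- file.path(ind, paste0("counts_", tis, ".tsv"))
    sheet_path <- file.path(ind, paste0("samples_", tis, ".tsv"))
    readr::write_tsv(cm$counts, counts_path)
    readr::write_tsv(
      cm$sample_sheet %>% mutate(tissue = tis) %>%
        select("sample_id", "tissue", "timepoint"),
      sheet_path
    )
    counts <- read_counts(counts_path)
    sheet <- read_sample_sheet(sheet_path)
    sf <- size_factors(counts)
    expressed <- filter_expressed(counts, sf)
    counts_expr <- filter(counts, .data$feature_id %in% expressed)
    de <- de_test(counts_expr, sheet, sf = sf, alpha = fdr)
    readr::write_tsv(as_tibble(de), file.path(res, paste0("de_", tis, ".tsv")))
    norm <- normalize_counts(counts_expr, sf)
    pairs <- find_cis_pairs(
      filter(lnc_ann, .data$transcript_id %in% expressed),
      reference,
      window = cfg$cis_window
    )
    cis <- call_cis_targets(pairs, norm, alpha = fdr)
    readr::write_tsv(as_tibble(cis), file.path(res, paste0("cis_", tis, ".tsv")))
    write_edge_list(cis, file.path(res, paste0("cis_edges_", tis, ".tsv")))
    de_mrna <- filter(as_tibble(de), .data$significant, .data$feature_id %in% mrna_genes)
    universe <- intersect(expressed, mrna_genes)
    sets <- simulate_gene_sets(universe, intersect(de_ids, universe),
      seed = tseed + 11L
    )
    write_gmt(sets, file.path(ind, paste0("sets_", tis, ".gmt")))
    enr <- enrich_hypergeom(de_mrna$feature_id, read_gmt(file.path(ind, paste0(
      "sets_", tis, ".gmt"
    ))), universe, correction = "bh", alpha = fdr)
    readr::write_tsv(as_tibble(enr), file.path(res, paste0("enrich_", tis, ".tsv")))
    tissue_reports[[tis]] <- list(
      n_samples = sum(gsz),
      n_features = length(feature_ids),
      n_expressed = length(expressed),
      n_expressed_lncrna = length(intersect(expressed, retained_ids)),
      n_de = sum(de$significant),
      n_de_mrna = nrow(de_mrna),
      n_de_lncrna = sum(de$significant & de$feature_id %in% retained_ids),
      n_cis_pairs_tested = nrow(cis),
      n_cis_targets = sum(cis$is_cis_target),
      n_enriched_sets = sum(enr$significant)
    )
  }

  report <- list(
    config = cfg[setdiff(names(cfg), "tissues")],
    design = purrr::imap(cfg$tissues, function(g, nm) as.list(g)),
    discovery = list(
      n_assembled = nrow(disc),
      n_pass_length = sum(disc$filter_length == "pass"),
      n_pass_class = sum(disc$filter_class == "pass"),
      n_retained = sum(disc$retained),
      n_known = sum(disc$known, na.rm = TRUE),
      n_novel = sum(!disc$known, na.rm = TRUE),
      length_bins = stats::setNames(
        as.list(chars$length_bins$n),
        as.character(chars$length_bins$bin)
      )
    ),
    tissues = tissue_reports
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(report)
}
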