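#' The 11 positional lncRNA classes
#'
#' Rule-defined, mutually exclusive genomic-location classes of a lncRNA
#' relative to the protein-coding annotation, evaluated in this precedence
#' order (first matching rule wins):
#' 1. `sense_exonic` — exonic overlap with a coding gene, same strand;
#' 2. `antisense_exonic` — exonic overlap, opposite strand;
#' 3. `containing_gene` — a coding gene's span lies entirely within the
#'    lncRNA span (no exonic overlap);
#' 4. `sense_intronic` — lncRNA span inside a coding gene span without
#'    exonic overlap, same strand;
#' 5. `antisense_intronic` — as above, opposite strand;
#' 6. `bidirectional_promoter` — no overlap, gap < 1 kb, divergent
#'    head-to-head orientation (both 5' ends facing);
#' 7. `upstream_proximal` — gap <= 1 kb on the nearest gene's 5' side;
#' 8. `downstream_proximal` — gap <= 1 kb on the nearest gene's 3' side;
#' 9. `intergenic_same` — gap > 1 kb, same strand as the nearest gene;
#' 10. `intergenic_divergent` — gap > 1 kb, opposite strands, 5' ends
#'     facing;
#' 11. `intergenic_convergent` — gap > 1 kb, opposite strands, 3' ends
#'     facing.
#' Distances are measured span-to-span (gap bp between spans).
#'
#' @format Character vector of the 11 class names.
#' @export
POSITIONAL_CLASSES <- c(
  "sense_exonic", "antisense_exonic", "containing_gene",
  "sense_intronic", "antisense_intronic", "bidirectional_promoter",
  "upstream_proximal", "downstream_proximal",
  "intergenic_same", "intergenic_divergent", "intergenic_convergent"
)

# gap in bp between two spans on the same chromosome; 0 when they overlap
.span_gap <- function(s1, e1, s2, e2) {
  if (s2 > e1) {
    return(s2 - e1 - 1L)
  }
  if (s1 > e2) {
    return(s1 - e2 - 1L)
  }
  0L
}

.classify_one_position <- function(lnc_ex, lnc_strand,
                                   genes, gene_exons_by_gene) {
  if (nrow(genes) == 0) {
    return("intergenic_same")
  }
  lnc_start <- min(lnc_ex[, 1])
  lnc_end <- max(lnc_ex[, 2])
  gaps <- vapply(
    seq_len(nrow(genes)),
    function(i) .span_gap(lnc_start, lnc_end, genes$gene_start[i], genes$gene_end[i]),
    integer(1)
  )
  overl <- which(lnc_start <= genes$gene_end & genes$gene_start <= lnc_end)
  same_strand <- function(gs) lnc_strand == "." | gs == lnc_strand
  for (i in overl) {
    gex <- gene_exons_by_gene[[genes$gene_id[i]]]
    if (.any_exon_overlap(lnc_ex, gex)) {
      return(if (same_strand(genes$strand[i])) "sense_exonic" else "antisense_exonic")
    }
  }
  for (i in overl) {
    if (lnc_start <= genes$gene_start[i] && genes$gene_end[i] <= lnc_end) {
      return("containing_gene")
    }
  }
  for (i in overl) {
    if (genes$gene_start[i] <= lnc_start && lnc_end <= genes$gene_end[i]) {
      return(if (same_strand(genes$strand[i])) "sense_intronic" else "antisense_intronic")
    }
  }
  # residual partial span overlap without exon overlap: treat as intronic
  if (length(overl) > 0) {
    i <- overl[1]
    return(if (same_strand(genes$strand[i])) "sense_intronic" else "antisense_intronic")
  }
  nearest <- which.min(gaps)
  gap <- gaps[nearest]
  g_strand <- genes$strand[nearest]
  g_start <- genes$gene_start[nearest]
  lnc_left_of_gene <- lnc_end < g_start
  # which side of the gene is the lncRNA on, in the gene's orientation?
  on_5prime_side <- if (g_strand == "-") !lnc_left_of_gene else lnc_left_of_gene
  opposite <- !(lnc_strand == "." || g_strand == "." || lnc_strand == g_strand)
  if (gap <= 1000L) {
    if (opposite && on_5prime_side && gap < 1000L) {
      return("bidirectional_promoter")
    }
    return(if (on_5prime_side) "upstream_proximal" else "downstream_proximal")
  }
  if (!opposite) {
    return("intergenic_same")
  }
  if (on_5prime_side) "intergenic_divergent" else "intergenic_convergent"
}

#' Positional classification of lncRNA candidates
#'
#' Assigns one of the 11 classes in [POSITIONAL_CLASSES] to each candidate
#' transcript, relative to the protein-coding genes of `reference`.
#'
#' @param candidates An annotation tibble of lncRNA transcripts.
#' @param reference The reference annotation; only `protein_coding` genes
#'   are used.
#' @return A tibble (`transcript_id`, `positional_class`,
#'   `nearest_gene_id`, `nearest_gene_distance`).
#' @export
classify_position <- function(candidates, reference) {
  validate_annotation(candidates)
  coding <- filter(reference, .data$biotype == "protein_coding")
  genes <- gene_table(coding)
  gene_exons <- lapply(
    split(seq_len(nrow(coding)), coding$gene_id),
    function(ix) cbind(coding$start[ix], coding$end[ix])
  )
  tx <- transcript_table(candidates)
  cand_exons <- lapply(
    split(seq_len(nrow(candidates)), candidates$transcript_id),
    function(ix) cbind(candidates$start[ix], candidates$end[ix])
  )
  res <- purrr::map_chr(seq_len(nrow(tx)), function(i) {
    g <- genes[genes$chrom == tx$chrom[i], , drop = FALSE]
    .classify_one_position(
      cand_exons[[tx$transcript_id[i]]], tx$strand[i], g, gene_exons
    )
  })
  nearest <- purrr::map(seq_len(nrow(tx)), function(i) {
    g <- genes[genes$chrom == tx$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      return(list(id = NA_character_, d = NA_integer_))
    }
    gaps <- vapply(
      seq_len(nrow(g)),
      function(k) .span_gap(tx$tx_start[i], tx$tx_end[i], g$gene_start[k], g$gene_end[k]),
      integer(1)
    )
    k <- which.min(gaps)
    list(id = g$gene_id[k], d = gaps[k])
  })
  tibble(
    transcript_id = tx$transcript_id,
    positional_class = res,
    nearest_gene_id = purrr::map_chr(nearest, "id"),
    nearest_gene_distance = purrr::map_int(nearest, "d")
  )
}

#' Run the lncRNA identification cascade
#'
#' The fixed filter order is: (1) spliced length strictly greater than
#' `min_length` bp; (2) class code in `keep_codes` (`i`, `u`, `x`) against
#' the protein-coding + other-ncRNA reference; (3) the coding-evidence
#' gate ([coding_gate()]), using external CNCI/CPAT scores and BLAST hits
#' when supplied and the built-in combiner otherwise; survivors are then
#' compared with the known-lncRNA annotation (codes `=`, `c`, `j` mean
#' known, the rest novel) and positionally classified. A transcript
#' failing filter k carries `"not_evaluated"` for all later filters.
#'
#' @param assembled Annotation tibble of assembled transcripts.
#' @param reference Reference annotation (protein-coding + other ncRNA).
#' @param known_lnc Known-lncRNA annotation.
#' @param seqs Sequence tibble from [read_fasta()]; a survivor candidate
#'   with no sequence fails the coding gate with reason `"no_sequence"`.
#' @param coding_model A `coding_model` for the built-in scorer (optional
#'   when both external score tables are supplied).
#' @param cnci,cpat Optional external score tibbles
#'   (`transcript_id`, `cnci_score`) / (`transcript_id`, `cpat_score`).
#' @param blast Optional BLAST hit tibble from [read_blast_tab()].
#' @param min_length Length filter in bp (strict `>`, default 200).
#' @param keep_codes Retained class codes (default `c("i","u","x")`).
#' @param thresholds Coding-gate thresholds.
#' @return A `wean_discovery` tibble with one row per assembled transcript:
#'   filter verdicts (`filter_length`, `filter_class`, `filter_coding`),
#'   `retained`, `known`, class codes against both references, positional
#'   class and the descriptive fields used by [characterize_lncrnas()].
#' @export
discover_lncrnas <- function(assembled, reference, known_lnc, seqs,
                             coding_model = NULL, cnci = NULL, cpat = NULL,
                             blast = NULL, min_length = 200,
                             keep_codes = c("i", "u", "x"),
                             thresholds = default_gate_thresholds()) {
  tx <- transcript_table(assembled)
  n <- nrow(tx)
  res <- tx %>% select(
    "transcript_id", "gene_id", "chrom", "strand",
    "tx_start", "tx_end", "n_exons", "tx_length"
  )

  # filter 1: length
  pass_len <- res$tx_length > min_length
  res$filter_length <- ifelse(pass_len, "pass", "fail")

  # filter 2: class code vs protein-coding + other ncRNA
  res$class_code <- NA_character_
  res$class_ref_id <- NA_character_
  idx2 <- which(pass_len)
  if (length(idx2) > 0) {
    sub <- filter(assembled, .data$transcript_id %in% res$transcript_id[idx2])
    cc <- compare_transcripts(sub, reference,
      biotypes = c("protein_coding", "other_ncRNA")
    )
    m <- match(res$transcript_id, cc$transcript_id)
    res$class_code <- cc$class_code[m]
    res$class_ref_id <- cc$ref_id[m]
  }
  pass_class <- pass_len & res$class_code %in% keep_codes
  res$filter_class <- dplyr::case_when(
    !pass_len ~ "not_evaluated",
    pass_class ~ "pass",
    TRUE ~ "fail"
  )

  # filter 3: coding gate
  res$filter_coding <- "not_evaluated"
  res$gate_reason <- NA_character_
  res$combined_prob <- NA_real_
  res$peptide_len <- NA_integer_
  idx3 <- which(pass_class)
  pass_coding <- rep(FALSE, n)
  if (length(idx3) > 0) {
    ids <- res$transcript_id[idx3]
    have_seq <- ids %in% seqs$transcript_id
    external_only <- !is.null(cnci) && !is.null(cpat)
    if (is.null(coding_model) && !external_only) {
      abort("discover_lncrnas() needs a coding_model or both external score tables")
    }
    cp <- tibble(transcript_id = ids)
    if (any(have_seq)) {
      ss <- seqs[match(ids[have_seq], seqs$transcript_id), ]
      if (!is.null(coding_model)) {
        scored <- score_coding_potential(ss, coding_model)
      } else {
        orfs <- purrr::map(ss$seq, find_longest_orf)
        scored <- tibble(
          transcript_id = ss$transcript_id,
          peptide_len = purrr::map_int(orfs, "peptide_len"),
          combined_prob = NA_real_
        )
      }
      cp <- left_join(cp, scored, by = "transcript_id")
    } else {
      cp$peptide_len <- NA_integer_
      cp$combined_prob <- NA_real_
    }
    if (!is.null(cnci)) cp <- left_join(cp, cnci, by = "transcript_id")
    if (!is.null(cpat)) cp <- left_join(cp, cpat, by = "transcript_id")
    if (!is.null(blast)) cp <- left_join(cp, blast, by = "transcript_id")
    if (any(have_seq)) {
      gated <- coding_gate(cp[have_seq, , drop = FALSE], thresholds)
      gated <- bind_rows(gated, cp[!have_seq, , drop = FALSE])
      gated <- gated[match(cp$transcript_id, gated$transcript_id), ]
    } else {
      gated <- cp
      gated$retain <- NA
      gated$gate_reason <- NA_character_
    }
    gated$retain[!have_seq] <- FALSE
    gated$gate_reason[!have_seq] <- "no_sequence"
    m <- match(res$transcript_id[idx3], gated$transcript_id)
    res$filter_coding[idx3] <- ifelse(gated$retain[m], "pass", "fail")
    res$gate_reason[idx3] <- gated$gate_reason[m]
    if ("combined_prob" %in% names(gated)) {
      res$combined_prob[idx3] <- gated$combined_prob[m]
    }
    if ("peptide_len" %in% names(gated)) {
      res$peptide_len[idx3] <- gated$peptide_len[m]
    }
    pass_coding[idx3] <- gated$retain[m]
  }

  res$retained <- pass_coding
  # known/novel vs the known-lncRNA reference
  res$class_code_vs_known <- NA_character_
  res$known <- NA
  idx4 <- which(res$retained)
  if (length(idx4) > 0) {
    sub <- filter(assembled, .data$transcript_id %in% res$transcript_id[idx4])
    ck <- compare_transcripts(sub, known_lnc)
    m <- match(res$transcript_id, ck$transcript_id)
    res$class_code_vs_known <- ck$class_code[m]
    res$known[idx4] <- res$class_code_vs_known[idx4] %in% c("=", "c", "j")
  }
  # positional classification of survivors
  res$positional_class <- NA_character_
  res$nearest_gene_id <- NA_character_
  res$nearest_gene_distance <- NA_integer_
  if (length(idx4) > 0) {
    sub <- filter(assembled, .data$transcript_id %in% res$transcript_id[idx4])
    pc <- classify_position(sub, reference)
    m <- match(res$transcript_id, pc$transcript_id)
    fill <- !is.na(m)
    res$positional_class[fill] <- pc$positional_class[m[fill]]
    res$nearest_gene_id[fill] <- pc$nearest_gene_id[m[fill]]
    res$nearest_gene_distance[fill] <- pc$nearest_gene_distance[m[fill]]
  }
  class(res) <- c("wean_discovery", class(res))
  res
}

#' Paper-style length bins for lncRNA transcripts
#'
#' @return Ordered factor labels of the bins.
#' @export
LENGTH_BINS <- c("200-999", "1000-2499", "2500-4999", "5000-9999", ">9999")

.length_bin <- function(len) {
  cut(len,
    breaks = c(-Inf, 999, 2499, 4999, 9999, Inf),
    labels = LENGTH_BINS
  )
}

#' Descriptive characterization of retained lncRNAs
#'
#' Length histogram in fixed bins (200-999, 1000-2499, 2500-4999,
#' 5000-9999, >9999 bp), transcripts per gene, exons per transcript and
#' per-chromosome counts.
#'
#' @param discovery A `wean_discovery` tibble (only retained rows are
#'   summarized) or any tibble with `tx_length`, `gene_id`, `n_exons`,
#'   `chrom` columns.
#' @return A named list of summary tibbles (`length_bins`,
#'   `transcripts_per_gene`, `exons_per_transcript`, `per_chromosome`,
#'   `n_transcripts`, `n_genes`).
#' @export
characterize_lncrnas <- function(discovery) {
  d <- discovery
  if ("retained" %in% names(d)) d <- filter(d, .data$retained)
  if (nrow(d) == 0) {
    return(list(
      length_bins = tibble(bin = character(), n = integer(), fraction = numeric()),
      transcripts_per_gene = tibble(n_transcripts = integer(), n_genes = integer()),
      exons_per_transcript = tibble(n_exons = integer(), n = integer()),
      per_chromosome = tibble(chrom = character(), n = integer()),
      n_transcripts = 0L, n_genes = 0L
    ))
  }
  bins <- d %>%
    mutate(bin = .length_bin(.data$tx_length)) %>%
    count(.data$bin, .drop = FALSE) %>%
    mutate(fraction = .data$n / sum(.data$n))
  tpg <- d %>%
    count(.data$gene_id, name = "n_transcripts") %>%
    count(.data$n_transcripts, name = "n_genes")
  ept <- d %>% count(.data$n_exons)
  chrom <- d %>% count(.data$chrom)
  list(
    length_bins = bins,
    transcripts_per_gene = tpg,
    exons_per_transcript = ept,
    per_chromosome = chrom,
    n_transcripts = nrow(d),
    n_genes = dplyr::n_distinct(d$gene_id)
  )
}
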