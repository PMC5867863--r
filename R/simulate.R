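# Run code under a temporary RNG state so simulations are reproducible
# without touching the caller's RNG.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The `"study"`
#' preset mirrors the shape of a two-tissue, two-timepoint weaning design:
#' rumen 16 + 16 and ileum 8 + 8 libraries, ~15k protein-coding genes,
#' ~2k lncRNA candidates, NB dispersion 0.1; the `"small"` preset keeps
#' the same per-sample design but shrinks the annotation for fast
#' end-to-end runs. Any field can be overridden by name.
#'
#' @param preset `"study"` or `"small"`.
#' @param seed Integer seed; the same config and seed give byte-identical
#'   outputs.
#' @param ... Named overrides of config fields.
#' @return A `sim_config` list.
#' @export
sim_config <- function(preset = c("study", "small"), seed = 1, ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    seed = as.integer(seed),
    n_chromosomes = 10,
    slot_bp = 130000,
    n_coding_genes = 15000,
    n_other_ncrna = 200,
    class_code_block_sizes = c(
      "=" = 25, "c" = 25, "j" = 25, "e" = 25,
      "o" = 25, "i" = 25, "x" = 25, "u" = 25
    ),
    n_known_lnc = 88,
    n_lnc_intergenic = 1500,
    n_cis_units = 400,
    n_short = 150,
    n_contaminants = 150,
    corpus_per_class = 500,
    max_noncoding_peptide = 60,
    # count model
    tissues = list(rumen = c(D33 = 16, D96 = 16), ileum = c(D33 = 8, D96 = 8)),
    mu_meanlog = log(250), mu_sdlog = 1.2,
    dispersion = 0.1,
    de_fraction = 0.10, de_log2fc = 1,
    lib_range = c(0.7, 1.4),
    cis_rho = 0.8,
    cis_window = 50000
  )
  if (preset == "small") {
    cfg$n_chromosomes <- 4
    cfg$n_coding_genes <- 300
    cfg$n_other_ncrna <- 30
    cfg$class_code_block_sizes <- c(
      "=" = 5, "c" = 5, "j" = 5, "e" = 5, "o" = 5, "i" = 5, "x" = 5, "u" = 5
    )
    cfg$n_known_lnc <- 20
    cfg$n_lnc_intergenic <- 120
    cfg$n_cis_units <- 40
    cfg$n_short <- 20
    cfg$n_contaminants <- 20
    cfg$corpus_per_class <- 300
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) abort(paste0("unknown sim_config field(s): ", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

# --- sequence generation ---------------------------------------------------

.noncoding_base_probs <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)

# codon usage for synthetic coding sequences: GC3-biased over the 61
# sense codons, so coding hexamer usage departs clearly from background
.coding_codon_probs <- local({
  b <- c("A", "C", "G", "T")
  codons <- do.call(paste0, expand.grid(b, b, b, stringsAsFactors = FALSE))
  codons <- setdiff(sort(codons), c("TAA", "TAG", "TGA"))
  third <- substr(codons, 3, 3)
  gc12 <- (substr(codons, 1, 1) %in% c("G", "C")) + (substr(codons, 2, 2) %in% c("G", "C"))
  w <- ifelse(third %in% c("G", "C"), 3, 1) * (1 + 0.5 * gc12)
  stats::setNames(w / sum(w), codons)
})

.random_noncoding <- function(len) {
  paste(
    sample(names(.noncoding_base_probs), len,
      replace = TRUE,
      prob = .noncoding_base_probs
    ),
    collapse = ""
  )
}

.random_coding <- function(n_codons, utr5 = 30, utr3 = 60) {
  cds <- paste(
    sample(names(.coding_codon_probs), n_codons,
      replace = TRUE,
      prob = .coding_codon_probs
    ),
    collapse = ""
  )
  paste0(
    .random_noncoding(utr5), "ATG", cds, "TAA", .random_noncoding(utr3)
  )
}

# Inject in-frame stop codons until no ORF can code for more than
# `max_pep` amino acids; keeps noncoding sequences noncoding by
# construction, whatever their length.
.cap_orf <- function(seq, max_pep = 60) {
  half <- max(1L, max_pep %/% 2L)
  repeat {
    orf <- find_longest_orf(seq)
    if (orf$peptide_len <= max_pep) {
      return(seq)
    }
    # break the offending ORF with stops every `half` codons in one pass
    offs <- orf$start_offset + 3L * seq(half, orf$peptide_len - 1L, by = half)
    for (at in offs) {
      substr(seq, at + 1L, at + 3L) <- "TAA"
    }
  }
}

#' Simulate a labeled coding/noncoding sequence corpus
#'
#' Coding sequences carry a GC3-biased open reading frame of 110-350
#' codons between short UTRs; noncoding sequences are background-composition
#' DNA with every ORF capped below `max_pep` amino acids.
#'
#' @param n_per_class Sequences per class.
#' @param seed Integer seed.
#' @param max_pep ORF cap for the noncoding class (amino acids).
#' @return A tibble (`transcript_id`, `seq`, `label`) with label 1 = coding.
#' @export
simulate_coding_corpus <- function(n_per_class, seed = 1, max_pep = 60) {
  .with_seed(seed, {
    coding <- vapply(
      seq_len(n_per_class),
      function(i) .random_coding(sample(110:350, 1)),
      character(1)
    )
    noncoding <- vapply(
      seq_len(n_per_class),
      function(i) .cap_orf(.random_noncoding(sample(300:1200, 1)), max_pep),
      character(1)
    )
    tibble(
      transcript_id = c(
        sprintf("COD_%05d", seq_len(n_per_class)),
        sprintf("NON_%05d", seq_len(n_per_class))
      ),
      seq = c(coding, noncoding),
      label = rep(c(1L, 0L), each = n_per_class)
    )
  })
}

# --- annotation geometry ---------------------------------------------------

# Planted query/reference exon-chain pairs satisfying each class-code
# definition by construction. Origin `o` is the unit anchor; the reference
# has exons o+[0,499], [1000,1499], [2000,2499] (strand +).
.plant_ref_exons <- function(o) {
  cbind(o + c(0L, 1000L, 2000L), o + c(499L, 1499L, 2499L))
}

.plant_query_exons <- function(code, o) {
  switch(code,
    "=" = list(ex = cbind(o + c(100L, 1000L, 2000L), o + c(499L, 1499L, 2399L)), strand = "+"),
    "c" = list(ex = cbind(o + c(1100L, 2000L), o + c(1499L, 2300L)), strand = "+"),
    "j" = list(ex = cbind(o + c(100L, 1000L, 1600L), o + c(499L, 1200L, 1900L)), strand = "+"),
    "e" = list(ex = cbind(o + 400L, o + 800L), strand = "+"),
    "o" = list(ex = cbind(o + c(300L, 1200L), o + c(700L, 1600L)), strand = "+"),
    "i" = list(ex = cbind(o + 600L, o + 900L), strand = "+"),
    "x" = list(ex = cbind(o + 100L, o + 400L), strand = "-"),
    "u" = list(ex = cbind(o + 0L, o + 599L), strand = "+"),
    abort(paste0("no planted construction for code ", code))
  )
}

.exon_rows <- function(ex, chrom, strand, gene_id, transcript_id, biotype) {
  tibble(
    chrom = chrom, start = as.integer(ex[, 1]), end = as.integer(ex[, 2]),
    strand = strand, gene_id = gene_id, transcript_id = transcript_id,
    biotype = biotype
  )
}

# random multi-exon chain with a given total exonic length, anchored at `at`
.random_chain <- function(at, total_len, n_exons) {
  if (n_exons == 1) {
    return(cbind(at, at + total_len - 1L))
  }
  cuts <- sort(sample(seq_len(total_len - 1L), n_exons - 1L))
  lens <- diff(c(0L, cuts, total_len))
  introns <- sample(200:2000, n_exons - 1L, replace = TRUE)
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  pos <- at
  for (k in seq_len(n_exons)) {
    starts[k] <- pos
    ends[k] <- pos + lens[k] - 1L
    if (k < n_exons) pos <- ends[k] + 1L + introns[k]
  }
  cbind(starts, ends)
}

.lnc_length <- function() {
  bin <- sample(1:5, 1, prob = c(0.447, 0.2925, 0.15, 0.098, 0.0125))
  switch(bin,
    sample(250:999, 1), sample(1000:2499, 1), sample(2500:4999, 1),
    sample(5000:9999, 1), sample(10000:12000, 1)
  )
}

.lnc_n_exons <- function(len) {
  max_ex <- max(1L, min(15L, len %/% 120L))
  min(1L + stats::rpois(1, 0.7), max_ex)
}

#' Simulate annotations, sequences and a planted-truth manifest
#'
#' Lays out isolated genomic "units" on toy chromosomes: filler
#' protein-coding and other-ncRNA genes, one block of query transcripts
#' per class code (each constructed to satisfy exactly its code
#' definition), known-lncRNA matches, intergenic lncRNA candidates, cis
#' units (a coding gene with a lncRNA 5-40 kb away), sub-200 bp
#' transcripts and protein-coding contaminants (planted in-frame ORF of at
#' least 120 codons plus a homology hit). Sequences follow the
#' coding/noncoding composition models of [simulate_coding_corpus()], and
#' every emitted transcript is recorded in the manifest with its planted
#' class code, coding label and expected filter outcomes.
#'
#' @param cfg A [sim_config()].
#' @return A list: `reference`, `known_lnc`, `assembled` (annotation
#'   tibbles), `seqs` (sequences of assembled transcripts), `blast`
#'   (synthetic homology hits for contaminants), `manifest`.
#' @export
simulate_annotation <- function(cfg) {
  .with_seed(cfg$seed + 101L, {
    ref <- list()
    known <- list()
    asm <- list()
    man <- list()
    unit <- 0L
    n_units_guess <- cfg$n_coding_genes + cfg$n_other_ncrna +
      sum(cfg$class_code_block_sizes) + cfg$n_known_lnc +
      cfg$n_lnc_intergenic + cfg$n_cis_units + cfg$n_short + cfg$n_contaminants
    per_chrom <- ceiling(n_units_guess / cfg$n_chromosomes)
    # shuffled slot assignment interleaves unit types across chromosomes
    slot_order <- sample.int(n_units_guess)
    next_slot <- function() {
      unit <<- unit + 1L
      k <- slot_order[unit] - 1L
      chrom_i <- (k %/% per_chrom) + 1L
      slot_i <- k %% per_chrom
      list(chrom = paste0("chr", chrom_i), o = slot_i * cfg$slot_bp + 10000L)
    }
    add_man <- function(tid, code, coding_label, len_ok, class_ok, coding_ok,
                        known_flag = FALSE, cis_gene = NA_character_,
                        cis_distance = NA_integer_) {
      man[[length(man) + 1L]] <<- tibble(
        transcript_id = tid, planted_code = code, coding_label = coding_label,
        expect_length_pass = len_ok, expect_class_pass = class_ok,
        expect_coding_pass = coding_ok,
        expect_retained = len_ok & class_ok & coding_ok,
        planted_known = known_flag, cis_gene = cis_gene,
        cis_distance = cis_distance
      )
    }

    # filler protein-coding genes
    for (g in seq_len(cfg$n_coding_genes)) {
      s <- next_slot()
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("MRNA_G%05d", g)
      n_tx <- sample(1:2, 1, prob = c(0.85, 0.15))
      for (t in seq_len(n_tx)) {
        len <- sample(600:3000, 1)
        ex <- .random_chain(s$o + (t - 1L) * 50L, len, sample(2:5, 1))
        ref[[length(ref) + 1L]] <- .exon_rows(
          ex, s$chrom, strand, gid,
          sprintf("%s_T%d", gid, t), "protein_coding"
        )
      }
    }
    # other-ncRNA genes (tRNA/snoRNA-like short features)
    for (g in seq_len(cfg$n_other_ncrna)) {
      s <- next_slot()
      gid <- sprintf("NCRNA_G%05d", g)
      ex <- cbind(s$o, s$o + sample(70:300, 1))
      ref[[length(ref) + 1L]] <- .exon_rows(
        ex, s$chrom, sample(c("+", "-"), 1), gid,
        paste0(gid, "_T1"), "other_ncRNA"
      )
    }

    qn <- 0L
    new_qid <- function() {
      qn <<- qn + 1L
      sprintf("ASM_%05d", qn)
    }

    # class-code blocks: one reference gene + one query per unit
    for (code in names(cfg$class_code_block_sizes)) {
      for (b in seq_len(cfg$class_code_block_sizes[[code]])) {
        s <- next_slot()
        if (code != "u") {
          gid <- sprintf("CCREF_%s_%03d", chartr("=", "E", code), b)
          ref[[length(ref) + 1L]] <- .exon_rows(
            .plant_ref_exons(s$o), s$chrom, "+", gid, paste0(gid, "_T1"),
            "protein_coding"
          )
        }
        q <- .plant_query_exons(code, s$o)
        tid <- new_qid()
        asm[[length(asm) + 1L]] <- .exon_rows(
          q$ex, s$chrom, q$strand, tid, tid, "unknown"
        )
        add_man(tid, code, "noncoding",
          len_ok = TRUE,
          class_ok = code %in% c("i", "u", "x"),
          coding_ok = if (code %in% c("i", "u", "x")) TRUE else NA
        )
      }
    }

    # known lncRNAs: a known reference transcript plus a query matching it
    # with code "=", "c" or "j" (cycled); "u" against the coding reference
    known_codes <- rep(c("=", "c", "j"), length.out = cfg$n_known_lnc)
    for (g in seq_len(cfg$n_known_lnc)) {
      s <- next_slot()
      gid <- sprintf("KNOWN_G%04d", g)
      known[[length(known) + 1L]] <- .exon_rows(
        .plant_ref_exons(s$o), s$chrom, "+", gid, paste0(gid, "_T1"),
        "known_lncRNA"
      )
      q <- .plant_query_exons(known_codes[g], s$o)
      tid <- new_qid()
      asm[[length(asm) + 1L]] <- .exon_rows(q$ex, s$chrom, q$strand, tid, tid, "unknown")
      add_man(tid, "u", "noncoding",
        len_ok = TRUE, class_ok = TRUE, coding_ok = TRUE,
        known_flag = TRUE
      )
    }

    # intergenic lncRNA candidates ("u")
    for (g in seq_len(cfg$n_lnc_intergenic)) {
      s <- next_slot()
      len <- .lnc_length()
      ex <- .random_chain(s$o + 50000L, len, .lnc_n_exons(len))
      tid <- new_qid()
      asm[[length(asm) + 1L]] <- .exon_rows(
        ex, s$chrom, sample(c("+", "-"), 1), tid, tid, "unknown"
      )
      add_man(tid, "u", "noncoding", len_ok = TRUE, class_ok = TRUE, coding_ok = TRUE)
    }

    # cis units: coding gene + intergenic lncRNA 5-40 kb downstream
    for (g in seq_len(cfg$n_cis_units)) {
      s <- next_slot()
      gid <- sprintf("CISG_%04d", g)
      glen <- sample(1500:4000, 1)
      gex <- .random_chain(s$o, glen, sample(2:4, 1))
      ref[[length(ref) + 1L]] <- .exon_rows(
        gex, s$chrom, sample(c("+", "-"), 1), gid, paste0(gid, "_T1"),
        "protein_coding"
      )
      d <- sample(5000:40000, 1)
      len <- sample(400:1500, 1)
      lstart <- max(gex[, 2]) + 1L + d # span gap from the gene is exactly d
      ex <- cbind(lstart, lstart + len - 1L)
      tid <- new_qid()
      asm[[length(asm) + 1L]] <- .exon_rows(
        ex, s$chrom, sample(c("+", "-"), 1), tid, tid, "unknown"
      )
      add_man(tid, "u", "noncoding",
        len_ok = TRUE, class_ok = TRUE, coding_ok = TRUE,
        cis_gene = gid, cis_distance = d
      )
    }

    # short transcripts (fail the >200 bp filter; 200 itself must fail)
    for (g in seq_len(cfg$n_short)) {
      s <- next_slot()
      len <- if (g == 1L) 200L else sample(80:200, 1)
      ex <- cbind(s$o + 60000L, s$o + 60000L + len - 1L)
      tid <- new_qid()
      asm[[length(asm) + 1L]] <- .exon_rows(ex, s$chrom, "+", tid, tid, "unknown")
      add_man(tid, "u", "noncoding", len_ok = FALSE, class_ok = NA, coding_ok = NA)
    }

    # protein-coding contaminants: intergenic but carry a long ORF and a
    # synthetic homology hit
    contam_ids <- character(0)
    for (g in seq_len(cfg$n_contaminants)) {
      s <- next_slot()
      len <- sample(600:1400, 1)
      ex <- .random_chain(s$o + 60000L, len, sample(1:3, 1))
      tid <- new_qid()
      asm[[length(asm) + 1L]] <- .exon_rows(ex, s$chrom, "+", tid, tid, "unknown")
      add_man(tid, "u", "coding", len_ok = TRUE, class_ok = TRUE, coding_ok = FALSE)
      contam_ids <- c(contam_ids, tid)
    }

    reference <- .normalize_exons(bind_rows(ref))
    known_lnc <- if (length(known) > 0) {
      .normalize_exons(bind_rows(known))
    } else {
      tibble(
        chrom = character(), start = integer(), end = integer(),
        strand = character(), gene_id = character(),
        transcript_id = character(), biotype = character()
      )
    }
    assembled <- .normalize_exons(bind_rows(asm))
    manifest <- bind_rows(man)

    # sequences: length-matched to the exon chains, composition by label
    tx <- transcript_table(assembled)
    lab <- manifest$coding_label[match(tx$transcript_id, manifest$transcript_id)]
    seqs <- tibble(
      transcript_id = tx$transcript_id,
      seq = purrr::map2_chr(tx$tx_length, lab, function(len, l) {
        if (l == "coding") {
          n_cod <- max(120L, (len - 100L) %/% 3L)
          s <- .random_coding(n_cod, utr5 = 20, utr3 = 20)
          # trim or pad to the annotated length, keeping the ORF intact
          if (nchar(s) >= len) substr(s, 1, len) else paste0(s, .random_noncoding(len - nchar(s)))
        } else {
          .cap_orf(.random_noncoding(len), cfg$max_noncoding_peptide)
        }
      })
    )
    seqs$length <- nchar(seqs$seq)
    blast <- tibble(
      transcript_id = contam_ids,
      min_evalue = 10^(-stats::runif(length(contam_ids), 10, 40))
    )
    list(
      reference = reference, known_lnc = known_lnc, assembled = assembled,
      seqs = seqs, blast = blast, manifest = manifest
    )
  })
}

# --- count simulation ------------------------------------------------------

#' Simulate a negative-binomial count matrix with planted structure
#'
#' Counts are NB with mean `s_j * mu_ij` and dispersion `alpha`
#' (`Var = mu + alpha mu^2`); `s_j` are per-library depth multipliers.
#' Planted DE features have their second-group mean multiplied by
#' `2^log2fc`. Planted cis pairs share a per-sample latent Gaussian factor
#' on the log2-mean scale whose loading is scaled so that the *realized*
#' correlation of `log2(count + 1)` matches the target `rho` after
#' counting-noise attenuation (delta-method correction).
#'
#' @param feature_ids Character vector of feature ids.
#' @param group_sizes Integer vector `c(nA, nB)` (e.g. D33/D96 libraries).
#' @param mu Baseline means: scalar, vector, or `NULL` to draw log-normal
#'   means `exp(N(mu_meanlog, mu_sdlog))`.
#' @param dispersion NB dispersion alpha (0 gives Poisson).
#' @param de_ids Features with a planted group shift.
#' @param de_log2fc Planted log2 fold change (scalar or per `de_ids`).
#' @param cis_pairs Tibble (`id_a`, `id_b`, optional `rho`) of planted
#'   co-expressed pairs (features must be disjoint from `de_ids`).
#' @param rho Default target correlation for `cis_pairs`.
#' @param lib_range Range of uniform library-depth multipliers.
#' @param mu_meanlog,mu_sdlog Log-normal parameters for drawn means.
#' @param sample_prefix Prefix for generated sample ids.
#' @param seed Integer seed.
#' @return A list: `counts` (tibble), `sample_sheet` (`sample_id`,
#'   `timepoint`), `truth` (per-feature `mu`, `is_de`, `log2fc`),
#'   `cis_truth` (the planted pairs with their loadings), `lib` (the true
#'   depth multipliers).
#' @export
simulate_counts <- function(feature_ids, group_sizes = c(16, 16), mu = NULL,
                            dispersion = 0.1, de_ids = character(0),
                            de_log2fc = 1, cis_pairs = NULL, rho = 0.8,
                            lib_range = c(0.7, 1.4),
                            mu_meanlog = log(250), mu_sdlog = 1.2,
                            sample_prefix = "S", seed = 1) {
  .with_seed(seed, {
    nfeat <- length(feature_ids)
    na <- group_sizes[1]
    nb <- group_sizes[2]
    n <- na + nb
    sample_id <- sprintf("%s_%s_%02d", sample_prefix, rep(c("D33", "D96"), c(na, nb)), c(seq_len(na), seq_len(nb)))
    timepoint <- rep(c("D33", "D96"), c(na, nb))
    if (is.null(mu)) {
      mu <- exp(stats::rnorm(nfeat, mu_meanlog, mu_sdlog))
    } else if (length(mu) == 1) {
      mu <- rep(mu, nfeat)
    }
    names(mu) <- feature_ids
    # planted cis features get a floor so counting noise stays moderate
    if (!is.null(cis_pairs) && nrow(cis_pairs) > 0) {
      cis_feats <- unique(c(cis_pairs$id_a, cis_pairs$id_b))
      mu[cis_feats] <- pmax(mu[cis_feats], 50)
    }
    lfc <- stats::setNames(rep(0, nfeat), feature_ids)
    lfc[de_ids] <- de_log2fc
    log2mu <- matrix(rep(log2(mu), n), nrow = nfeat)
    log2mu[, (na + 1):n] <- log2mu[, (na + 1):n] + lfc
    cis_truth <- NULL
    if (!is.null(cis_pairs) && nrow(cis_pairs) > 0) {
      if (!"rho" %in% names(cis_pairs)) cis_pairs$rho <- rho
      l2e2 <- log2(exp(1))^2
      tau <- numeric(nrow(cis_pairs))
      for (p in seq_len(nrow(cis_pairs))) {
        a <- cis_pairs$id_a[p]
        b <- cis_pairs$id_b[p]
        r <- cis_pairs$rho[p]
        # Var(log2(K+1)) ~ (1/mu + alpha) / ln(2)^2 by the delta method
        ca <- (1 / mu[a] + dispersion) * l2e2
        cb <- (1 / mu[b] + dispersion) * l2e2
        # solve rho^2 (tau^2+ca)(tau^2+cb) = tau^4 for tau^2
        A <- 1 - r^2
        B <- -r^2 * (ca + cb)
        C <- -r^2 * ca * cb
        tau2 <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
        tau[p] <- sqrt(tau2)
        f <- stats::rnorm(n)
        log2mu[match(a, feature_ids), ] <- log2mu[match(a, feature_ids), ] + tau[p] * f
        log2mu[match(b, feature_ids), ] <- log2mu[match(b, feature_ids), ] + tau[p] * f
      }
      cis_truth <- cis_pairs %>% mutate(tau = tau)
    }
    lib <- stats::runif(n, lib_range[1], lib_range[2])
    mean_mat <- sweep(2^log2mu, 2, lib, "*")
    counts <- if (dispersion > 0) {
      matrix(
        stats::rnbinom(nfeat * n, mu = mean_mat, size = 1 / dispersion),
        nrow = nfeat
      )
    } else {
      matrix(stats::rpois(nfeat * n, lambda = mean_mat), nrow = nfeat)
    }
    rownames(counts) <- feature_ids
    colnames(counts) <- sample_id
    list(
      counts = .matrix_to_tbl(counts),
      sample_sheet = tibble(sample_id = sample_id, timepoint = timepoint),
      truth = tibble(
        feature_id = feature_ids, mu = unname(mu),
        is_de = feature_ids %in% de_ids, log2fc = unname(lfc)
      ),
      cis_truth = cis_truth,
      lib = tibble(sample_id = sample_id, lib = lib)
    )
  })
}

#' Simulate gene-set collections with one planted enriched set
#'
#' @param universe Character vector of gene ids.
#' @param enriched_in Genes the planted set is drawn from (e.g. planted DE
#'   genes).
#' @param n_sets Number of background sets.
#' @param set_size Genes per set.
#' @param seed Integer seed.
#' @return A named list of gene sets; the planted set is named
#'   `"planted_set"`.
#' @export
simulate_gene_sets <- function(universe, enriched_in, n_sets = 20,
                               set_size = 50, seed = 1) {
  .with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) sample(universe, set_size))
    names(sets) <- sprintf("random_set_%02d", seq_len(n_sets))
    planted <- unique(c(
      sample(enriched_in, min(set_size * 0.8, length(enriched_in))),
      sample(universe, ceiling(set_size * 0.2))
    ))
    c(sets, list(planted_set = planted))
  })
}
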