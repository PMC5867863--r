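# Fickett (1982) TESTCODE lookup tables: position-asymmetry and composition
# probabilities per base, with their weights and threshold bins.
.fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
.fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_position_breaks <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
.fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
.fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
.fickett_content_breaks <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)

STOP_CODONS <- c("TAA", "TAG", "TGA")

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.frame_codons <- function(seq, frame) {
  n <- nchar(seq)
  m <- (n - frame) %/% 3
  if (m < 1) {
    return(character(0))
  }
  starts <- frame + 1L + 3L * (0:(m - 1L))
  substring(seq, starts, starts + 2L)
}

# Longest ORF in the three forward frames of one strand.
.orf_one_strand <- function(seq) {
  best <- list(frame = 0L, start_offset = NA_integer_, peptide_len = 0L, has_stop = NA)
  for (f in 0:2) {
    cods <- .frame_codons(seq, f)
    m <- length(cods)
    if (m == 0) next
    is_stop <- cods %in% STOP_CODONS
    is_atg <- cods == "ATG"
    if (!any(is_atg)) next
    stop_idx <- which(is_stop)
    for (a in which(is_atg)) {
      nxt <- stop_idx[stop_idx > a]
      if (length(nxt) > 0) {
        len <- nxt[1] - a
        has_stop <- TRUE
        # skip ATGs inside an already-scanned ORF of this frame: the first
        # ATG before a given stop is the longest, but later ATGs before the
        # same stop are shorter, so they can never beat it
      } else {
        len <- m - a + 1L
        has_stop <- FALSE
      }
      off <- f + 3L * (a - 1L)
      if (len > best$peptide_len ||
        (len == best$peptide_len && len > 0 && off < best$start_offset)) {
        best <- list(frame = f, start_offset = off, peptide_len = len, has_stop = has_stop)
      }
    }
  }
  best
}

#' Find the longest open reading frame of a transcript sequence
#'
#' Scans ATG-initiated reading frames for the longest ORF. `peptide_len`
#' counts codons from the initial ATG up to but excluding the stop codon;
#' ORFs with no in-frame stop are counted open-ended to the sequence end.
#' Ties are broken by the smaller start offset. Stranded transcripts are
#' scanned on the sense strand only; with `strand = "."` both strands are
#' scanned and the longer ORF kept.
#'
#' @param seq A DNA sequence string (`A`,`C`,`G`,`T`,`N`).
#' @param strand `"+"` (sense only, the default for assembled stranded
#'   transcripts) or `"."` (both strands).
#' @return A one-row tibble (`frame`, `orf_strand`, `start_offset` 0-based,
#'   `peptide_len` in amino acids, `has_stop`).
#' @export
find_longest_orf <- function(seq, strand = "+") {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (nchar(seq) == 0) {
    return(tibble(
      frame = 0L, orf_strand = strand, start_offset = NA_integer_,
      peptide_len = 0L, has_stop = NA
    ))
  }
  fwd <- .orf_one_strand(seq)
  res <- fwd
  ostrand <- if (strand == ".") "+" else strand
  if (strand == ".") {
    rev <- .orf_one_strand(.revcomp(seq))
    if (rev$peptide_len > fwd$peptide_len) {
      res <- rev
      ostrand <- "-"
    }
  }
  tibble(
    frame = res$frame, orf_strand = ostrand, start_offset = res$start_offset,
    peptide_len = res$peptide_len, has_stop = res$has_stop
  )
}

.fickett_lookup <- function(value, breaks, probs) {
  idx <- which(value >= breaks)[1]
  probs[idx]
}

#' Fickett TESTCODE statistic
#'
#' Composition/position-asymmetry coding score from the published TESTCODE
#' lookup tables. For each base, the position parameter is
#' `max(n1,n2,n3)/(min(n1,n2,n3)+1)` over the three codon positions and the
#' content parameter is the base's overall fraction; both are mapped
#' through the lookup tables and combined with the published weights.
#'
#' @param seq A DNA sequence string of length at least 6.
#' @return The TESTCODE score (deterministic; higher is more coding-like).
#' @export
fickett_score <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 6) abort("fickett_score() needs a sequence of length >= 6")
  chars <- strsplit(seq, "")[[1]]
  pos <- (seq_len(n) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(chars == b & pos == p), numeric(1))
    posval <- max(cnt) / (min(cnt) + 1)
    content <- sum(cnt) / n
    score <- score +
      .fickett_lookup(posval, .fickett_position_breaks, .fickett_position_prob[[b]]) *
        .fickett_position_weight[[b]] +
      .fickett_lookup(content, .fickett_content_breaks, .fickett_content_prob[[b]]) *
        .fickett_content_weight[[b]]
  }
  unname(score)
}

#' All DNA hexamers
#'
#' @return Character vector of the 4096 hexamers in alphabetical order.
#' @export
all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  sort(do.call(paste0, expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)))
}

.inframe_hexamers <- function(seq) {
  n <- nchar(seq)
  if (n < 6) {
    return(character(0))
  }
  starts <- seq(1L, n - 5L, by = 3L)
  substring(seq, starts, starts + 5L)
}

#' Estimate a hexamer probability table from sequences
#'
#' Counts in-frame (step 3) hexamers over a set of sequences and normalizes
#' to a probability distribution over all 4096 hexamers, with one
#' pseudo-observation per hexamer. Hexamers containing `N` are skipped.
#'
#' @param seqs Character vector of DNA sequences.
#' @return Named numeric vector of 4096 probabilities summing to 1.
#' @export
hexamer_table <- function(seqs) {
  hx <- all_hexamers()
  counts <- stats::setNames(rep(1, length(hx)), hx) # one pseudo-observation each
  for (s in seqs) {
    h <- .inframe_hexamers(toupper(s))
    h <- h[!grepl("N", h, fixed = TRUE)]
    t <- table(h)
    counts[names(t)] <- counts[names(t)] + as.numeric(t)
  }
  counts / sum(counts)
}

.check_hexamer_table <- function(tab, what) {
  if (length(tab) != 4096 || is.null(names(tab))) {
    abort(paste0(what, " must be a named vector over the 4096 hexamers"))
  }
  if (abs(sum(tab) - 1) > 1e-9) {
    abort(paste0(what, " does not sum to 1 (within 1e-9)"))
  }
  invisible(tab)
}

#' Mean hexamer log-likelihood ratio (coding vs noncoding)
#'
#' Mean over sliding in-frame hexamers (step 3) of
#' `log(p_coding / p_noncoding)`, with pseudocount 1e-9 substituted for
#' zero probabilities. Sequences shorter than 6 nt score 0; identical
#' tables score 0 for any sequence.
#'
#' @param seq A DNA sequence string.
#' @param coding_table,noncoding_table Named probability vectors over the
#'   4096 hexamers, each summing to 1 within 1e-9.
#' @return The mean log-likelihood ratio.
#' @export
hexamer_llr <- function(seq, coding_table, noncoding_table) {
  .check_hexamer_table(coding_table, "coding_table")
  .check_hexamer_table(noncoding_table, "noncoding_table")
  h <- .inframe_hexamers(toupper(seq))
  h <- h[h %in% names(coding_table)]
  if (length(h) == 0) {
    return(0)
  }
  pc <- coding_table[h]
  pn <- noncoding_table[h]
  pc[pc == 0] <- 1e-9
  pn[pn == 0] <- 1e-9
  mean(log(pc / pn))
}

#' Compute coding-potential features for transcript sequences
#'
#' For each sequence: longest-ORF peptide length and coverage (ORF
#' nucleotides / transcript length), Fickett TESTCODE score, and mean
#' hexamer log-likelihood ratio against the supplied tables.
#'
#' @param seqs A tibble with `transcript_id` and `seq` columns (as from
#'   [read_fasta()]).
#' @param coding_table,noncoding_table Hexamer probability tables.
#' @return A tibble of features, one row per transcript.
#' @export
coding_features <- function(seqs, coding_table, noncoding_table) {
  orfs <- purrr::map(seqs$seq, find_longest_orf)
  tibble(
    transcript_id = seqs$transcript_id,
    peptide_len = purrr::map_int(orfs, "peptide_len"),
    orf_coverage = purrr::map_dbl(orfs, "peptide_len") * 3 / pmax(nchar(seqs$seq), 1),
    fickett = purrr::map_dbl(seqs$seq, fickett_score),
    hexamer = purrr::map_dbl(seqs$seq, hexamer_llr, coding_table, noncoding_table),
    orf_start = purrr::map_int(orfs, "start_offset"),
    orf_has_stop = purrr::map_lgl(orfs, "has_stop")
  )
}

#' Fit the logistic coding-potential combiner
#'
#' Maximum-likelihood logistic regression of a coding/noncoding label on
#' the four features (`peptide_len`, `orf_coverage`, `fickett`, `hexamer`),
#' fitted by iteratively reweighted least squares (100 iteration cap,
#' tolerance 1e-8). Under perfect separation, coefficients are capped at
#' +/-30 with a warning.
#'
#' @param features A tibble of [coding_features()] columns plus a `label`
#'   column (1/TRUE = coding).
#' @param coding_table,noncoding_table The hexamer tables the features were
#'   computed with (stored for scoring new sequences).
#' @return A `coding_model` object.
#' @export
train_coding_model <- function(features, coding_table, noncoding_table) {
  if (dplyr::n_distinct(as.integer(features$label)) < 2) {
    abort("need at least one example per class")
  }
  df <- tibble(
    label = as.integer(features$label),
    peptide_len = features$peptide_len,
    orf_coverage = features$orf_coverage,
    fickett = features$fickett,
    hexamer = features$hexamer
  )
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(label ~ peptide_len + orf_coverage + fickett + hexamer,
      family = stats::binomial(), data = df,
      control = stats::glm.control(epsilon = 1e-8, maxit = 100)
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
        conditionMessage(w)
      )) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0 # aliased/constant feature columns drop out of the fit
  if (all(abs(fit$fitted.values - df$label) < 1e-6)) separated <- TRUE
  capped <- abs(cf) > 30
  if (separated || any(capped)) {
    warn("perfectly separated training set: coefficients capped at +/-30")
  }
  cf[capped] <- sign(cf[capped]) * 30
  structure(
    list(
      coefficients = cf, fit = fit,
      coding_table = coding_table, noncoding_table = noncoding_table
    ),
    class = "coding_model"
  )
}

#' @export
print.coding_model <- function(x, ...) {
  cat("<coding_model> logistic combiner of (peptide_len, orf_coverage, fickett, hexamer)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Score coding probability of sequences with a fitted combiner
#'
#' @param seqs A tibble with `transcript_id` and `seq` columns.
#' @param model A `coding_model` from [train_coding_model()].
#' @return The [coding_features()] tibble with a `combined_prob` column
#'   (fitted logistic probability of being coding, in `[0, 1]`).
#' @export
score_coding_potential <- function(seqs, model) {
  feats <- coding_features(seqs, model$coding_table, model$noncoding_table)
  eta <- model$coefficients[1] +
    model$coefficients["peptide_len"] * feats$peptide_len +
    model$coefficients["orf_coverage"] * feats$orf_coverage +
    model$coefficients["fickett"] * feats$fickett +
    model$coefficients["hexamer"] * feats$hexamer
  feats$combined_prob <- as.numeric(stats::plogis(eta))
  feats
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' @param path Path to a 12-column tab-separated BLAST output file.
#' @return A tibble (`transcript_id`, `min_evalue`): minimum e-value per
#'   query id. Empty files give an empty tibble.
#' @export
read_blast_tab <- function(path) {
  cols <- c(
    "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0) {
    return(tibble(transcript_id = character(), min_evalue = numeric()))
  }
  df <- readr::read_tsv(path,
    col_names = cols, show_col_types = FALSE,
    col_types = readr::cols(
      qseqid = "c", sseqid = "c", evalue = "d", .default = readr::col_guess()
    )
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0("BLAST tabular parse error at line ", probs$row[1], " of ", path))
  }
  if (anyNA(df$evalue)) {
    abort(paste0(
      "non-numeric e-value at line ", which(is.na(df$evalue))[1], " of ", path
    ))
  }
  df %>%
    group_by(transcript_id = .data$qseqid) %>%
    summarise(min_evalue = min(.data$evalue), .groups = "drop")
}

#' Read a two-column external score table (CNCI- or CPAT-style)
#'
#' @param path Path to a TSV with header columns id and score (names free).
#' @param score_name Name for the score column in the result.
#' @return A tibble (`transcript_id`, `<score_name>`).
#' @export
read_score_table <- function(path, score_name = "score") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(df) < 2) abort("score table needs two columns: id, score")
  out <- tibble(transcript_id = as.character(df[[1]]), score = as.numeric(df[[2]]))
  names(out)[2] <- score_name
  out
}

#' Default coding-gate thresholds
#'
#' CNCI score below 0, CPAT (or built-in combined) probability below 0.5,
#' protein-homology e-value at or above 1e-5, and longest-ORF peptide under
#' 100 amino acids are all required to call a transcript noncoding.
#'
#' @return A named list of thresholds.
#' @export
default_gate_thresholds <- function() {
  list(cnci = 0, cpat = 0.5, evalue = 1e-5, peptide = 100)
}

#' Apply the coding-evidence gate
#'
#' A transcript is retained as noncoding only if every *available* line of
#' coding evidence falls below its threshold: `cnci_score < cnci` (when
#' present), `cpat_score < cpat` (or `combined_prob < cpat` when no
#' external CPAT score is present), no homology hit with
#' `min_evalue < evalue`, and `peptide_len < peptide`. Absent evidence is
#' skipped. Increasing any piece of coding evidence can only flip
#' retain -> discard, never the reverse.
#'
#' @param cp A tibble with `transcript_id`, `peptide_len` and any of
#'   `cnci_score`, `cpat_score`, `combined_prob`, `min_evalue`.
#' @param thresholds Named list as [default_gate_thresholds()].
#' @return `cp` with logical `retain` and character `gate_reason`
#'   (`"noncoding"` or the first failed criterion).
#' @export
coding_gate <- function(cp, thresholds = default_gate_thresholds()) {
  get_col <- function(nm) {
    if (nm %in% names(cp)) cp[[nm]] else rep(NA_real_, nrow(cp))
  }
  cnci <- get_col("cnci_score")
  cpat <- get_col("cpat_score")
  comb <- get_col("combined_prob")
  ev <- get_col("min_evalue")
  pep <- get_col("peptide_len")
  if (all(is.na(pep))) abort("coding_gate() needs a peptide_len column")
  prob <- ifelse(is.na(cpat), comb, cpat)
  fail_cnci <- !is.na(cnci) & cnci >= thresholds$cnci
  fail_cpat <- !is.na(prob) & prob >= thresholds$cpat
  fail_ev <- !is.na(ev) & ev < thresholds$evalue
  fail_pep <- !is.na(pep) & pep >= thresholds$peptide
  reason <- dplyr::case_when(
    fail_pep ~ "orf_peptide",
    fail_cnci ~ "cnci",
    fail_cpat ~ "cpat",
    fail_ev ~ "homology",
    TRUE ~ "noncoding"
  )
  cp %>% mutate(
    retain = !(fail_cnci | fail_cpat | fail_ev | fail_pep),
    gate_reason = reason
  )
}
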