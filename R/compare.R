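#' Transcript class codes
#'
#' Codes summarizing how a query transcript relates to a reference
#' transcript's exon/intron structure, ordered most-specific first. This
#' precedence resolves multi-match ties when a query intersects several
#' reference transcripts.
#'
#' @format Character vector of codes: `=` identical intron chain, `c`
#'   contained, `j` shared splice junction (novel isoform), `e` single-exon
#'   exonic overlap, `o` generic exonic overlap, `i` intronic, `x`
#'   opposite-strand exonic overlap, `u` intergenic.
#' @export
CLASS_CODE_PRECEDENCE <- c("=", "c", "j", "e", "o", "i", "x", "u")

# Rank helper: smaller is more specific
.code_rank <- function(code) match(code, CLASS_CODE_PRECEDENCE)

# Exon chains are 2-column integer matrices (start, end), sorted by start.
.chain_introns <- function(ex) {
  if (nrow(ex) < 2) {
    return(matrix(integer(0), ncol = 2))
  }
  cbind(ex[-nrow(ex), 2] + 1L, ex[-1, 1] - 1L)
}

.any_exon_overlap <- function(a, b) {
  for (i in seq_len(nrow(a))) {
    if (any(a[i, 1] <= b[, 2] & b[, 1] <= a[i, 2])) {
      return(TRUE)
    }
  }
  FALSE
}

.same_chain <- function(a, b) {
  nrow(a) == nrow(b) && (nrow(a) == 0 || all(a == b))
}

# Is chain `a` a contiguous sub-chain of `b`? Empty chains qualify.
.contiguous_subchain <- function(a, b) {
  if (nrow(a) == 0) {
    return(TRUE)
  }
  if (nrow(a) > nrow(b)) {
    return(FALSE)
  }
  key_a <- paste(a[, 1], a[, 2])
  key_b <- paste(b[, 1], b[, 2])
  first <- match(key_a[1], key_b)
  if (is.na(first)) {
    return(FALSE)
  }
  idx <- first:(first + length(key_a) - 1)
  if (max(idx) > length(key_b)) {
    return(FALSE)
  }
  all(key_a == key_b[idx])
}

.exons_contained <- function(q, r) {
  all(vapply(
    seq_len(nrow(q)),
    function(i) any(r[, 1] <= q[i, 1] & q[i, 2] <= r[, 2]),
    logical(1)
  ))
}

.shares_junction <- function(qi, ri) {
  if (nrow(qi) == 0 || nrow(ri) == 0) {
    return(FALSE)
  }
  any(paste(qi[, 1], qi[, 2]) %in% paste(ri[, 1], ri[, 2]))
}

.span_in_one_intron <- function(q, ri) {
  if (nrow(ri) == 0) {
    return(FALSE)
  }
  qs <- min(q[, 1])
  qe <- max(q[, 2])
  any(ri[, 1] <= qs & qe <= ri[, 2])
}

# Code of one query/reference transcript pair whose spans intersect.
# `same_strand` treats an unstranded party as matching.
.pair_code <- function(qex, qstrand, rex, rstrand) {
  qs <- min(qex[, 1])
  qe <- max(qex[, 2])
  rs <- min(rex[, 1])
  re <- max(rex[, 2])
  if (qe < rs || re < qs) {
    return(NA_character_)
  }
  qi <- .chain_introns(qex)
  ri <- .chain_introns(rex)
  same_strand <- qstrand == "." || rstrand == "." || qstrand == rstrand
  exonic <- .any_exon_overlap(qex, rex)
  if (same_strand) {
    if (.same_chain(qi, ri) && exonic) {
      return("=")
    }
    if (exonic && .exons_contained(qex, rex) && .contiguous_subchain(qi, ri)) {
      return("c")
    }
    if (.shares_junction(qi, ri)) {
      return("j")
    }
    if (exonic) {
      return(if (nrow(qex) == 1) "e" else "o")
    }
    if (.span_in_one_intron(qex, ri)) {
      return("i")
    }
    # residual: query straddles the reference without touching an exon
    return("o")
  }
  if (exonic) {
    return("x")
  }
  if (.span_in_one_intron(qex, ri)) {
    return("i")
  }
  "x"
}

.split_exon_mats <- function(ann) {
  tx_ids <- unique(ann$transcript_id)
  ord <- order(ann$transcript_id, ann$start)
  a <- ann[ord, ]
  lapply(
    split(seq_len(nrow(a)), a$transcript_id),
    function(ix) cbind(a$start[ix], a$end[ix])
  )
}

#' Assign class codes to query transcripts against a reference annotation
#'
#' Each query transcript receives exactly one code, chosen by the precedence
#' `=` > `c` > `j` > `e` > `o` > `i` > `x` > `u` over all reference
#' transcripts whose spans intersect the query span (`u` when none do, or
#' when the query chromosome is absent from the reference). Unstranded
#' queries (`.`) are compared against both strands and keep the most
#' specific interpretation. Codes `u` and `i` carry no `ref_id`; for `i`
#' the `strand_relation` column records whether the enclosing intron is on
#' the same or opposite strand.
#'
#' @param query,reference Annotation tibbles (see [validate_annotation()]).
#' @param biotypes Optional character vector: restrict the reference to
#'   these biotypes before comparison (e.g. `c("protein_coding",
#'   "other_ncRNA")` for the lncRNA removal step).
#' @return A tibble (`transcript_id`, `class_code`, `ref_id`,
#'   `strand_relation`), one row per query transcript, with a per-code
#'   count table in attribute `"code_counts"`.
#' @export
compare_transcripts <- function(query, reference, biotypes = NULL) {
  validate_annotation(query)
  validate_annotation(reference)
  if (!is.null(biotypes)) {
    reference <- filter(reference, .data$biotype %in% biotypes)
  }
  qtx <- transcript_table(query)
  if (nrow(qtx) == 0) {
    out <- tibble(
      transcript_id = character(), class_code = character(),
      ref_id = character(), strand_relation = character()
    )
    attr(out, "code_counts") <- count(out, .data$class_code)
    return(out)
  }
  rtx <- transcript_table(reference)
  qmats <- .split_exon_mats(query)
  rmats <- .split_exon_mats(reference)

  known_chrom <- unique(rtx$chrom)
  unknown <- setdiff(unique(qtx$chrom), known_chrom)
  if (length(unknown) > 0) {
    warn(paste0(
      "query chromosome(s) absent from reference, coded 'u': ",
      paste(unknown, collapse = ", ")
    ))
  }

  if (nrow(rtx) > 0) {
    hits <- GenomicRanges::findOverlaps(.tx_granges(qtx), .tx_granges(rtx),
      ignore.strand = TRUE
    )
    cand <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  } else {
    cand <- list()
  }

  n <- nrow(qtx)
  code <- rep("u", n)
  ref_id <- rep(NA_character_, n)
  strand_rel <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    js <- cand[[as.character(i)]]
    if (is.null(js)) next
    qex <- qmats[[qtx$transcript_id[i]]]
    if (is.null(qex) || nrow(qex) == 0) abort("query transcript with zero exons")
    best_rank <- .code_rank("u")
    best_ref <- NA_character_
    best_rel <- NA_character_
    for (j in js) {
      rex <- rmats[[rtx$transcript_id[j]]]
      cd <- .pair_code(qex, qtx$strand[i], rex, rtx$strand[j])
      if (is.na(cd)) next
      rk <- .code_rank(cd)
      rid <- rtx$transcript_id[j]
      if (rk < best_rank || (rk == best_rank && !is.na(best_ref) && rid < best_ref)) {
        best_rank <- rk
        best_ref <- rid
        best_rel <- if (qtx$strand[i] == "." || rtx$strand[j] == "." ||
          qtx$strand[i] == rtx$strand[j]) {
          "same"
        } else {
          "opposite"
        }
      }
    }
    if (best_rank < .code_rank("u")) {
      code[i] <- CLASS_CODE_PRECEDENCE[best_rank]
      ref_id[i] <- best_ref
      strand_rel[i] <- best_rel
    }
  }
  ref_id[code %in% c("u", "i")] <- NA_character_
  strand_rel[code == "u"] <- NA_character_
  out <- tibble(
    transcript_id = qtx$transcript_id, class_code = code,
    ref_id = ref_id, strand_relation = strand_rel
  )
  attr(out, "code_counts") <- count(out, .data$class_code)
  out
}

#' Class code of a single transcript
#'
#' Convenience wrapper around [compare_transcripts()] for one query
#' transcript.
#'
#' @param query An annotation tibble containing exactly one transcript.
#' @param reference A reference annotation tibble.
#' @return A one-row class-code tibble.
#' @export
assign_class_code <- function(query, reference) {
  if (dplyr::n_distinct(query$transcript_id) != 1) {
    abort("assign_class_code() expects exactly one query transcript")
  }
  compare_transcripts(query, reference)
}
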