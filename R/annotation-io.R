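#' @importFrom rlang .data %||% abort warn
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

ANN_COLS <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id", "biotype")
BIOTYPES <- c("protein_coding", "known_lncRNA", "other_ncRNA", "unknown")

#' Validate an exon-level annotation tibble
#'
#' An annotation is a plain tibble with one row per exon and columns
#' `chrom`, `start`, `end` (1-based inclusive), `strand` (`+`, `-` or `.`),
#' `gene_id`, `transcript_id` and `biotype` (one of `protein_coding`,
#' `known_lncRNA`, `other_ncRNA`, `unknown`). All package functions that
#' take an annotation expect this shape.
#'
#' @param ann A data frame of exon records.
#' @return The input, invisibly, after checks.
#' @export
validate_annotation <- function(ann) {
  missing <- setdiff(ANN_COLS, names(ann))
  if (length(missing) > 0) {
    abort(paste0("annotation is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(ann$start > ann$end)) abort("exon start > end")
  if (any(ann$start < 1)) abort("exon start < 1")
  if (!all(ann$strand %in% c("+", "-", "."))) abort("strand must be one of '+', '-', '.'")
  bad <- setdiff(unique(ann$biotype), BIOTYPES)
  if (length(bad) > 0) abort(paste0("unknown biotype: ", paste(bad, collapse = ", ")))
  invisible(ann)
}

.normalize_exons <- function(ann) {
  if (nrow(ann) == 0) {
    return(as_tibble(ann[ANN_COLS]))
  }
  # merge overlapping/adjacent exons within a transcript, sort
  ann <- ann %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(.grp = cumsum(.data$start > cummax(dplyr::lag(.data$end, default = -1L) + 1L))) %>%
    group_by(.data$transcript_id, .grp = .data$.grp) %>%
    summarise(
      chrom = dplyr::first(.data$chrom), start = min(.data$start), end = max(.data$end),
      strand = dplyr::first(.data$strand), gene_id = dplyr::first(.data$gene_id),
      biotype = dplyr::first(.data$biotype), .groups = "drop"
    ) %>%
    select(dplyr::all_of(ANN_COLS)) %>%
    arrange(.data$chrom, .data$gene_id, .data$transcript_id, .data$start)
  ann
}

.map_biotype <- function(x) {
  x <- tolower(as.character(x %||% "unknown"))
  dplyr::case_when(
    x == "protein_coding" ~ "protein_coding",
    x %in% c("known_lncrna", "lncrna", "lincrna", "antisense") ~ "known_lncRNA",
    x %in% c(
      "other_ncrna", "trna", "rrna", "snrna", "snorna", "mirna",
      "misc_rna", "scarna", "srna"
    ) ~ "other_ncRNA",
    TRUE ~ "unknown"
  )
}

#' Read transcript models from a GTF file
#'
#' Parses a 9-column GTF (Ensembl dialect) into an exon-level annotation
#' tibble. Coordinates are kept 1-based inclusive; exons are merged and
#' sorted per transcript; biotype is resolved from the
#' `gene_biotype`/`transcript_biotype` attributes when `dialect = "ensembl"`
#' and left `"unknown"` otherwise.
#'
#' @param path Path to a GTF file.
#' @param dialect `"ensembl"` (parse biotype attributes) or `"generic"`.
#' @return An annotation tibble (see [validate_annotation()]).
#' @export
read_gtf <- function(path, dialect = c("ensembl", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) abort(paste0("GTF parse error in ", path, ": ", conditionMessage(e)))
  )
  if (length(gr) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(), strand = character(),
      gene_id = character(), transcript_id = character(), biotype = character()
    ))
  }
  mc <- S4Vectors::mcols(gr)
  keep <- !is.na(mc$type) & as.character(mc$type) == "exon"
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  tid <- as.character(mc$transcript_id %||% rep(NA_character_, length(gr)))
  if (anyNA(tid)) {
    warn(paste0(sum(is.na(tid)), " exon record(s) without transcript_id rejected"))
    gr <- gr[!is.na(tid)]
    mc <- S4Vectors::mcols(gr)
    tid <- as.character(mc$transcript_id)
  }
  bio <- rep("unknown", length(gr))
  if (dialect == "ensembl") {
    raw <- as.character(mc$transcript_biotype %||% rep(NA_character_, length(gr)))
    raw2 <- as.character(mc$gene_biotype %||% rep(NA_character_, length(gr)))
    raw[is.na(raw)] <- raw2[is.na(raw)]
    bio <- .map_biotype(raw)
  }
  ann <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    gene_id = as.character(mc$gene_id %||% tid),
    transcript_id = tid,
    biotype = bio
  )
  validate_annotation(.normalize_exons(ann))
}

#' Write an annotation to a GTF file
#'
#' Emits one `transcript` row and its `exon` rows per transcript, with
#' `gene_id`, `transcript_id` and `gene_biotype` attributes, so that
#' `read_gtf(write_gtf(ann, path))` recovers `ann` on all modeled fields.
#' Output bytes are deterministic (no timestamp headers).
#'
#' @param ann An annotation tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  validate_annotation(ann)
  ann <- .normalize_exons(ann)
  if (nrow(ann) == 0) {
    writeLines("##gff-version 2", path)
    return(invisible(path))
  }
  tx <- transcript_table(ann)
  mk <- function(chrom, start, end, strand, type, gid, tid, bio) {
    GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start, end),
      strand = sub("^\\.$", "*", strand),
      type = type, gene_id = gid, transcript_id = tid, gene_biotype = bio
    )
  }
  gr_tx <- mk(tx$chrom, tx$tx_start, tx$tx_end, tx$strand, "transcript", tx$gene_id, tx$transcript_id, tx$biotype)
  gr_ex <- mk(ann$chrom, ann$start, ann$end, ann$strand, "exon", ann$gene_id, ann$transcript_id, ann$biotype)
  gr <- c(gr_tx, gr_ex)
  ord <- order(
    as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr),
    S4Vectors::mcols(gr)$transcript_id, S4Vectors::mcols(gr)$type != "transcript"
  )
  gr <- gr[ord]
  tryCatch(
    rtracklayer::export(gr, path, format = "gtf"),
    error = function(e) abort(paste0("cannot write GTF to ", path, ": ", conditionMessage(e)))
  )
  # drop volatile comment headers (tool version, date) for byte-stable output
  lines <- readLines(path)
  lines <- lines[!grepl("^##(source-version|date)", lines)]
  writeLines(lines, path)
  invisible(path)
}

#' Per-transcript summary of an annotation
#'
#' @param ann An annotation tibble.
#' @return A tibble with one row per transcript: span, exon count, spliced
#'   length (sum of exon widths).
#' @export
transcript_table <- function(ann) {
  validate_annotation(ann)
  if (nrow(ann) == 0) {
    return(tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), tx_start = integer(), tx_end = integer(),
      n_exons = integer(), tx_length = integer(), biotype = character()
    ))
  }
  ann %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = dplyr::first(.data$gene_id),
      chrom = dplyr::first(.data$chrom),
      strand = dplyr::first(.data$strand),
      tx_start = min(.data$start),
      tx_end = max(.data$end),
      n_exons = dplyr::n(),
      tx_length = sum(.data$end - .data$start + 1L),
      biotype = dplyr::first(.data$biotype),
      .groups = "drop"
    ) %>%
    arrange(.data$chrom, .data$tx_start, .data$transcript_id)
}

#' Intron table of an annotation
#'
#' Gaps between consecutive exons of each transcript, 1-based inclusive.
#'
#' @param ann An annotation tibble.
#' @return A tibble (`transcript_id`, `chrom`, `strand`, `intron_start`,
#'   `intron_end`).
#' @export
intron_table <- function(ann) {
  validate_annotation(ann)
  ann %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    reframe(
      chrom = dplyr::first(.data$chrom),
      strand = dplyr::first(.data$strand),
      intron_start = .data$end[-dplyr::n()] + 1L,
      intron_end = .data$start[-1L] - 1L
    ) %>%
    filter(.data$intron_start <= .data$intron_end)
}

#' Gene-span table of an annotation
#'
#' @param ann An annotation tibble.
#' @return One row per gene with its covering span and strand.
#' @export
gene_table <- function(ann) {
  validate_annotation(ann)
  ann %>%
    group_by(.data$gene_id) %>%
    summarise(
      chrom = dplyr::first(.data$chrom), strand = dplyr::first(.data$strand),
      gene_start = min(.data$start), gene_end = max(.data$end),
      n_transcripts = dplyr::n_distinct(.data$transcript_id),
      biotype = dplyr::first(.data$biotype), .groups = "drop"
    ) %>%
    arrange(.data$chrom, .data$gene_start, .data$gene_id)
}

.tx_granges <- function(tx) {
  GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$tx_start, tx$tx_end),
    strand = sub("^\\.$", "*", tx$strand),
    transcript_id = tx$transcript_id, gene_id = tx$gene_id
  )
}

.gene_granges <- function(gt) {
  GenomicRanges::GRanges(
    gt$chrom, IRanges::IRanges(gt$gene_start, gt$gene_end),
    strand = sub("^\\.$", "*", gt$strand), gene_id = gt$gene_id
  )
}

#' Genes whose spans intersect a query interval
#'
#' Interval-indexed span query (GenomicRanges backed); chromosome names are
#' compared by exact string match.
#'
#' @param ann An annotation tibble.
#' @param chrom,start,end Query interval, 1-based inclusive.
#' @return Character vector of gene ids, sorted.
#' @export
overlapping_genes <- function(ann, chrom, start, end) {
  gt <- gene_table(ann)
  gr <- .gene_granges(gt)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
  sort(unique(gt$gene_id[S4Vectors::subjectHits(hits)]))
}

#' Read transcript sequences from a FASTA file
#'
#' @param path Path to a FASTA file of transcript sequences.
#' @return A tibble (`transcript_id`, `seq`, `length`); sequences are
#'   uppercased and restricted to the `A`,`C`,`G`,`T`,`N` alphabet.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][1]))
  }
  seqs <- unname(toupper(as.character(ss)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("non-DNA symbol in FASTA record ", ids[bad][1]))
  }
  tibble(transcript_id = unname(ids), seq = seqs, length = nchar(seqs))
}

#' Write transcript sequences to a FASTA file
#'
#' @param seqs A tibble with `transcript_id` and `seq` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs$seq)
  names(ss) <- seqs$transcript_id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Export gene or transcript spans as BED6
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param ann An annotation tibble.
#' @param path Output path.
#' @param level `"transcript"` or `"gene"`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ann, path, level = c("transcript", "gene")) {
  level <- match.arg(level)
  if (level == "transcript") {
    tx <- transcript_table(ann)
    df <- tibble(
      chrom = tx$chrom, start = tx$tx_start - 1L, end = tx$tx_end,
      name = tx$transcript_id, score = 0L, strand = tx$strand
    )
  } else {
    gt <- gene_table(ann)
    df <- tibble(
      chrom = gt$chrom, start = gt$gene_start - 1L, end = gt$gene_end,
      name = gt$gene_id, score = 0L, strand = gt$strand
    )
  }
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
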