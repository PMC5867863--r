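# Independent brute-force oracles, written directly from the definitions
# with no shared code paths with the package internals.

# --- class-code oracle -----------------------------------------------------

# introns of an exon matrix (start,end rows sorted by start)
oracle_introns <- function(ex) {
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  if (nrow(ex) < 2) {
    return(data.frame(s = integer(0), e = integer(0)))
  }
  data.frame(s = ex[-nrow(ex), 2] + 1, e = ex[-1, 1] - 1)
}

oracle_exon_overlap <- function(a, b) {
  hit <- FALSE
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a[i, 1] <= b[j, 2] && b[j, 1] <= a[i, 2]) hit <- TRUE
    }
  }
  hit
}

# exhaustive test of every definition for one query/reference pair
oracle_pair_code <- function(qex, qstrand, rex, rstrand) {
  qspan <- range(qex)
  rspan <- range(rex)
  if (qspan[2] < rspan[1] || rspan[2] < qspan[1]) {
    return(NA_character_)
  }
  qi <- oracle_introns(qex)
  ri <- oracle_introns(rex)
  same <- qstrand == "." || rstrand == "." || qstrand == rstrand
  exonic <- oracle_exon_overlap(qex, rex)
  in_one_intron <- FALSE
  for (j in seq_len(nrow(ri))) {
    if (ri$s[j] <= qspan[1] && qspan[2] <= ri$e[j]) in_one_intron <- TRUE
  }
  if (same) {
    chains_equal <- nrow(qi) == nrow(ri) &&
      (nrow(qi) == 0 || all(qi$s == ri$s & qi$e == ri$e))
    if (chains_equal && exonic) {
      return("=")
    }
    contained <- TRUE
    for (i in seq_len(nrow(qex))) {
      inside <- FALSE
      for (j in seq_len(nrow(rex))) {
        if (rex[j, 1] <= qex[i, 1] && qex[i, 2] <= rex[j, 2]) inside <- TRUE
      }
      if (!inside) contained <- FALSE
    }
    subchain <- FALSE
    if (nrow(qi) == 0) {
      subchain <- TRUE
    } else if (nrow(qi) <= nrow(ri)) {
      for (off in 0:(nrow(ri) - nrow(qi))) {
        idx <- seq_len(nrow(qi)) + off
        if (all(qi$s == ri$s[idx] & qi$e == ri$e[idx])) subchain <- TRUE
      }
    }
    if (exonic && contained && subchain) {
      return("c")
    }
    shared <- FALSE
    for (i in seq_len(nrow(qi))) {
      for (j in seq_len(nrow(ri))) {
        if (qi$s[i] == ri$s[j] && qi$e[i] == ri$e[j]) shared <- TRUE
      }
    }
    if (shared) {
      return("j")
    }
    if (exonic) {
      return(if (nrow(qex) == 1) "e" else "o")
    }
    if (in_one_intron) {
      return("i")
    }
    return("o")
  }
  if (exonic) {
    return("x")
  }
  if (in_one_intron) {
    return("i")
  }
  "x"
}

# full oracle over a set of reference transcripts, with the precedence
oracle_class_code <- function(qex, qstrand, refs) {
  prec <- c("=", "c", "j", "e", "o", "i", "x", "u")
  codes_seen <- character(0)
  for (r in refs) {
    cd <- oracle_pair_code(qex, qstrand, r$ex, r$strand)
    if (!is.na(cd)) codes_seen <- c(codes_seen, cd)
  }
  if (length(codes_seen) == 0) {
    return("u")
  }
  prec[min(match(codes_seen, prec))]
}

# --- ORF oracle ------------------------------------------------------------

oracle_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best_len <- 0L
  best_off <- NA_integer_
  for (start in seq_len(max(n - 2, 0))) {
    if (substr(seq, start, start + 2) != "ATG") next
    len <- 0L
    pos <- start
    stopped <- FALSE
    while (pos + 2 <= n) {
      cod <- substr(seq, pos, pos + 2)
      if (len > 0 && cod %in% c("TAA", "TAG", "TGA")) {
        stopped <- TRUE
        break
      }
      len <- len + 1L
      pos <- pos + 3L
    }
    if (len > best_len || (len == best_len && len > 0 && (start - 1L) < best_off)) {
      best_len <- len
      best_off <- start - 1L
    }
  }
  list(peptide_len = best_len, start_offset = best_off)
}

# --- BH oracle -------------------------------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (k in seq_len(m)) {
    q[k] <- min(1, min(ps[k:m] * m / (k:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# --- hypergeometric upper-tail oracle (exact enumeration) ------------------

oracle_hyper <- function(N, K, n, k) {
  tot <- choose(N, n)
  s <- 0
  for (j in seq(k, min(K, n))) {
    s <- s + choose(K, j) * choose(N - K, n - j)
  }
  s / tot
}

# --- candidate-pair windowing oracle ---------------------------------------

oracle_cis_pairs <- function(lnc_spans, gene_spans, window) {
  out <- list()
  for (i in seq_len(nrow(lnc_spans))) {
    for (j in seq_len(nrow(gene_spans))) {
      if (lnc_spans$chrom[i] != gene_spans$chrom[j]) next
      ws <- lnc_spans$start[i] - window
      we <- lnc_spans$end[i] + window
      if (gene_spans$start[j] <= we && ws <= gene_spans$end[j]) {
        if (gene_spans$start[j] > lnc_spans$end[i]) {
          d <- gene_spans$start[j] - lnc_spans$end[i] - 1L
        } else if (lnc_spans$start[i] > gene_spans$end[j]) {
          d <- lnc_spans$start[i] - gene_spans$end[j] - 1L
        } else {
          d <- 0L
        }
        out[[length(out) + 1L]] <- data.frame(
          lncrna_id = lnc_spans$id[i], gene_id = gene_spans$id[j], distance_bp = d
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      lncrna_id = character(0), gene_id = character(0),
      distance_bp = integer(0)
    ))
  }
  do.call(rbind, out)
}

# --- positional-class rule oracle ------------------------------------------

oracle_positional <- function(lnc, genes, gene_exons) {
  # lnc: list(ex = exon matrix, strand); genes: data.frame on one chromosome
  if (nrow(genes) == 0) {
    return("intergenic_same")
  }
  lnc$start <- min(lnc$ex[, 1])
  lnc$end <- max(lnc$ex[, 2])
  same <- function(gs) lnc$strand == "." || gs == lnc$strand
  ov <- which(genes$start <= lnc$end & lnc$start <= genes$end)
  for (i in ov) {
    gex <- gene_exons[[genes$id[i]]]
    for (j in seq_len(nrow(gex))) {
      for (k in seq_len(nrow(lnc$ex))) {
        if (gex[j, 1] <= lnc$ex[k, 2] && lnc$ex[k, 1] <= gex[j, 2]) {
          return(if (same(genes$strand[i])) "sense_exonic" else "antisense_exonic")
        }
      }
    }
  }
  for (i in ov) {
    if (lnc$start <= genes$start[i] && genes$end[i] <= lnc$end) {
      return("containing_gene")
    }
  }
  for (i in ov) {
    if (genes$start[i] <= lnc$start && lnc$end <= genes$end[i]) {
      return(if (same(genes$strand[i])) "sense_intronic" else "antisense_intronic")
    }
  }
  if (length(ov) > 0) {
    return(if (same(genes$strand[ov[1]])) "sense_intronic" else "antisense_intronic")
  }
  gaps <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gaps[i] <- if (genes$start[i] > lnc$end) {
      genes$start[i] - lnc$end - 1L
    } else {
      lnc$start - genes$end[i] - 1L
    }
  }
  i <- which.min(gaps)
  gap <- gaps[i]
  left <- lnc$end < genes$start[i]
  on5 <- if (genes$strand[i] == "-") !left else left
  opp <- !(lnc$strand == "." || genes$strand[i] == "." || lnc$strand == genes$strand[i])
  if (gap <= 1000L) {
    if (opp && on5 && gap < 1000L) {
      return("bidirectional_promoter")
    }
    return(if (on5) "upstream_proximal" else "downstream_proximal")
  }
  if (!opp) {
    return("intergenic_same")
  }
  if (on5) "intergenic_divergent" else "intergenic_convergent"
}
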