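# Independent brute-force oracles. Deliberately naive implementations,
# sharing no code with the package paths they check.

# all-pairs opposite-strand span overlap, O(n^2) via outer products
oracle_pairs <- function(df, min_overlap = 50) {
  n <- nrow(df)
  ov <- pmin(outer(df$end, rep(1, n)), outer(rep(1, n), df$end)) -
    pmax(outer(df$start, rep(1, n)), outer(rep(1, n), df$start)) + 1
  keep <- ov >= min_overlap &
    outer(df$chrom, df$chrom, "==") &
    outer(df$strand, df$strand, "!=")
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  key <- apply(cbind(df$transcript_id[idx[, 1]], df$transcript_id[idx[, 2]]),
               1, function(x) paste(sort(x), collapse = "|"))
  sort(key)
}

# per-read containment scan for precursor support
oracle_precursors <- function(pairs, reads_df, min_reads = 1,
                              sirna_len = c(20, 24)) {
  vapply(seq_len(nrow(pairs)), function(i) {
    sup <- reads_df$chrom == pairs$chrom[i] &
      reads_df$len >= sirna_len[1] & reads_df$len <= sirna_len[2] &
      reads_df$start >= pairs$overlap_start[i] &
      reads_df$end <= pairs$overlap_end[i]
    sum(sup)
  }, numeric(1))
}

# sliding-window HSE matcher with explicit per-window checks
oracle_hse <- function(s) {
  s <- toupper(s)
  pats <- list(
    canonical_double = list(w = 10, g = 2, a = c(3, 4), c = 9, t = c(7, 8)),
    canonical_triple = list(w = 15, g = c(2, 12), a = list(c(3, 4), c(13, 14)),
                            c = 9, t = list(c(7, 8))),
    non_canonical = list(w = 12, g = 2, a = c(3, 4), c = 11, t = c(9, 10)))
  check_units <- function(ch, pat) {
    mism <- 0
    gs <- pat$g
    as_ <- if (is.list(pat$a)) pat$a else list(pat$a)
    for (ui in seq_along(gs)) {
      if (ch[gs[ui]] != "G") return(NA)
      um <- sum(ch[as_[[ui]]] != "A")
      if (um > 1) return(NA)
      mism <- mism + um
    }
    cs <- pat$c
    ts_ <- if (is.list(pat$t)) pat$t else list(pat$t)
    for (ui in seq_along(cs)) {
      if (ch[cs[ui]] != "C") return(NA)
      um <- sum(ch[ts_[[ui]]] != "T")
      if (um > 1) return(NA)
      mism <- mism + um
    }
    mism
  }
  revcomp <- function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }
  scan1 <- function(seqstr, strand_label, L) {
    ch_all <- strsplit(seqstr, "")[[1]]
    out <- list()
    for (kind in names(pats)) {
      p <- pats[[kind]]
      if (nchar(seqstr) < p$w) next
      for (i in seq_len(nchar(seqstr) - p$w + 1)) {
        m <- check_units(ch_all[i:(i + p$w - 1)], p)
        if (!is.na(m)) {
          st <- if (strand_label == "+") i else L - (i + p$w - 1) + 1
          out[[length(out) + 1L]] <- data.frame(
            start = st, end = st + p$w - 1, strand = strand_label,
            kind = kind, n_mismatches = m)
        }
      }
    }
    do.call(rbind, c(out, list(data.frame(start = integer(), end = integer(),
                                          strand = character(),
                                          kind = character(),
                                          n_mismatches = integer()))))
  }
  L <- nchar(s)
  hits <- rbind(scan1(s, "+", L), scan1(revcomp(s), "-", L))
  # collapse duplicate intervals of the same kind (best mismatch count)
  hits <- hits[order(hits$start, hits$end, hits$kind, hits$n_mismatches,
                     hits$strand), ]
  hits <- hits[!duplicated(hits[, c("start", "end", "kind")]), ]
  # triples suppress contained doubles
  tri <- hits[hits$kind == "canonical_triple", ]
  if (nrow(tri) > 0) {
    drop <- hits$kind == "canonical_double" &
      vapply(seq_len(nrow(hits)), function(i) {
        any(hits$start[i] >= tri$start & hits$end[i] <= tri$end)
      }, logical(1))
    hits <- hits[!drop, ]
  }
  rownames(hits) <- NULL
  hits
}
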