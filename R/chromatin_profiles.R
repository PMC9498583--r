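# Chromatin context of NAT genes: histone-mark association and TSS
# metaprofiles, methylation context/temporal summaries, and promoter
# scanning for heat-shock elements (HSE).

#' Histone-peak association with TSS windows by gene class
#'
#' Per mark and per class, the fraction of genes with at least one peak
#' overlapping (any bp) the clipped `[TSS - window, TSS + window]` region.
#'
#' @param peaks named list of `GRanges`, one element per histone mark.
#' @param annotation a [nat_annotation()].
#' @param classes named list mapping class name to transcript ids.
#' @param window half-width in bp (default 1000).
#' @param marks admissible mark names; entries of `peaks` outside this set
#'   raise a configuration error. `NULL` disables the check.
#' @return tibble `mark`, `class`, `n_genes`, `n_associated`, `fraction`.
#' @export
peak_association <- function(peaks, annotation, classes, window = 1000,
                             marks = c("H3K27me2", "H3K27me3", "H3K36me2",
                                       "H3K4me1", "H3K4me2", "H3K4me3")) {
  if (!is.null(marks)) {
    bad <- setdiff(names(peaks), marks)
    if (length(bad) > 0) {
      stop("config error: unknown mark name(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  tx <- annotation$transcripts
  out <- list()
  for (m in names(peaks)) {
    for (cl in names(classes)) {
      ids <- classes[[cl]]
      gr <- tx[match(ids, tx$transcript_id)]
      win <- tss_window(gr, window, annotation$chrom_sizes)
      n_assoc <- sum(GenomicRanges::countOverlaps(
        win, peaks[[m]], ignore.strand = TRUE) > 0)
      out[[length(out) + 1L]] <- tibble(
        mark = m, class = cl, n_genes = length(ids), n_associated = n_assoc,
        fraction = if (length(ids) > 0) n_assoc / length(ids) else NA_real_)
    }
  }
  bind_rows(out)
}

#' TSS metaprofile of an interval track
#'
#' Mean signal per strand-oriented offset in `[-window, window - 1]`
#' (positive offsets downstream of the TSS). The signal is interval coverage
#' (a `score` metadata column weights it when present). Positions clipped at
#' a chromosome edge are excluded from both numerator and denominator, and
#' minus-strand genes are flipped.
#'
#' @param track `GRanges` (optionally with `score`).
#' @param annotation a [nat_annotation()].
#' @param ids transcript ids to profile.
#' @param window half-width in bp (default 1000).
#' @return tibble `offset`, `mean_signal`, `n_genes` (contributing genes at
#'   that offset).
#' @export
tss_metaprofile <- function(track, annotation, ids, window = 1000) {
  weight <- if (!is.null(track$score)) track$score else 1L
  cov <- GenomicRanges::coverage(track, weight = weight)
  tx <- annotation$transcripts
  gr <- tx[match(ids, tx$transcript_id)]
  offsets <- seq(-window, window - 1L)
  acc <- numeric(length(offsets))
  cnt <- integer(length(offsets))
  sizes <- annotation$chrom_sizes
  for (k in seq_along(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr))[k]
    st <- as.character(BiocGenerics::strand(gr))[k]
    tss <- tss_of(gr[k])
    pos <- if (st == "+") tss + offsets else tss - offsets
    hi <- if (!is.null(sizes)) sizes[[chrom]] else Inf
    ok <- pos >= 1 & pos <= hi
    rle <- if (chrom %in% names(cov)) cov[[chrom]] else S4Vectors::Rle(0L, 0)
    sig <- numeric(sum(ok))
    inrle <- pos[ok] <= length(rle)
    sig[inrle] <- as.numeric(rle[pos[ok][inrle]])
    acc[ok] <- acc[ok] + sig
    cnt[ok] <- cnt[ok] + 1L
  }
  tibble(offset = offsets,
         mean_signal = ifelse(cnt > 0, acc / cnt, NA_real_),
         n_genes = cnt)
}

# gene body plus 1-kb upstream promoter, strand-aware and clipped
gene_region <- function(annotation, ids, promoter = 1000) {
  tx <- annotation$transcripts
  gr <- tx[match(ids, tx$transcript_id)]
  st <- as.character(BiocGenerics::strand(gr))
  lo <- ifelse(st == "+", BiocGenerics::start(gr) - promoter,
               BiocGenerics::start(gr))
  hi <- ifelse(st == "+", BiocGenerics::end(gr),
               BiocGenerics::end(gr) + promoter)
  lo <- pmax(1, lo)
  if (!is.null(annotation$chrom_sizes)) {
    hi <- pmin(hi, annotation$chrom_sizes[
      as.character(GenomicRanges::seqnames(gr))])
  }
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(lo, hi),
                                strand = st)
  out$transcript_id <- gr$transcript_id
  out
}

#' Methylation change of gene regions between timepoints
#'
#' Per gene, the mean cytosine level over the gene body plus 1-kb promoter
#' is compared between a heated timepoint and baseline:
#' `delta = mean(level at t) - mean(level at t0)`, pooling contexts. Genes
#' with `delta > 0` are up, `< 0` down; exact ties are excluded from the
#' fractions, and genes with no cytosines at either timepoint are dropped.
#'
#' @param meth tibble `chrom`, `pos`, `context`, `level`, `timepoint_h`.
#' @param annotation a [nat_annotation()].
#' @param classes named list mapping class name to transcript ids.
#' @param timepoint heated timepoint in hours (e.g. 6, 12 or 24).
#' @param baseline baseline timepoint (default 0).
#' @param promoter upstream extension in bp (default 1000).
#' @return list with `per_gene` (tibble `class`, `transcript_id`,
#'   `mean_baseline`, `mean_treated`, `delta`) and `summary` (tibble
#'   `class`, `n_up`, `n_down`, `frac_up`, `frac_down`).
#' @export
methylation_change <- function(meth, annotation, classes, timepoint,
                               baseline = 0, promoter = 1000) {
  pts <- GenomicRanges::GRanges(meth$chrom, IRanges::IRanges(meth$pos, meth$pos))
  per_gene <- list()
  for (cl in names(classes)) {
    ids <- classes[[cl]]
    if (length(ids) == 0) next
    regions <- gene_region(annotation, ids, promoter)
    hits <- GenomicRanges::findOverlaps(pts, regions, ignore.strand = TRUE)
    if (length(hits) == 0) next
    d <- tibble(
      transcript_id = regions$transcript_id[S4Vectors::subjectHits(hits)],
      level = meth$level[S4Vectors::queryHits(hits)],
      timepoint_h = meth$timepoint_h[S4Vectors::queryHits(hits)]) |>
      filter(timepoint_h %in% c(baseline, timepoint)) |>
      group_by(transcript_id,
               when = ifelse(timepoint_h == baseline, "baseline", "treated")) |>
      summarise(m = mean(level), .groups = "drop") |>
      pivot_wider(names_from = when, values_from = m)
    if (!all(c("baseline", "treated") %in% names(d))) next
    d <- d |>
      filter(!is.na(baseline), !is.na(treated)) |>
      transmute(class = cl, transcript_id,
                mean_baseline = baseline, mean_treated = treated,
                delta = treated - baseline)
    per_gene[[cl]] <- d
  }
  per_gene <- if (length(per_gene)) bind_rows(per_gene) else
    tibble(class = character(), transcript_id = character(),
           mean_baseline = numeric(), mean_treated = numeric(),
           delta = numeric())
  summary <- per_gene |>
    filter(delta != 0) |>
    group_by(class) |>
    summarise(n_up = sum(delta > 0), n_down = sum(delta < 0),
              frac_up = n_up / (n_up + n_down),
              frac_down = n_down / (n_up + n_down), .groups = "drop")
  list(per_gene = per_gene, summary = summary)
}

#' Per-context methylation summary around TSS
#'
#' Mean cytosine level per sequence context (CpG, CHG, CHH) among sites
#' within `[TSS - window, TSS + window]` of the given genes at one
#' timepoint. Used to compare context ordering (e.g. CpG > CHH > CHG).
#'
#' @param meth tibble `chrom`, `pos`, `context`, `level`, `timepoint_h`.
#' @param annotation a [nat_annotation()].
#' @param ids transcript ids.
#' @param window half-width in bp (default 1000).
#' @param timepoint timepoint to summarise (default 0).
#' @return tibble `context`, `n_sites`, `mean_level`.
#' @export
methylation_context_summary <- function(meth, annotation, ids, window = 1000,
                                        timepoint = 0) {
  meth <- meth |> filter(timepoint_h == timepoint)
  pts <- GenomicRanges::GRanges(meth$chrom, IRanges::IRanges(meth$pos, meth$pos))
  tx <- annotation$transcripts
  win <- tss_window(tx[match(ids, tx$transcript_id)], window,
                    annotation$chrom_sizes)
  keep <- GenomicRanges::countOverlaps(pts, win, ignore.strand = TRUE) > 0
  meth[keep, ] |>
    group_by(context) |>
    summarise(n_sites = n(), mean_level = mean(level), .groups = "drop") |>
    arrange(desc(mean_level))
}

# --- heat-shock element scanning --------------------------------------------

# HSE patterns are built from 5-bp units nGAAn / nTTCn. Within a unit the
# G (or C) is invariant and at most one of the two A's (T's) may mismatch;
# n positions are free. Unit definitions give, for each motif, the 1-based
# offsets of the invariant base and of the two degenerate bases.
hse_patterns <- list(
  canonical_double = list(width = 10L, units = list(
    list(inv = 2L, invb = "G", deg = c(3L, 4L), degb = "A"),
    list(inv = 9L, invb = "C", deg = c(7L, 8L), degb = "T"))),
  canonical_triple = list(width = 15L, units = list(
    list(inv = 2L, invb = "G", deg = c(3L, 4L), degb = "A"),
    list(inv = 9L, invb = "C", deg = c(7L, 8L), degb = "T"),
    list(inv = 12L, invb = "G", deg = c(13L, 14L), degb = "A"))),
  non_canonical = list(width = 12L, units = list(
    list(inv = 2L, invb = "G", deg = c(3L, 4L), degb = "A"),
    list(inv = 11L, invb = "C", deg = c(9L, 10L), degb = "T")))
)

# scan one strand of an upper-case character vector; returns start positions
# and mismatch totals for one pattern
scan_pattern <- function(chars, pat) {
  L <- length(chars)
  w <- pat$width
  if (L < w) return(list(start = integer(0), mism = integer(0)))
  idx <- seq_len(L - w + 1L)
  ok <- rep(TRUE, length(idx))
  mism <- rep(0L, length(idx))
  for (u in pat$units) {
    ok <- ok & chars[idx + u$inv - 1L] == u$invb
    um <- (chars[idx + u$deg[1] - 1L] != u$degb) +
          (chars[idx + u$deg[2] - 1L] != u$degb)
    ok <- ok & um <= 1L
    mism <- mism + um
  }
  list(start = idx[ok], mism = mism[ok])
}

#' Scan a promoter sequence for heat-shock elements
#'
#' Matches, on both strands, the canonical double HSE `nGAAnnTTCn` (10 nt),
#' the canonical triple HSE `nGAAnnTTCnnGAAn` (15 nt) and the non-canonical
#' HSE `nGAAnnnnTTCn` (12 nt). Within each 5-bp unit the G (or C) is
#' invariant and at most one of the two conserved A's (T's) may be
#' exchanged; `n` positions are free. The TTC-first phases are the
#' reverse-complement images of these patterns, so the opposite-strand scan
#' covers them; since the double and non-canonical patterns are their own
#' reverse complements, duplicate (start, end, kind) intervals are collapsed
#' to a single record with the best mismatch count. Overlapping hits are all
#' reported, except canonical doubles whose interval is contained in a
#' canonical triple hit (suppressed to avoid double counting). Positions are
#' 1-based on the given string, for both strands.
#'
#' @param promoter character string or `DNAString` over A, C, G, T, N
#'   (case-insensitive). `N` matches only free positions.
#' @return tibble `start`, `end`, `strand`, `kind`, `n_mismatches`, sorted
#'   by position.
#' @export
scan_hse <- function(promoter) {
  s <- toupper(as.character(promoter))
  if (!grepl("^[ACGTN]*$", s)) {
    stop("input error: promoter contains characters outside A/C/G/T/N",
         call. = FALSE)
  }
  L <- nchar(s)
  fwd <- strsplit(s, "", fixed = TRUE)[[1]]
  rev <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))),
    "", fixed = TRUE)[[1]]
  rows <- list()
  for (kind in names(hse_patterns)) {
    pat <- hse_patterns[[kind]]
    f <- scan_pattern(fwd, pat)
    if (length(f$start) > 0) {
      rows[[length(rows) + 1L]] <- tibble(
        start = f$start, end = f$start + pat$width - 1L, strand = "+",
        kind = kind, n_mismatches = f$mism)
    }
    r <- scan_pattern(rev, pat)
    if (length(r$start) > 0) {
      # map reverse-complement coordinates back onto the forward string
      rows[[length(rows) + 1L]] <- tibble(
        start = L - (r$start + pat$width - 1L) + 1L,
        end = L - r$start + 1L, strand = "-",
        kind = kind, n_mismatches = r$mism)
    }
  }
  hits <- if (length(rows)) bind_rows(rows) else
    tibble(start = integer(), end = integer(), strand = character(),
           kind = character(), n_mismatches = integer())
  # the double and non-canonical patterns are their own reverse complements,
  # so each such element matches identically on both strands: collapse
  # duplicate (start, end, kind) intervals, keeping the best mismatch count
  hits <- hits |>
    arrange(start, end, kind, n_mismatches, strand) |>
    distinct(start, end, kind, .keep_all = TRUE)
  triples <- hits |> filter(kind == "canonical_triple")
  if (nrow(triples) > 0 && any(hits$kind == "canonical_double")) {
    dbl <- hits$kind == "canonical_double"
    contained <- vapply(which(dbl), function(i) {
      any(hits$start[i] >= triples$start & hits$end[i] <= triples$end)
    }, logical(1))
    hits <- hits[!(dbl & replace(rep(FALSE, nrow(hits)), which(dbl), contained)), ]
  }
  arrange(hits, start, end, strand, kind)
}

#' Scan a set of promoters for heat-shock elements
#'
#' @param promoters named `DNAStringSet` or named character vector.
#' @return tibble with a `sequence_id` column followed by [scan_hse()]
#'   columns.
#' @export
scan_hse_set <- function(promoters) {
  seqs <- as.character(promoters)
  out <- lapply(names(seqs), function(nm) {
    h <- scan_hse(seqs[[nm]])
    if (nrow(h) > 0) mutate(h, sequence_id = nm, .before = 1) else NULL
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(sequence_id = character(), start = integer(),
                  end = integer(), strand = character(), kind = character(),
                  n_mismatches = integer())
  }
  res
}
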