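# Heat-response calling on replicated TPM expression.
#
# Per-transcript calls use the printed decision rule (fold change >= 2 and
# raw p < 0.05, no multiple-testing correction) with Welch's two-sample
# t-test on log2(TPM + 1) replicate values and a pseudo-count of 1 TPM in
# the fold change. A pair is heat-responsive when both members qualify in
# the same tissue-by-timepoint contrast; responsive pairs split into
# concordant/discordant by the sign of the Pearson correlation of their
# fold-change vectors over all contrasts.

#' TPM from raw counts and transcript lengths
#'
#' `TPM(t, s) = 1e6 * rate(t, s) / sum_u rate(u, s)` with
#' `rate = count / length_kb`; every column with any signal sums to 1e6.
#'
#' @param counts integer matrix, transcripts x samples.
#' @param lengths named vector of exonic lengths in bp (> 0), covering all
#'   transcripts.
#' @return TPM matrix with the same dimnames.
#' @export
compute_tpm <- function(counts, lengths) {
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths) || any(lengths <= 0)) {
    stop("validation error: missing or non-positive transcript length",
         call. = FALSE)
  }
  rate <- counts / (lengths / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero count column(s): ",
            paste(colnames(counts)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

# Row-wise Welch two-sample test (x, y: matrices with one row per
# transcript). Verified against stats::t.test in the test suite.
welch_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(stat), df)
  # degenerate: both groups constant
  flat <- se2 == 0
  p[flat] <- ifelse(m1[flat] == m2[flat], 1, 0)
  list(stat = stat, df = df, p = p)
}

#' Differential heat-response test per transcript
#'
#' For each requested tissue and heated timepoint, compares treated
#' replicates against the tissue's 0-h control:
#' `log2fc = log2((mean treated + c) / (mean control + c))` with pseudo-count
#' `c`, p from Welch's t-test on `log2(TPM + 1)` replicate values. Status is
#' `up` when `log2fc >= log2(fc)` and `p < p_threshold`, `down` when
#' `log2fc <= -log2(fc)` and `p < p_threshold`, else `ns`.
#'
#' @param expr a `tpm_expression`.
#' @param tissues tissues to test (default: all in the design).
#' @param timepoints heated timepoints to test (default `c(1, 5)`).
#' @param fc fold-change threshold (default 2).
#' @param p_threshold raw p-value threshold (default 0.05).
#' @param pseudo pseudo-count in TPM added inside the fold change (default 1).
#' @return tibble `transcript_id`, `tissue`, `timepoint_h`, `log2fc`, `p`,
#'   `status`.
#' @export
diff_test <- function(expr, tissues = NULL, timepoints = c(1, 5), fc = 2,
                      p_threshold = 0.05, pseudo = 1) {
  design <- expr$design
  if (is.null(tissues)) tissues <- unique(design$tissue)
  thr <- log2(fc)
  out <- list()
  for (ti in tissues) {
    ctrl_cols <- design$sample_id[design$tissue == ti & design$timepoint_h == 0]
    if (length(ctrl_cols) < 2) {
      stop("missing control group for (", ti, ", 0 h)", call. = FALSE)
    }
    ctrl <- expr$tpm[, ctrl_cols, drop = FALSE]
    for (tp in timepoints) {
      trt_cols <- design$sample_id[design$tissue == ti &
                                     design$timepoint_h == tp]
      if (length(trt_cols) < 2) {
        stop("missing treated group for (", ti, ", ", tp, " h)", call. = FALSE)
      }
      trt <- expr$tpm[, trt_cols, drop = FALSE]
      lfc <- log2((rowMeans(trt) + pseudo) / (rowMeans(ctrl) + pseudo))
      w <- welch_rows(log2(trt + 1), log2(ctrl + 1))
      lfc <- unname(lfc); p <- unname(w$p)
      out[[length(out) + 1L]] <- tibble(
        transcript_id = rownames(expr$tpm), tissue = ti, timepoint_h = tp,
        log2fc = lfc, p = p,
        status = ifelse(p < p_threshold & lfc >= thr, "up",
                  ifelse(p < p_threshold & lfc <= -thr, "down", "ns")))
    }
  }
  bind_rows(out)
}

#' Call heat-responsive NAT pairs
#'
#' A pair is responsive iff there exists a tissue-by-timepoint contrast in
#' which BOTH members have `|log2fc| >= lfc_threshold` and
#' `p < p_threshold`. All qualifying contrasts are recorded.
#'
#' @param pairs oriented pair tibble with `pair_id`, `sense_id`,
#'   `antisense_id`.
#' @param diff tibble from [diff_test()] covering all members and contrasts.
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param p_threshold raw p threshold (default 0.05).
#' @return tibble `pair_id`, `responsive`, `n_qualifying`, `qualifying`
#'   (semicolon-separated `tissue@timepointh` labels).
#' @export
call_responsive_pairs <- function(pairs, diff, lfc_threshold = 1,
                                  p_threshold = 0.05) {
  sig <- diff |>
    mutate(sig = abs(log2fc) >= lfc_threshold & p < p_threshold) |>
    select(transcript_id, tissue, timepoint_h, sig)
  joined <- pairs |>
    select(pair_id, sense_id, antisense_id) |>
    inner_join(rename(sig, sense_id = transcript_id, sig_s = sig),
               by = "sense_id") |>
    inner_join(rename(sig, antisense_id = transcript_id, sig_a = sig),
               by = c("antisense_id", "tissue", "timepoint_h")) |>
    mutate(both = sig_s & sig_a)
  res <- joined |>
    group_by(pair_id) |>
    summarise(
      responsive = any(both),
      n_qualifying = sum(both),
      qualifying = paste(sprintf("%s@%gh", tissue[both], timepoint_h[both]),
                         collapse = ";"),
      .groups = "drop")
  pairs |>
    select(pair_id) |>
    left_join(res, by = "pair_id") |>
    mutate(responsive = ifelse(is.na(responsive), FALSE, responsive),
           n_qualifying = ifelse(is.na(n_qualifying), 0L, n_qualifying),
           qualifying = ifelse(is.na(qualifying), "", qualifying))
}

#' Concordance of sense and antisense fold changes
#'
#' Pearson correlation between the sense and antisense log2 fold-change
#' vectors over all tested contrasts. `r > 0` is concordant, `r < 0`
#' discordant; an undefined or exactly zero correlation is unclassified.
#'
#' @param pairs oriented pair tibble.
#' @param diff tibble from [diff_test()].
#' @return tibble `pair_id`, `r`, `concordance`.
#' @export
pair_concordance <- function(pairs, diff) {
  wide <- diff |>
    mutate(contrast = paste(tissue, timepoint_h, sep = "@")) |>
    select(transcript_id, contrast, log2fc) |>
    pivot_wider(names_from = contrast, values_from = log2fc)
  L <- as.matrix(wide[, -1])
  rownames(L) <- wide$transcript_id
  S <- L[pairs$sense_id, , drop = FALSE]
  A <- L[pairs$antisense_id, , drop = FALSE]
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    suppressWarnings(cor(S[i, ], A[i, ]))
  }, numeric(1))
  tibble(pair_id = pairs$pair_id, r = r,
         concordance = ifelse(is.na(r) | r == 0, "unclassified",
                        ifelse(r > 0, "concordant", "discordant")))
}

#' Full per-pair heat response
#'
#' Joins [call_responsive_pairs()] and [pair_concordance()]; the concordance
#' class is reported for responsive pairs and `NA` otherwise.
#'
#' @inheritParams call_responsive_pairs
#' @return tibble `pair_id`, `responsive`, `n_qualifying`, `qualifying`,
#'   `r`, `concordance`.
#' @export
pair_response <- function(pairs, diff, lfc_threshold = 1, p_threshold = 0.05) {
  resp <- call_responsive_pairs(pairs, diff, lfc_threshold, p_threshold)
  conc <- pair_concordance(pairs, diff)
  resp |>
    left_join(conc, by = "pair_id") |>
    mutate(concordance = ifelse(responsive, concordance, NA_character_))
}

#' Tissue-specificity partition of responsive pairs
#'
#' Each responsive pair is assigned to the exact set of tissues (union over
#' timepoints) in which it qualifies; counts are reported per tissue subset,
#' together with the tissue-specific (singleton-subset) total and its share
#' of all responsive pairs.
#'
#' @param responses tibble from [pair_response()] /
#'   [call_responsive_pairs()] with populated `qualifying`.
#' @return list with `counts` (tibble `subset`, `n_tissues`, `n`),
#'   `n_responsive`, `tissue_specific_n`, `tissue_specific_pct`.
#' @export
tissue_specificity <- function(responses) {
  resp <- responses |> filter(responsive)
  subsets <- vapply(strsplit(resp$qualifying, ";", fixed = TRUE),
                    function(q) {
                      ts <- sort(unique(sub("@.*$", "", q)))
                      paste(ts, collapse = "+")
                    }, character(1))
  counts <- tibble(subset = subsets) |>
    count(subset, name = "n") |>
    mutate(n_tissues = lengths(strsplit(subset, "+", fixed = TRUE))) |>
    arrange(n_tissues, subset) |>
    relocate(subset, n_tissues, n)
  specific <- sum(counts$n[counts$n_tissues == 1])
  list(counts = counts,
       n_responsive = nrow(resp),
       tissue_specific_n = specific,
       tissue_specific_pct = if (nrow(resp) > 0) 100 * specific / nrow(resp)
                             else NA_real_)
}

#' Shared differential-expression fraction across tissues
#'
#' Intersection-over-union of per-tissue differentially expressed gene sets
#' (up and down are handled by separate calls):
#' `pct = 100 * |intersection| / |union|`.
#'
#' @param sets named list (one element per tissue) of transcript id vectors.
#' @return list `n_shared`, `n_union`, `pct` (`NA` with a warning when the
#'   union is empty).
#' @export
shared_de_fraction <- function(sets) {
  stopifnot(length(sets) >= 2)
  inter <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  if (length(uni) == 0) {
    warning("empty union: shared fraction undefined")
    return(list(n_shared = 0L, n_union = 0L, pct = NA_real_))
  }
  list(n_shared = length(inter), n_union = length(uni),
       pct = 100 * length(inter) / length(uni))
}
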