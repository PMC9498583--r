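# lncRNA candidate filter cascade and positional classification.
#
# Filter order is fixed and matters: (1) spliced length < 200 nt,
# (2) any exonic overlap with the structural-RNA blacklist (strand-blind,
# 1-bp trigger), (3) coding label, then positional classification of the
# survivors against the known (annotated mRNA) gene set.

LNC_STATUSES <- c("annotated_mRNA", "discarded_short", "discarded_blacklist",
                  "discarded_coding", "lincRNA", "incRNA", "NAT_candidate")

#' Filter lncRNA candidates and classify survivors
#'
#' Transcripts with biotype `mRNA` are passed through as `annotated_mRNA`.
#' Every other transcript runs the cascade: spliced (exonic) length
#' < `min_len` discards as `discarded_short` (exactly `min_len` is kept);
#' >= 1 bp exonic overlap with the blacklist (either strand) discards as
#' `discarded_blacklist`; a `coding` label (or positive `score` when the
#' label is absent) discards as `discarded_coding`. Survivors are classified
#' positionally by [classify_position()].
#'
#' @param annotation a [nat_annotation()]; its `mRNA` transcripts are the
#'   known-gene set.
#' @param blacklist `GRanges` of structural-RNA intervals (tRNA, rRNA, sRNA,
#'   miRNA).
#' @param coding_labels data frame with `transcript_id` and `label`
#'   (`coding`/`noncoding`), optionally a numeric `score` (> 0 means coding)
#'   used when `label` is missing. Must cover every non-mRNA transcript.
#' @param min_len minimum spliced length in nt (default 200).
#' @return tibble with one row per transcript: `transcript_id`, `status`
#'   (one of `annotated_mRNA`, `discarded_short`, `discarded_blacklist`,
#'   `discarded_coding`, `lincRNA`, `incRNA`, `NAT_candidate`) and `reason`.
#'   Statuses partition the input set.
#' @export
filter_candidates <- function(annotation, blacklist, coding_labels,
                              min_len = 200) {
  tx <- annotation$transcripts
  ids <- tx$transcript_id
  status <- setNames(rep(NA_character_, length(ids)), ids)
  reason <- setNames(rep("", length(ids)), ids)

  is_mrna <- tx$biotype == "mRNA"
  status[is_mrna] <- "annotated_mRNA"
  reason[is_mrna] <- "annotated protein-coding transcript"
  cand <- ids[!is_mrna]

  # (1) spliced length
  elen <- exonic_length(annotation, cand)
  short <- cand[elen < min_len]
  status[short] <- "discarded_short"
  reason[short] <- sprintf("spliced length %d nt < %d nt", elen[elen < min_len],
                           as.integer(min_len))
  cand <- setdiff(cand, short)

  # (2) blacklist overlap: exon-level, strand-blind, 1-bp trigger
  if (length(cand) > 0 && length(blacklist) > 0) {
    exu <- unlist(annotation$exons[cand], use.names = TRUE)
    hit <- GenomicRanges::findOverlaps(exu, blacklist, ignore.strand = TRUE)
    bl <- unique(names(exu)[S4Vectors::queryHits(hit)])
    status[bl] <- "discarded_blacklist"
    reason[bl] <- "exonic overlap with structural-RNA blacklist"
    cand <- setdiff(cand, bl)
  }

  # (3) coding potential (consumed as labels)
  lab <- coding_labels
  missing_ids <- setdiff(cand, lab$transcript_id)
  if (length(missing_ids) > 0) {
    stop("validation error: missing coding label for: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  li <- match(cand, lab$transcript_id)
  label <- if ("label" %in% names(lab)) lab$label[li] else rep(NA, length(cand))
  if ("score" %in% names(lab)) {
    label[is.na(label)] <- ifelse(lab$score[li][is.na(label)] > 0,
                                  "coding", "noncoding")
  }
  coding <- cand[!is.na(label) & label == "coding"]
  status[coding] <- "discarded_coding"
  reason[coding] <- "classified as coding"
  cand <- setdiff(cand, coding)

  # (4) positional classification of survivors
  if (length(cand) > 0) {
    pos <- classify_position(annotation, cand)
    status[cand] <- pos$class
    reason[cand] <- pos$reason
  }

  tibble(transcript_id = ids, status = unname(status[ids]),
         reason = unname(reason[ids]))
}

#' Positionally classify lncRNA candidates against known genes
#'
#' Precedence: `NAT_candidate` if the candidate span overlaps a known gene's
#' span on the opposite strand (>= 1 bp); else `incRNA` if the span is fully
#' contained in an intron of a known gene (either strand); else `lincRNA`.
#' Known genes are the annotation's `mRNA` transcripts. Overlap is computed
#' on genomic spans (introns included).
#'
#' @param annotation a [nat_annotation()].
#' @param ids candidate transcript ids (default: all non-mRNA transcripts).
#' @return tibble `transcript_id`, `class`, `reason`.
#' @export
classify_position <- function(annotation, ids = NULL) {
  tx <- annotation$transcripts
  if (is.null(ids)) ids <- tx$transcript_id[tx$biotype != "mRNA"]
  cand <- tx[match(ids, tx$transcript_id)]
  known <- tx[tx$biotype == "mRNA"]

  cls <- rep("lincRNA", length(cand))
  why <- rep("no span overlap with any known gene", length(cand))

  if (length(known) > 0) {
    hits <- GenomicRanges::findOverlaps(cand, known, ignore.strand = TRUE)
    opp <- as.character(BiocGenerics::strand(cand))[S4Vectors::queryHits(hits)] !=
      as.character(BiocGenerics::strand(known))[S4Vectors::subjectHits(hits)]
    any_overlap <- unique(S4Vectors::queryHits(hits))
    nat <- unique(S4Vectors::queryHits(hits)[opp])

    multi <- known[S4Vectors::elementNROWS(
      annotation$exons[known$transcript_id]) > 1]
    inc <- integer(0)
    if (length(multi) > 0) {
      introns <- unlist(introns_of(annotation, multi$transcript_id))
      if (length(introns) > 0) {
        wi <- GenomicRanges::findOverlaps(cand, introns, type = "within",
                                          ignore.strand = TRUE)
        inc <- unique(S4Vectors::queryHits(wi))
      }
    }

    same_only <- setdiff(any_overlap, nat)
    cls[same_only] <- "lincRNA"
    why[same_only] <- "same-strand span overlap with a known gene (not intron-contained)"
    cls[inc] <- "incRNA"
    why[inc] <- "span contained in an intron of a known gene"
    cls[nat] <- "NAT_candidate"
    why[nat] <- "span overlaps a known gene on the opposite strand"
  }
  tibble(transcript_id = ids, class = cls, reason = why)
}
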