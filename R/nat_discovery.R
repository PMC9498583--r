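# cis-NAT pair discovery, orientation and classification.
#
# A cis-NAT pair is two transcripts on opposite strands of the same
# chromosome whose genomic spans overlap by at least 50 bp. Discovery uses
# the interval-tree overlap engine of GenomicRanges (O(n log n + k)); a
# brute-force all-pairs scan serves as the oracle in the test suite.

#' Find candidate cis-NAT pairs
#'
#' All unordered transcript pairs on opposite strands of the same chromosome
#' whose spans (introns included) overlap by at least `min_overlap` bp.
#'
#' @param annotation a [nat_annotation()] (typically restricted to
#'   filter-surviving transcripts).
#' @param min_overlap minimum span overlap in bp (default 50, inclusive).
#' @return tibble with one row per unordered pair: `id1`, `id2`, `chrom`,
#'   `overlap_start`, `overlap_end`, `overlap_len`.
#' @export
find_nat_pairs <- function(annotation, min_overlap = 50) {
  gr <- annotation$transcripts
  hits <- GenomicRanges::findOverlaps(gr, minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE,
                                      drop.self = TRUE, drop.redundant = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  opp <- as.character(BiocGenerics::strand(gr))[q] !=
    as.character(BiocGenerics::strand(gr))[s]
  q <- q[opp]; s <- s[opp]
  os <- pmax(BiocGenerics::start(gr)[q], BiocGenerics::start(gr)[s])
  oe <- pmin(BiocGenerics::end(gr)[q], BiocGenerics::end(gr)[s])
  out <- tibble(
    id1 = gr$transcript_id[q], id2 = gr$transcript_id[s],
    chrom = as.character(GenomicRanges::seqnames(gr))[q],
    overlap_start = os, overlap_end = oe,
    overlap_len = oe - os + 1L)
  arrange(out, chrom, overlap_start, id1, id2)
}

#' Orient pairs into sense and antisense
#'
#' The sense transcript is, in order of precedence: the member with the
#' higher conservation score when both are scored and the scores differ
#' (`orientation_basis = "conservation"`); otherwise the member detected
#' (replicate-mean TPM >= `detect_tpm`) in more tissue-by-timepoint sample
#' groups (`"expression_breadth"`); remaining ties go to the
#' lexicographically smaller transcript id under C collation
#' (`"tie_break"`, a convention rather than biology).
#'
#' @param pairs tibble from [find_nat_pairs()].
#' @param expr a `tpm_expression` covering every pair member.
#' @param conservation optional data frame `transcript_id`, `score`.
#' @param detect_tpm detection threshold on replicate-mean TPM (default 1).
#' @return `pairs` with `sense_id`, `antisense_id`, `orientation_basis`
#'   (and without `id1`/`id2`).
#' @export
assign_sense_antisense <- function(pairs, expr, conservation = NULL,
                                   detect_tpm = 1) {
  members <- unique(c(pairs$id1, pairs$id2))
  missing_ids <- setdiff(members, rownames(expr$tpm))
  if (length(missing_ids) > 0) {
    stop("validation error: pair member(s) missing from expression matrix: ",
         paste(head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }

  cons <- setNames(rep(NA_real_, length(members)), members)
  if (!is.null(conservation)) {
    i <- match(members, conservation$transcript_id)
    cons[!is.na(i)] <- conservation$score[i[!is.na(i)]]
  }

  # detection breadth: groups = tissue x timepoint, detected when the mean
  # TPM over that group's replicates reaches detect_tpm
  grp <- paste(expr$design$tissue, expr$design$timepoint_h)
  tpm <- expr$tpm[members, , drop = FALSE]
  gmeans <- vapply(split(seq_len(ncol(tpm)), grp),
                   function(cols) rowMeans(tpm[, cols, drop = FALSE]),
                   numeric(length(members)))
  if (is.null(dim(gmeans))) gmeans <- matrix(gmeans, nrow = 1,
                                             dimnames = list(members, NULL))
  breadth <- setNames(rowSums(gmeans >= detect_tpm), members)

  c1 <- unname(cons[pairs$id1]); c2 <- unname(cons[pairs$id2])
  b1 <- unname(breadth[pairs$id1]); b2 <- unname(breadth[pairs$id2])
  use_cons <- !is.na(c1) & !is.na(c2) & c1 != c2
  use_breadth <- !use_cons & b1 != b2

  sense_first <- ifelse(use_cons, c1 > c2,
                 ifelse(use_breadth, b1 > b2,
                        # C-collation lexicographic tie-break
                        vapply(seq_len(nrow(pairs)), function(i) {
                          sort(c(pairs$id1[i], pairs$id2[i]),
                               method = "radix")[1] == pairs$id1[i]
                        }, logical(1))))
  pairs |>
    mutate(sense_id = ifelse(sense_first, id1, id2),
           antisense_id = ifelse(sense_first, id2, id1),
           orientation_basis = ifelse(use_cons, "conservation",
                                ifelse(use_breadth, "expression_breadth",
                                       "tie_break"))) |>
    select(-id1, -id2) |>
    relocate(sense_id, antisense_id)
}

#' Classify pair overlap configuration
#'
#' `enclosed` when either span contains the other (identical spans count as
#' mutual containment); otherwise `convergent` when both members' 3' ends
#' lie inside the overlap (transcription pointing toward each other), and
#' `divergent` when both 5' ends do. For partial overlaps of opposite-strand
#' spans exactly one of the two holds, so the classification is exhaustive
#' and orientation-independent.
#'
#' @param pairs tibble with `sense_id`/`antisense_id` (or `id1`/`id2`).
#' @param annotation the [nat_annotation()] holding the members' spans.
#' @return `pairs` with a `configuration` column.
#' @export
classify_configuration <- function(pairs, annotation) {
  a_col <- if ("sense_id" %in% names(pairs)) "sense_id" else "id1"
  b_col <- if ("antisense_id" %in% names(pairs)) "antisense_id" else "id2"
  tx <- annotation$transcripts
  ga <- tx[match(pairs[[a_col]], tx$transcript_id)]
  gb <- tx[match(pairs[[b_col]], tx$transcript_id)]
  s1 <- BiocGenerics::start(ga); e1 <- BiocGenerics::end(ga)
  s2 <- BiocGenerics::start(gb); e2 <- BiocGenerics::end(gb)
  st1 <- as.character(BiocGenerics::strand(ga))
  if (any(st1 == as.character(BiocGenerics::strand(gb)))) {
    stop("validation error: pair members on the same strand", call. = FALSE)
  }
  enclosed <- (s1 <= s2 & e1 >= e2) | (s2 <= s1 & e2 >= e1)
  # partial overlap: the pair is convergent iff the plus-strand member is the
  # left one (then both 3' ends fall inside the overlap), divergent otherwise
  plus_start <- ifelse(st1 == "+", s1, s2)
  minus_start <- ifelse(st1 == "+", s2, s1)
  pairs$configuration <- ifelse(enclosed, "enclosed",
                          ifelse(plus_start < minus_start, "convergent",
                                 "divergent"))
  pairs
}

#' Classify pair type from member calls
#'
#' `annotated_mRNA` members count as mRNA; `lincRNA`, `incRNA` and
#' `NAT_candidate` members count as lncRNA. The label is unordered.
#'
#' @param pairs oriented pair tibble.
#' @param calls tibble from [filter_candidates()].
#' @return `pairs` with a `pair_type` column (`mRNA-mRNA`, `mRNA-lncRNA` or
#'   `lncRNA-lncRNA`).
#' @export
classify_pair_type <- function(pairs, calls) {
  a_col <- if ("sense_id" %in% names(pairs)) "sense_id" else "id1"
  b_col <- if ("antisense_id" %in% names(pairs)) "antisense_id" else "id2"
  status <- setNames(calls$status, calls$transcript_id)
  side <- function(ids) {
    st <- status[ids]
    if (anyNA(st)) {
      stop("validation error: missing lncRNA call for: ",
           paste(head(ids[is.na(st)], 5), collapse = ", "), call. = FALSE)
    }
    if (any(startsWith(st, "discarded"))) {
      stop("validation error: discarded transcript in pair: ",
           paste(head(ids[startsWith(st, "discarded")], 5), collapse = ", "),
           call. = FALSE)
    }
    unname(ifelse(st == "annotated_mRNA", "mRNA", "lncRNA"))
  }
  m1 <- side(pairs[[a_col]]); m2 <- side(pairs[[b_col]])
  pairs$pair_type <- ifelse(m1 == "mRNA" & m2 == "mRNA", "mRNA-mRNA",
                      ifelse(m1 == "lncRNA" & m2 == "lncRNA", "lncRNA-lncRNA",
                             "mRNA-lncRNA"))
  pairs
}

#' Discover, orient and classify cis-NAT pairs in one call
#'
#' Runs [find_nat_pairs()], [assign_sense_antisense()],
#' [classify_configuration()] and [classify_pair_type()], and assigns stable
#' `pair_id`s in (chromosome, overlap start, sense id) order.
#'
#' @inheritParams find_nat_pairs
#' @inheritParams assign_sense_antisense
#' @param calls tibble from [filter_candidates()].
#' @return oriented, classified pair tibble with `pair_id` first.
#' @export
discover_nat_pairs <- function(annotation, expr, calls, conservation = NULL,
                               min_overlap = 50, detect_tpm = 1) {
  pairs <- find_nat_pairs(annotation, min_overlap = min_overlap)
  if (nrow(pairs) == 0) {
    return(tibble(pair_id = character(), sense_id = character(),
                  antisense_id = character(), chrom = character(),
                  overlap_start = integer(), overlap_end = integer(),
                  overlap_len = integer(), configuration = character(),
                  pair_type = character(), orientation_basis = character()))
  }
  pairs <- assign_sense_antisense(pairs, expr, conservation = conservation,
                                  detect_tpm = detect_tpm)
  pairs <- classify_configuration(pairs, annotation)
  pairs <- classify_pair_type(pairs, calls)
  pairs <- arrange(pairs, chrom, overlap_start, sense_id)
  pairs |>
    mutate(pair_id = sprintf("p%05d", seq_len(nrow(pairs)))) |>
    relocate(pair_id)
}
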