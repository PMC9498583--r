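# Small-RNA analysis: nat-siRNA precursor calling from pair overlap regions
# and TSS-anchored read densities by gene class.

#' Read small-RNA alignments from BED6
#'
#' Read length is `end - start` in on-disk half-open coordinates (the range
#' width in memory); lengths outside `len_range` are rejected.
#'
#' @param path BED file of stranded single-end alignments.
#' @param len_range admissible length range in nt (default 18--30).
#' @return stranded `GRanges`.
#' @export
read_smrna_bed <- function(path, len_range = c(18, 30)) {
  gr <- read_bed(path)
  w <- BiocGenerics::width(gr)
  if (any(w < len_range[1] | w > len_range[2])) {
    stop("validation error: read length outside ", len_range[1], "-",
         len_range[2], " nt in '", path, "'", call. = FALSE)
  }
  gr
}

#' Call nat-siRNA precursor candidates
#'
#' A read supports a pair iff its length is within `sirna_len` (20--24 nt by
#' default) and its interval is fully contained in the pair's overlap
#' (complementary) region; read strand is ignored, the overlap being
#' double-stranded by construction. A pair is flagged when supporting reads
#' reach `min_reads`.
#'
#' @param pairs pair tibble with `pair_id`, `chrom`, `overlap_start`,
#'   `overlap_end`.
#' @param reads stranded `GRanges` of small-RNA alignments.
#' @param min_reads minimum supporting reads to flag a pair (default 1).
#' @param sirna_len qualifying length range in nt (default `c(20, 24)`).
#' @return tibble `pair_id`, `n_supporting`, `precursor`.
#' @export
call_nat_sirna_precursors <- function(pairs, reads, min_reads = 1,
                                      sirna_len = c(20, 24)) {
  w <- BiocGenerics::width(reads)
  q <- reads[w >= sirna_len[1] & w <= sirna_len[2]]
  regions <- GenomicRanges::GRanges(
    pairs$chrom, IRanges::IRanges(pairs$overlap_start, pairs$overlap_end))
  hits <- GenomicRanges::findOverlaps(q, regions, type = "within",
                                      ignore.strand = TRUE)
  n <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(pairs))
  tibble(pair_id = pairs$pair_id, n_supporting = n,
         precursor = n >= min_reads)
}

#' Small-RNA density around TSS by gene class
#'
#' A read is counted for a gene iff it lies fully inside
#' `[TSS - window, TSS + window]` (chromosome-clipped). Per class the mean
#' is total counted reads over number of genes; the per-position profile
#' counts reads by the strand-oriented offset of their 5'-most base
#' (positive offsets downstream of the TSS), averaged over genes.
#'
#' @param reads stranded `GRanges` of small-RNA alignments.
#' @param annotation a [nat_annotation()].
#' @param classes named list mapping class name (e.g. `sense`, `antisense`,
#'   `non_NAT`) to transcript ids.
#' @param window half-width in bp (default 1000).
#' @return list with `means` (tibble `class`, `n_genes`, `total_reads`,
#'   `mean_reads`; mean is `NA` for an empty class) and `profile`
#'   (tibble `class`, `offset`, `mean_reads`).
#' @export
tss_smrna_density <- function(reads, annotation, classes, window = 1000) {
  tx <- annotation$transcripts
  means <- list(); prof <- list()
  for (cl in names(classes)) {
    ids <- classes[[cl]]
    if (length(ids) == 0) {
      means[[cl]] <- tibble(class = cl, n_genes = 0L, total_reads = 0L,
                            mean_reads = NA_real_)
      next
    }
    gr <- tx[match(ids, tx$transcript_id)]
    win <- tss_window(gr, window, annotation$chrom_sizes)
    hits <- GenomicRanges::findOverlaps(reads, win, type = "within",
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    means[[cl]] <- tibble(class = cl, n_genes = length(ids),
                          total_reads = length(qh),
                          mean_reads = length(qh) / length(ids))
    if (length(qh) > 0) {
      gstrand <- as.character(BiocGenerics::strand(win))[sh]
      tss <- win$tss[sh]
      off <- ifelse(gstrand == "+",
                    BiocGenerics::start(reads)[qh] - tss,
                    tss - BiocGenerics::end(reads)[qh])
      prof[[cl]] <- tibble(class = cl, offset = off) |>
        count(class, offset, name = "reads") |>
        mutate(mean_reads = reads / length(ids)) |>
        select(class, offset, mean_reads)
    }
  }
  list(means = bind_rows(means),
       profile = if (length(prof)) bind_rows(prof) else
         tibble(class = character(), offset = integer(),
                mean_reads = numeric()))
}

#' Length histogram of reads within regions
#'
#' @param reads `GRanges` of small-RNA alignments.
#' @param regions optional `GRanges`; when supplied only reads fully within
#'   a region are counted.
#' @param len_range histogram support (default 18--30 nt).
#' @return tibble `length`, `n` covering every length in `len_range`.
#' @export
smrna_length_distribution <- function(reads, regions = NULL,
                                      len_range = c(18, 30)) {
  if (!is.null(regions)) {
    keep <- GenomicRanges::countOverlaps(reads, regions, type = "within",
                                         ignore.strand = TRUE) > 0
    reads <- reads[keep]
  }
  support <- seq(len_range[1], len_range[2])
  w <- BiocGenerics::width(reads)
  tibble(length = support,
         n = vapply(support, function(l) sum(w == l), integer(1)))
}

#' Estimate small-RNA enrichment in pair overlap regions
#'
#' Ratio of read-start density (starts per bp) inside the merged overlap
#' regions to the density over the rest of the genome. Under the generator's
#' Poisson model its expectation is the planted enrichment fold.
#'
#' @param reads `GRanges` of small-RNA alignments.
#' @param regions `GRanges` of pair overlap regions.
#' @param chrom_sizes named chromosome lengths.
#' @return list `fold`, `n_inside`, `n_outside`, `bp_inside`, `bp_outside`.
#' @export
estimate_overlap_enrichment <- function(reads, regions, chrom_sizes) {
  merged <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  starts <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(reads),
    IRanges::IRanges(BiocGenerics::start(reads), width = 1))
  inside <- GenomicRanges::countOverlaps(starts, merged,
                                         ignore.strand = TRUE) > 0
  bp_in <- sum(BiocGenerics::width(merged))
  bp_out <- sum(chrom_sizes) - bp_in
  n_in <- sum(inside); n_out <- length(reads) - n_in
  list(fold = (n_in / bp_in) / (n_out / bp_out),
       n_inside = n_in, n_outside = n_out,
       bp_inside = bp_in, bp_outside = bp_out)
}
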