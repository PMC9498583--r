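# Fixture builders shared across the suite. Everything is constructed in
# code; no data files.

# annotation from a data frame of transcripts; single-exon unless an `exons`
# list-column (list of data.frames with start/end) is given
mk_annotation <- function(df, chrom_sizes = NULL) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$transcript_id <- df$transcript_id
  gr$gene_id <- if (!is.null(df[["gene_id"]])) df[["gene_id"]] else
    paste0("g_", df$transcript_id)
  gr$biotype <- if (!is.null(df[["biotype"]])) df[["biotype"]] else "unknown"
  ex <- lapply(seq_len(nrow(df)), function(i) {
    if (!is.null(df[["exons"]]) && !is.null(df[["exons"]][[i]])) {
      e <- df[["exons"]][[i]]
      GenomicRanges::GRanges(df$chrom[i], IRanges::IRanges(e$start, e$end))
    } else {
      GenomicRanges::GRanges(df$chrom[i],
                             IRanges::IRanges(df$start[i], df$end[i]))
    }
  })
  exl <- GenomicRanges::GRangesList(ex)
  names(exl) <- df$transcript_id
  natheat::nat_annotation(gr, exl, chrom_sizes = chrom_sizes)
}

# full 5-tissue x {0,1,5} h x 3-replicate design
mk_design <- function(tissues = c("Shoot", "Root", "RL", "Bud", "OF"),
                      timepoints = c(0, 1, 5), reps = 3) {
  d <- expand.grid(replicate = seq_len(reps), timepoint_h = timepoints,
                   tissue = tissues, stringsAsFactors = FALSE)[, 3:1]
  d$sample_id <- sprintf("%s_%gh_r%d", d$tissue, d$timepoint_h, d$replicate)
  tibble::as_tibble(d[, c("sample_id", "tissue", "timepoint_h", "replicate")])
}

# tpm_expression with constant baseline, overridable per transcript/sample
mk_expr <- function(ids, design = mk_design(), baseline = 10) {
  tpm <- matrix(baseline, nrow = length(ids), ncol = nrow(design),
                dimnames = list(ids, design$sample_id))
  structure(list(tpm = tpm, design = design), class = "tpm_expression")
}

# a diff_test-shaped tibble from per-transcript named log2fc/p vectors over
# given contrasts (tissue@timepoint)
mk_diff <- function(lfc_by_tx, p_by_tx, contrasts) {
  rows <- lapply(names(lfc_by_tx), function(id) {
    tibble::tibble(
      transcript_id = id,
      tissue = sub("@.*$", "", contrasts),
      timepoint_h = as.numeric(sub("^.*@", "", contrasts)),
      log2fc = lfc_by_tx[[id]],
      p = p_by_tx[[id]])
  })
  d <- dplyr::bind_rows(rows)
  d$status <- ifelse(d$p < 0.05 & d$log2fc >= 1, "up",
               ifelse(d$p < 0.05 & d$log2fc <= -1, "down", "ns"))
  d
}

random_transcripts <- function(n, n_chrom = 3, span = c(200, 3000),
                               genome = 5e5) {
  tibble::tibble(
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    start = sample.int(genome, n, replace = TRUE),
    width = sample(span[1]:span[2], n, replace = TRUE),
    end = start + width - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    transcript_id = sprintf("tx%05d", seq_len(n)),
    biotype = "mRNA")
}
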