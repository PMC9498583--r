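# Core genomic containers and interval arithmetic.
#
# Internal convention: all coordinates are held in GenomicRanges objects
# (1-based, closed intervals). On disk, GTF is 1-based inclusive and BED is
# 0-based half-open; rtracklayer performs both conversions.

#' Genome annotation container
#'
#' Bundles transcript spans, per-transcript exon structure and (optionally)
#' chromosome sizes. Transcript spans and exons are `GRanges`/`GRangesList`
#' in 1-based closed coordinates.
#'
#' @param transcripts `GRanges` with one range per transcript and metadata
#'   columns `transcript_id`, `gene_id`, `biotype`
#'   (`biotype` in `mRNA`, `lncRNA`, `unknown`).
#' @param exons `GRangesList` named by `transcript_id`; per transcript the
#'   exons must be sorted, non-overlapping and contained in the span.
#' @param chrom_sizes optional named integer vector of chromosome lengths;
#'   when supplied every span must fit inside its chromosome.
#'
#' @return An object of class `nat_annotation` (a list with elements
#'   `transcripts`, `exons`, `chrom_sizes`).
#' @export
nat_annotation <- function(transcripts, exons, chrom_sizes = NULL) {
  stopifnot(is(transcripts, "GRanges"), is(exons, "GRangesList"))
  obj <- structure(
    list(transcripts = transcripts, exons = exons, chrom_sizes = chrom_sizes),
    class = "nat_annotation"
  )
  validate_annotation(obj)
  obj
}

#' Validate a `nat_annotation`
#'
#' Checks id uniqueness, strand validity, exon containment/disjointness and
#' (when chromosome sizes are known) that spans fit their chromosomes.
#'
#' @param ann a `nat_annotation`.
#' @return `ann`, invisibly. Stops with a validation error otherwise.
#' @export
validate_annotation <- function(ann) {
  tx <- ann$transcripts
  need <- c("transcript_id", "gene_id", "biotype")
  missing_cols <- setdiff(need, names(S4Vectors::mcols(tx)))
  if (length(missing_cols) > 0) {
    stop("validation error: transcripts lack metadata column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- tx$transcript_id
  if (anyDuplicated(ids)) {
    stop("validation error: duplicated transcript_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (!all(as.character(BiocGenerics::strand(tx)) %in% c("+", "-"))) {
    stop("validation error: every transcript must be stranded (+ or -)",
         call. = FALSE)
  }
  if (any(BiocGenerics::width(tx) < 1)) {
    stop("validation error: zero-width transcript span", call. = FALSE)
  }
  if (!setequal(names(ann$exons), ids)) {
    stop("validation error: exon list names do not match transcript ids",
         call. = FALSE)
  }
  ex <- ann$exons[ids]
  if (!all(IRanges::isDisjoint(ex))) {
    bad <- ids[!IRanges::isDisjoint(ex)]
    stop("validation error: overlapping exons in: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  exu <- unlist(ex, use.names = TRUE)
  span_of_exon <- tx[match(names(exu), ids)]
  contained <- as.character(GenomicRanges::seqnames(exu)) ==
      as.character(GenomicRanges::seqnames(span_of_exon)) &
    BiocGenerics::start(exu) >= BiocGenerics::start(span_of_exon) &
    BiocGenerics::end(exu) <= BiocGenerics::end(span_of_exon)
  if (!all(contained)) {
    stop("validation error: exon outside transcript span for: ",
         paste(unique(names(exu)[!contained]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(ann$chrom_sizes)) {
    sz <- ann$chrom_sizes[as.character(GenomicRanges::seqnames(tx))]
    if (anyNA(sz)) {
      stop("validation error: transcript on unknown chromosome", call. = FALSE)
    }
    if (any(BiocGenerics::start(tx) < 1 | BiocGenerics::end(tx) > sz)) {
      stop("validation error: transcript span outside chromosome bounds",
           call. = FALSE)
    }
  }
  invisible(ann)
}

#' @export
print.nat_annotation <- function(x, ...) {
  cat("<nat_annotation> ", length(x$transcripts), " transcripts on ",
      length(unique(as.character(GenomicRanges::seqnames(x$transcripts)))),
      " chromosome(s)\n", sep = "")
  bt <- table(x$transcripts$biotype)
  cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of transcripts in an annotation
#' @param ann a `nat_annotation`.
#' @return integer count.
#' @export
n_transcripts <- function(ann) length(ann$transcripts)

#' Spliced (exonic) transcript length
#'
#' @param ann a `nat_annotation`.
#' @param ids transcript ids (default: all).
#' @return named integer vector of summed exon widths.
#' @export
exonic_length <- function(ann, ids = NULL) {
  if (is.null(ids)) ids <- ann$transcripts$transcript_id
  setNames(sum(BiocGenerics::width(ann$exons[ids])), ids)
}

#' Intron intervals of transcripts
#'
#' @param ann a `nat_annotation`.
#' @param ids transcript ids (default: all).
#' @return `GRangesList` of per-transcript introns (span minus exons);
#'   empty for single-exon transcripts.
#' @export
introns_of <- function(ann, ids = NULL) {
  if (is.null(ids)) ids <- ann$transcripts$transcript_id
  tx <- ann$transcripts[match(ids, ann$transcripts$transcript_id)]
  spans <- GenomicRanges::granges(tx)
  out <- GenomicRanges::psetdiff(spans, ann$exons[ids])
  names(out) <- ids
  out
}

#' Length of the intersection of two closed intervals
#'
#' Vectorised; intervals are 1-based inclusive `[start, end]`. Returns 0 for
#' disjoint intervals (including intervals that merely touch end-to-start in
#' half-open terms).
#'
#' @param start1,end1,start2,end2 interval bounds.
#' @return integer vector of intersection lengths (>= 0).
#' @export
overlap_length <- function(start1, end1, start2, end2) {
  stopifnot(all(end1 >= start1), all(end2 >= start2))
  pmax(0L, pmin(end1, end2) - pmax(start1, start2) + 1L)
}

#' Transcription start sites
#'
#' The TSS is the 5'-most transcribed base: span start on the plus strand,
#' span end on the minus strand.
#'
#' @param gr stranded `GRanges` of transcript spans.
#' @return integer vector of TSS positions (1-based).
#' @export
tss_of <- function(gr) {
  st <- as.character(BiocGenerics::strand(gr))
  if (!all(st %in% c("+", "-"))) {
    stop("tss_of: unstranded range", call. = FALSE)
  }
  ifelse(st == "+", BiocGenerics::start(gr), BiocGenerics::end(gr))
}

#' TSS-centred windows
#'
#' Builds `[TSS - window, TSS + window]` for every transcript, clipped at
#' chromosome edges when sizes are known. Strand is carried over from the
#' transcript so downstream profile code can orient offsets.
#'
#' @param gr stranded `GRanges` of transcript spans.
#' @param window half-width in bp (default 1000).
#' @param chrom_sizes optional named chromosome lengths used for clipping.
#' @return `GRanges` of clipped TSS windows, metadata column `tss`.
#' @export
tss_window <- function(gr, window = 1000, chrom_sizes = NULL) {
  tss <- tss_of(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  lo <- pmax(1L, tss - as.integer(window))
  hi <- tss + as.integer(window)
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes[chrom]
    hi <- pmin(hi, ifelse(is.na(sz), hi, sz))
  }
  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, hi),
                                strand = BiocGenerics::strand(gr))
  out$tss <- tss
  out
}

# --- readers / writers -------------------------------------------------------

#' Read transcript models from GTF
#'
#' Reads `transcript` and `exon` features; when no `transcript` features are
#' present, spans are inferred as the range of each transcript's exons. A
#' `biotype` attribute is honoured when present, otherwise biotype is
#' `unknown`. On-disk 1-based inclusive coordinates become 1-based closed
#' `GRanges` (the same convention), so no shifting is applied.
#'
#' @param path GTF file.
#' @param chrom_sizes optional named chromosome lengths for bound checking.
#' @return a validated [nat_annotation()].
#' @export
read_gtf <- function(path, chrom_sizes = NULL) {
  gr <- tryCatch(
    suppressWarnings(rtracklayer::import(path, format = "gtf")),
    error = function(e) stop("parse error in GTF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!"transcript_id" %in% names(S4Vectors::mcols(gr))) {
    stop("parse error in GTF '", path, "': no transcript_id attribute",
         call. = FALSE)
  }
  ex <- gr[gr$type == "exon"]
  tx <- gr[gr$type == "transcript"]
  if (length(ex) == 0) {
    stop("parse error in GTF '", path, "': no exon features", call. = FALSE)
  }
  exl <- GenomicRanges::split(GenomicRanges::granges(ex), ex$transcript_id)
  exl <- BiocGenerics::sort(exl)
  if (length(tx) == 0) {
    spans <- unlist(range(exl))
    meta <- as_tibble(S4Vectors::mcols(ex)) |>
      distinct(transcript_id, .keep_all = TRUE)
    meta <- meta[match(names(spans), meta$transcript_id), ]
    tx <- spans
    tx$transcript_id <- meta$transcript_id
    tx$gene_id <- meta$gene_id
    tx$biotype <- if ("biotype" %in% names(meta)) meta$biotype else "unknown"
  } else {
    keep <- GenomicRanges::granges(tx)
    keep$transcript_id <- tx$transcript_id
    keep$gene_id <- tx$gene_id
    keep$biotype <- if ("biotype" %in% names(S4Vectors::mcols(tx))) {
      tx$biotype
    } else {
      "unknown"
    }
    tx <- keep
  }
  tx$biotype[is.na(tx$biotype)] <- "unknown"
  o <- order(as.character(GenomicRanges::seqnames(tx)),
             BiocGenerics::start(tx), tx$transcript_id)
  tx <- tx[o]
  nat_annotation(tx, exl[tx$transcript_id], chrom_sizes = chrom_sizes)
}

#' Write an annotation as GTF
#'
#' Emits one `transcript` feature followed by its sorted `exon` features,
#' transcripts ordered by (chromosome, start, transcript_id) so output is
#' deterministic. Round-trips with [read_gtf()].
#'
#' @param ann a `nat_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  tx <- ann$transcripts
  o <- order(as.character(GenomicRanges::seqnames(tx)),
             BiocGenerics::start(tx), tx$transcript_id)
  tx <- tx[o]
  exl <- BiocGenerics::sort(ann$exons[tx$transcript_id])
  exu <- unlist(exl, use.names = TRUE)
  idx <- match(names(exu), tx$transcript_id)

  txgr <- GenomicRanges::granges(tx)
  txgr$type <- "transcript"
  txgr$transcript_id <- tx$transcript_id
  txgr$gene_id <- tx$gene_id
  txgr$biotype <- tx$biotype

  exgr <- GenomicRanges::granges(exu)
  BiocGenerics::strand(exgr) <- BiocGenerics::strand(tx)[idx]
  exgr$type <- "exon"
  exgr$transcript_id <- tx$transcript_id[idx]
  exgr$gene_id <- tx$gene_id[idx]
  exgr$biotype <- tx$biotype[idx]

  all <- c(txgr, exgr)
  names(all) <- NULL
  ord <- order(c(seq_along(txgr), idx),
               c(rep(0L, length(txgr)), rep(1L, length(exgr))),
               c(rep(0L, length(txgr)), BiocGenerics::start(exgr)))
  rtracklayer::export(all[ord], path, format = "gtf")
  invisible(path)
}

#' Read a BED file as `GRanges`
#'
#' 0-based half-open on disk; 1-based closed in memory (rtracklayer converts).
#'
#' @param path BED3/BED6 file.
#' @return `GRanges`.
#' @export
read_bed <- function(path) {
  tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("parse error in BED '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
}

#' Write `GRanges` as BED6
#'
#' Records are sorted by (chromosome, start, name) for deterministic output.
#'
#' @param gr `GRanges`; a `name` metadata column is used when present.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  if (is.null(gr$name)) gr$name <- sprintf("r%06d", seq_along(gr))
  if (is.null(gr$score)) gr$score <- 0L
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             BiocGenerics::start(gr), gr$name)
  rtracklayer::export(gr[o], path, format = "bed")
  invisible(path)
}

#' Compare two annotations for semantic equality
#'
#' Equality of transcript ids, gene ids, biotypes, spans, strands and exon
#' structures, irrespective of storage order. Used to verify the GTF
#' round-trip contract.
#'
#' @param a,b `nat_annotation` objects.
#' @return `TRUE` or `FALSE`.
#' @export
annotations_equal <- function(a, b) {
  ia <- order(a$transcripts$transcript_id)
  ib <- order(b$transcripts$transcript_id)
  ta <- a$transcripts[ia]; tb <- b$transcripts[ib]
  if (length(ta) != length(tb)) return(FALSE)
  same_tx <- all(
    ta$transcript_id == tb$transcript_id,
    ta$gene_id == tb$gene_id,
    ta$biotype == tb$biotype,
    as.character(GenomicRanges::seqnames(ta)) ==
      as.character(GenomicRanges::seqnames(tb)),
    as.character(BiocGenerics::strand(ta)) ==
      as.character(BiocGenerics::strand(tb)),
    BiocGenerics::start(ta) == BiocGenerics::start(tb),
    BiocGenerics::end(ta) == BiocGenerics::end(tb)
  )
  if (!same_tx) return(FALSE)
  ea <- BiocGenerics::sort(a$exons[ta$transcript_id])
  eb <- BiocGenerics::sort(b$exons[tb$transcript_id])
  identical(as.list(BiocGenerics::start(ea)), as.list(BiocGenerics::start(eb))) &&
    identical(as.list(BiocGenerics::end(ea)), as.list(BiocGenerics::end(eb)))
}

# TSV plumbing shared by every module: readr with explicit, quiet types.
read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Atomically write a TSV
#'
#' Writes to a temporary sibling and renames, so partial outputs never
#' clobber previous results.
#'
#' @param x data frame.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_tsv_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_tsv(x, tmp, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read chromosome sizes from a two-column TSV
#' @param path TSV with columns `chrom`, `length`.
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  d <- read_tsv_quiet(path)
  setNames(as.integer(d$length), d$chrom)
}
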