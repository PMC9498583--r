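# Synthetic dataset generator.
#
# Emits a complete toy study -- annotation with planted antisense geometry,
# TPM expression with planted heat fold-changes, small-RNA reads enriched in
# pair overlap regions, TSS-proximal histone peaks, context-specific
# methylation and promoters with planted heat-shock elements -- together with
# a truth table, so every pipeline stage can be validated end to end.
#
# Determinism contract: identical config (including seed) gives identical
# output. Each stage draws from its own derived seed (seed + stage index) so
# stages are independently reproducible.

#' Simulation configuration
#'
#' All knobs of the synthetic dataset, with defaults chosen to emulate the
#' study design the pipeline targets: 5 tissues (Shoot, Root, RL, Bud, OF),
#' heat timepoints 0/1/5 h with 3 replicates, a predominantly enclosed
#' pair-configuration mix, a mostly mRNA-lncRNA pair-type mix, log-normal
#' TPM with planted log2 fold-changes well above the 2-fold calling
#' threshold, 2.4-fold small-RNA enrichment in pair overlap regions, and
#' CpG > CHH > CHG methylation context means.
#'
#' @param seed integer seed; every stage derives its stream from it.
#' @param n_gene_loci number of gene loci to lay out.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param frac_with_antisense proportion of gene loci given an overlapping
#'   opposite-strand partner (>= 50 bp overlap, guaranteed geometrically).
#' @param configuration_mix named probabilities over
#'   `enclosed`, `convergent`, `divergent`; must sum to 1.
#' @param pair_type_mix named probabilities over `mRNA-mRNA`, `mRNA-lncRNA`,
#'   `lncRNA-lncRNA`.
#' @param frac_heat_responsive proportion of pairs (and isolated genes) with
#'   a planted heat effect.
#' @param frac_tissue_specific proportion of responsive pairs/genes whose
#'   effect is planted in a single random tissue; the rest respond in all
#'   tissues.
#' @param planted_log2fc_range range of planted |log2FC|; the minimum must be
#'   >= 1 so planted effects exceed the 2-fold calling threshold.
#' @param frac_up probability a planted effect is an induction.
#' @param attenuation_5h multiplier applied to planted log2FC at 5 h
#'   (1 = no attenuation).
#' @param replicate_cv coefficient of variation of multiplicative log-normal
#'   replicate noise (0 = noise-free).
#' @param baseline_log_tpm_mean,baseline_log_tpm_sd natural-log parameters of
#'   baseline TPM.
#' @param frac_concordant proportion of responsive pairs whose antisense
#'   effect shares the sense sign.
#' @param smrna_background_rate genome-wide small-RNA read starts per kb.
#' @param smrna_overlap_enrichment fold enrichment of read-start rate inside
#'   pair overlap regions.
#' @param smrna_len_weights sampling weights for read lengths 18--30 nt.
#' @param frac_smrna_enriched proportion of pairs whose overlap is enriched.
#' @param marks histone mark names.
#' @param frac_tss_marked per-mark probability that a pair-member gene
#'   carries a peak overlapping its TSS window (scalar or named per mark).
#' @param methylation_context_means named mean methylation level per context.
#' @param meth_context_probs sampling probabilities of contexts per cytosine.
#' @param meth_sites_per_kb cytosine density over gene body plus 1-kb promoter.
#' @param meth_conc Beta concentration of per-cytosine levels around the mean.
#' @param meth_shift absolute mean methylation shift planted at heated
#'   timepoints.
#' @param frac_meth_down proportion of genes whose methylation shifts down.
#' @param meth_timepoints methylation assay timepoints in hours.
#' @param n_lincrna,n_incrna,n_short_decoys,n_blacklist_decoys,n_coding_decoys
#'   counts of intergenic lncRNAs, intronic lncRNAs, sub-200-nt decoys,
#'   blacklist-overlapping decoys and coding-labelled decoys.
#' @param frac_hse probability a responsive sense promoter carries a planted
#'   heat-shock element.
#' @param promoter_len promoter sequence length in bp.
#' @param tissues,timepoints,n_replicates expression design.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_gene_loci = 200L,
                       chrom_sizes = c(chr1 = 1500000L, chr2 = 1500000L),
                       frac_with_antisense = 0.5,
                       configuration_mix = c(enclosed = 0.645,
                                             convergent = 0.2,
                                             divergent = 0.155),
                       pair_type_mix = c("mRNA-mRNA" = 0.03,
                                         "mRNA-lncRNA" = 0.91,
                                         "lncRNA-lncRNA" = 0.06),
                       frac_heat_responsive = 0.3,
                       frac_tissue_specific = 0.7,
                       planted_log2fc_range = c(1.5, 4),
                       frac_up = 0.7,
                       attenuation_5h = 1.0,
                       replicate_cv = 0.2,
                       baseline_log_tpm_mean = 3,
                       baseline_log_tpm_sd = 1,
                       frac_concordant = 0.8,
                       smrna_background_rate = 5,
                       smrna_overlap_enrichment = 2.4,
                       smrna_len_weights = setNames(rep(1, 13), 18:30),
                       frac_smrna_enriched = 1.0,
                       marks = c("H3K27me2", "H3K27me3", "H3K36me2",
                                 "H3K4me1", "H3K4me2", "H3K4me3"),
                       frac_tss_marked = 0.5,
                       methylation_context_means = c(CpG = 0.30, CHH = 0.15,
                                                     CHG = 0.08),
                       meth_context_probs = c(CpG = 0.35, CHG = 0.30,
                                              CHH = 0.35),
                       meth_sites_per_kb = 20,
                       meth_conc = 50,
                       meth_shift = 0.05,
                       frac_meth_down = 0.6,
                       meth_timepoints = c(0, 6, 12, 24),
                       n_lincrna = 20L,
                       n_incrna = 10L,
                       n_short_decoys = 8L,
                       n_blacklist_decoys = 8L,
                       n_coding_decoys = 8L,
                       frac_hse = 0.4,
                       promoter_len = 1000L,
                       tissues = c("Shoot", "Root", "RL", "Bud", "OF"),
                       timepoints = c(0, 1, 5),
                       n_replicates = 3L) {
  cfg <- as.list(environment())
  props <- c(frac_with_antisense, frac_heat_responsive, frac_tissue_specific,
             frac_up, frac_concordant, frac_smrna_enriched, frac_meth_down,
             frac_hse)
  if (any(props < 0 | props > 1)) {
    stop("config error: proportions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(configuration_mix) - 1) > 1e-8) {
    stop("config error: configuration_mix must sum to 1", call. = FALSE)
  }
  if (abs(sum(pair_type_mix) - 1) > 1e-8) {
    stop("config error: pair_type_mix must sum to 1", call. = FALSE)
  }
  if (min(planted_log2fc_range) < 1) {
    stop("config error: planted |log2FC| must be >= 1 so planted effects ",
         "exceed the 2-fold calling threshold", call. = FALSE)
  }
  if (replicate_cv < 0) stop("config error: replicate_cv < 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# expand per-mark marking probability
mark_probs <- function(cfg) {
  p <- cfg$frac_tss_marked
  if (length(p) == 1 && is.null(names(p))) p <- setNames(rep(p, length(cfg$marks)), cfg$marks)
  p[cfg$marks]
}

#' Generate a synthetic annotation with planted antisense geometry
#'
#' Lays out gene loci along the configured chromosomes. A configured fraction
#' receives an opposite-strand partner whose span overlap (>= 50 bp) realises
#' a configuration drawn from `configuration_mix`: `enclosed` partners sit
#' fully inside the gene span; `convergent` partners overlap the gene's 3'
#' end; `divergent` partners overlap its 5' end. Also emits isolated genes,
#' intergenic lncRNAs, intronic lncRNAs (same strand as their host, inside an
#' intron), sub-200-nt decoys, blacklist-overlapping decoys and
#' coding-labelled decoys, plus the blacklist itself, conservation scores
#' (sense scored higher) and per-pair/per-transcript planted heat effects.
#'
#' @param cfg a [sim_config()].
#' @return list of class `nat_sim` with elements `annotation`
#'   ([nat_annotation()]), `truth` (list of tibbles `transcripts`, `pairs`,
#'   `planted_lfc`), `blacklist` (`GRanges`), `coding_labels` (tibble),
#'   `conservation` (tibble) and `cfg`.
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)

  chroms <- names(cfg$chrom_sizes)
  nc <- length(chroms)
  cursor <- setNames(rep(2000L, nc), chroms)
  margin <- 1300L

  n_gene <- cfg$n_gene_loci
  has_anti <- runif(n_gene) < cfg$frac_with_antisense
  host_pool <- which(!has_anti)
  n_inc <- min(cfg$n_incrna, length(host_pool))
  inc_hosts <- if (n_inc > 0) sort(sample(host_pool, n_inc)) else integer(0)

  slots <- c(rep("gene", n_gene), rep("linc", cfg$n_lincrna),
             rep("short", cfg$n_short_decoys),
             rep("blk", cfg$n_blacklist_decoys),
             rep("cod", cfg$n_coding_decoys))

  tx_rows <- list()       # chrom, start, end, strand, tx_id, gene_id, biotype
  exon_rows <- list()     # tx_id, start, end
  truth_tx <- list()
  truth_pairs <- list()
  bl_rows <- list()
  gene_i <- 0L

  add_tx <- function(chrom, s, e, strand, tx_id, gene_id, biotype, exons) {
    tx_rows[[length(tx_rows) + 1L]] <<- list(
      chrom = chrom, start = s, end = e, strand = strand,
      transcript_id = tx_id, gene_id = gene_id, biotype = biotype)
    n <- length(exons$start)
    exon_rows[[length(exon_rows) + 1L]] <<- list(
      transcript_id = rep(tx_id, n), start = exons$start, end = exons$end)
  }
  truth_row <- function(tx_id, gene_id, class, biotype, expected_status,
                        pair_id = NA_character_, pair_role = NA_character_) {
    truth_tx[[length(truth_tx) + 1L]] <<- list(
      transcript_id = tx_id, gene_id = gene_id, class = class,
      biotype = biotype, expected_status = expected_status,
      pair_id = pair_id, pair_role = pair_role)
  }

  # split a span [s, e] into n_ex exons with intron gaps, all segments >= 60 bp
  make_exons <- function(s, e, n_ex) {
    L <- e - s + 1L
    if (n_ex == 1L || L < 140L * n_ex) return(list(start = s, end = e))
    nseg <- 2L * n_ex - 1L
    w <- runif(nseg, 0.5, 1.5)
    lens <- pmax(60L, as.integer(round(w / sum(w) * L)))
    lens[nseg] <- L - sum(lens[-nseg])
    if (lens[nseg] < 60L) return(list(start = s, end = e))
    ends <- s - 1L + cumsum(lens)
    starts <- c(s, ends[-nseg] + 1L)
    keep <- seq(1L, nseg, by = 2L)
    list(start = starts[keep], end = ends[keep])
  }

  for (i in seq_along(slots)) {
    kind <- slots[i]
    chrom <- chroms[((i - 1L) %% nc) + 1L]
    size <- cfg$chrom_sizes[[chrom]]
    s0 <- cursor[[chrom]] + margin

    if (kind == "gene") {
      gene_i <- gene_i + 1L
      gi <- gene_i
      is_host <- gi %in% inc_hosts
      L <- if (is_host) sample(2000:3000, 1) else sample(1000:3000, 1)
      strand <- sample(c("+", "-"), 1)
      s <- s0; e <- s + L - 1L
      gid <- sprintf("g%04d", gi)
      tid <- sprintf("t%04d", gi)
      anti <- has_anti[gi]
      ptype <- if (anti) {
        sample(names(cfg$pair_type_mix), 1, prob = cfg$pair_type_mix)
      } else NA_character_
      gene_bt <- if (!is.na(ptype) && ptype == "lncRNA-lncRNA") "lncRNA" else "mRNA"

      if (is_host) {
        # fixed 3-exon structure with a 600-bp intron 1 hosting an incRNA
        ex <- list(start = c(s, s + 900L, s + 1600L),
                   end = c(s + 299L, s + 1199L, e))
      } else {
        ex <- make_exons(s, e, sample(1:3, 1, prob = c(0.4, 0.3, 0.3)))
      }
      add_tx(chrom, s, e, strand, tid, gid, gene_bt, ex)
      truth_row(tid, gid, "gene", gene_bt,
                if (gene_bt == "mRNA") "annotated_mRNA" else "lincRNA")

      if (is_host) {
        iid <- sprintf("inc%03d", match(gi, inc_hosts))
        is_ <- s + 420L; ie_ <- is_ + 299L
        add_tx(chrom, is_, ie_, strand, iid, paste0(gid, "_inc"), "unknown",
               list(start = is_, end = ie_))
        truth_row(iid, paste0(gid, "_inc"), "incRNA", "unknown", "incRNA")
      }

      if (anti) {
        config <- sample(names(cfg$configuration_mix), 1,
                         prob = cfg$configuration_mix)
        if (config == "enclosed") {
          plen <- max(250L, as.integer(round(L * runif(1, 0.2, 0.6))))
          off <- sample.int(L - plen + 1L, 1) - 1L
          ps <- s + off; pe <- ps + plen - 1L
        } else {
          ov <- sample(60:min(500L, L - 100L), 1)
          ext <- sample(400:1200, 1)
          at_3prime <- (config == "convergent")
          right_side <- if (strand == "+") at_3prime else !at_3prime
          if (right_side) { ps <- e - ov + 1L; pe <- e + ext }
          else            { ps <- s - ext;     pe <- s + ov - 1L }
        }
        pid <- sprintf("pair%04d", gi)
        aid <- sprintf("a%04d", gi)
        a_strand <- if (strand == "+") "-" else "+"
        a_bt <- if (ptype == "mRNA-mRNA") "mRNA" else "lncRNA"
        add_tx(chrom, ps, pe, a_strand, aid, paste0(gid, "_as"), a_bt,
               list(start = ps, end = pe))
        exp_status <- if (a_bt == "mRNA") "annotated_mRNA"
          else if (gene_bt == "mRNA") "NAT_candidate" else "lincRNA"
        truth_row(aid, paste0(gid, "_as"), "antisense", a_bt, exp_status,
                  pair_id = pid, pair_role = "antisense")
        truth_tx[[length(truth_tx) - 1L]][["pair_id"]] <- pid
        truth_tx[[length(truth_tx) - 1L]][["pair_role"]] <- "sense"
        truth_pairs[[length(truth_pairs) + 1L]] <- list(
          pair_id = pid, sense_id = tid, antisense_id = aid, chrom = chrom,
          overlap_start = max(s, ps), overlap_end = min(e, pe),
          configuration = config, pair_type = ptype)
        e_right <- max(e, pe)
      } else {
        e_right <- e
      }
      cursor[[chrom]] <- e_right + margin + sample(500:1500, 1)
    } else if (kind == "linc") {
      L <- sample(300:1500, 1)
      s <- s0; e <- s + L - 1L
      tid <- sprintf("linc%03d", i)
      add_tx(chrom, s, e, sample(c("+", "-"), 1), tid, paste0("g_", tid),
             "unknown", list(start = s, end = e))
      truth_row(tid, paste0("g_", tid), "lincRNA", "unknown", "lincRNA")
      cursor[[chrom]] <- e + margin + sample(500:1500, 1)
    } else if (kind == "short") {
      s <- s0; e <- s + 149L
      tid <- sprintf("short%03d", i)
      add_tx(chrom, s, e, sample(c("+", "-"), 1), tid, paste0("g_", tid),
             "unknown", list(start = s, end = e))
      truth_row(tid, paste0("g_", tid), "short_decoy", "unknown",
                "discarded_short")
      cursor[[chrom]] <- e + margin + sample(500:1500, 1)
    } else if (kind == "blk") {
      # a structural-RNA blacklist interval plus a decoy transcript crossing it
      bl_rows[[length(bl_rows) + 1L]] <- list(
        chrom = chrom, start = s0, end = s0 + 199L)
      s <- s0 + 100L; e <- s + 450L
      tid <- sprintf("blk%03d", i)
      add_tx(chrom, s, e, sample(c("+", "-"), 1), tid, paste0("g_", tid),
             "unknown", list(start = s, end = e))
      truth_row(tid, paste0("g_", tid), "blacklist_decoy", "unknown",
                "discarded_blacklist")
      cursor[[chrom]] <- e + margin + sample(500:1500, 1)
    } else { # coding-labelled decoy
      L <- sample(400:1200, 1)
      s <- s0; e <- s + L - 1L
      tid <- sprintf("cod%03d", i)
      add_tx(chrom, s, e, sample(c("+", "-"), 1), tid, paste0("g_", tid),
             "unknown", list(start = s, end = e))
      truth_row(tid, paste0("g_", tid), "coding_decoy", "unknown",
                "discarded_coding")
      cursor[[chrom]] <- e + margin + sample(500:1500, 1)
    }
    if (cursor[[chrom]] > size - 2L * margin) {
      stop("config error: infeasible packing -- loci do not fit chrom_sizes",
           call. = FALSE)
    }
  }

  txd <- bind_rows(tx_rows)
  exd <- bind_rows(exon_rows)
  truth_tx <- bind_rows(truth_tx)
  truth_pairs <- if (length(truth_pairs)) bind_rows(truth_pairs) else
    tibble(pair_id = character(), sense_id = character(),
           antisense_id = character(), chrom = character(),
           overlap_start = integer(), overlap_end = integer(),
           configuration = character(), pair_type = character())
  truth_pairs <- truth_pairs |>
    mutate(overlap_len = overlap_end - overlap_start + 1L)

  gr <- GenomicRanges::GRanges(
    txd$chrom, IRanges::IRanges(txd$start, txd$end), strand = txd$strand)
  gr$transcript_id <- txd$transcript_id
  gr$gene_id <- txd$gene_id
  gr$biotype <- txd$biotype
  exl <- GenomicRanges::split(
    GenomicRanges::GRanges(
      txd$chrom[match(exd$transcript_id, txd$transcript_id)],
      IRanges::IRanges(exd$start, exd$end)),
    factor(exd$transcript_id, levels = txd$transcript_id))
  ann <- nat_annotation(gr, exl, chrom_sizes = cfg$chrom_sizes)

  # planted heat effects: pairs and isolated genes
  truth_pairs <- truth_pairs |>
    mutate(responsive = runif(n()) < cfg$frac_heat_responsive,
           concordant = runif(n()) < cfg$frac_concordant,
           smrna_enriched = runif(n()) < cfg$frac_smrna_enriched)
  lfc_rows <- list()
  # effects are planted with tissue-to-tissue variation (shared between the
  # two pair members up to a scale factor) so fold-change vectors carry the
  # planted concordance sign; a configurable share responds in one tissue
  # only, the rest in all tissues
  plant_lfc <- function(tx_id, base, ts, m) {
    nt <- length(ts)
    list(transcript_id = rep(tx_id, 2L * nt),
         tissue = rep(ts, 2L),
         timepoint_h = rep(c(1, 5), each = nt),
         log2fc = c(base * m, base * m * cfg$attenuation_5h))
  }
  draw_base <- function() {
    runif(1, cfg$planted_log2fc_range[1], cfg$planted_log2fc_range[2]) *
      if (runif(1) < cfg$frac_up) 1 else -1
  }
  draw_tissues <- function() {
    if (runif(1) < cfg$frac_tissue_specific) sample(cfg$tissues, 1)
    else cfg$tissues
  }
  for (k in seq_len(nrow(truth_pairs))) {
    if (!truth_pairs$responsive[k]) next
    base <- draw_base()
    ts <- draw_tissues()
    m <- runif(length(ts), 0.5, 1.5)
    a_base <- base * (if (truth_pairs$concordant[k]) 1 else -1) *
      runif(1, 0.8, 1.2)
    lfc_rows[[length(lfc_rows) + 1L]] <-
      plant_lfc(truth_pairs$sense_id[k], base, ts, m)
    lfc_rows[[length(lfc_rows) + 1L]] <-
      plant_lfc(truth_pairs$antisense_id[k], a_base, ts, m)
  }
  isolated <- truth_tx |>
    filter(class == "gene", is.na(pair_id))
  iso_resp <- runif(nrow(isolated)) < cfg$frac_heat_responsive
  for (k in which(iso_resp)) {
    ts <- draw_tissues()
    lfc_rows[[length(lfc_rows) + 1L]] <-
      plant_lfc(isolated$transcript_id[k], draw_base(), ts,
                runif(length(ts), 0.5, 1.5))
  }
  planted_lfc <- if (length(lfc_rows)) bind_rows(lfc_rows) else
    tibble(transcript_id = character(), tissue = character(),
           timepoint_h = numeric(), log2fc = numeric())
  truth_tx <- truth_tx |>
    mutate(responsive = transcript_id %in% planted_lfc$transcript_id)

  blacklist <- if (length(bl_rows)) {
    bd <- bind_rows(bl_rows)
    GenomicRanges::GRanges(bd$chrom, IRanges::IRanges(bd$start, bd$end))
  } else GenomicRanges::GRanges()

  coding_labels <- truth_tx |>
    filter(biotype != "mRNA") |>
    transmute(transcript_id,
              label = ifelse(class == "coding_decoy", "coding", "noncoding"))

  conservation <- bind_rows(
    truth_pairs |> transmute(transcript_id = sense_id,
                             score = round(runif(n(), 0.6, 1.0), 4)),
    truth_pairs |> transmute(transcript_id = antisense_id,
                             score = round(runif(n(), 0.0, 0.4), 4)))

  structure(
    list(annotation = ann,
         truth = list(transcripts = truth_tx, pairs = truth_pairs,
                      planted_lfc = planted_lfc),
         blacklist = blacklist, coding_labels = coding_labels,
         conservation = conservation, cfg = cfg),
    class = "nat_sim")
}

#' Simulate a TPM expression matrix with planted heat effects
#'
#' `TPM(t, s) = baseline(t) * 2^lfc(t, tissue(s), time(s)) * noise`, with
#' log-normal baseline `exp(N(mean, sd))`, the planted log2 fold-change
#' applied at heated timepoints of responsive transcripts, and multiplicative
#' log-normal replicate noise with unit mean and the configured CV
#' (`replicate_cv = 0` gives exact, noise-free ratios).
#'
#' @param sim a `nat_sim` from [generate_annotation()].
#' @param cfg a [sim_config()] (defaults to the one stored in `sim`).
#' @return list of class `tpm_expression`: `tpm` (matrix, transcripts x
#'   samples) and `design` (tibble `sample_id`, `tissue`, `timepoint_h`,
#'   `replicate`).
#' @export
simulate_expression <- function(sim, cfg = sim$cfg) {
  set.seed(cfg$seed + 2L)
  design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        timepoint_h = cfg$timepoints,
                        tissue = cfg$tissues,
                        stringsAsFactors = FALSE)[, 3:1] |>
    as_tibble() |>
    mutate(sample_id = sprintf("%s_%gh_r%d", tissue, timepoint_h, replicate)) |>
    select(sample_id, tissue, timepoint_h, replicate)

  ids <- sim$annotation$transcripts$transcript_id
  n <- length(ids); ns <- nrow(design)
  baseline <- exp(rnorm(n, cfg$baseline_log_tpm_mean, cfg$baseline_log_tpm_sd))

  lfc <- matrix(0, n, ns, dimnames = list(ids, design$sample_id))
  pl <- sim$truth$planted_lfc
  if (nrow(pl) > 0) {
    col_key <- paste(design$tissue, design$timepoint_h)
    row_i <- match(pl$transcript_id, ids)
    for (j in seq_len(ns)) {
      hit <- paste(pl$tissue, pl$timepoint_h) == col_key[j]
      if (any(hit)) lfc[row_i[hit], j] <- pl$log2fc[hit]
    }
  }

  if (cfg$replicate_cv > 0) {
    sig <- sqrt(log(1 + cfg$replicate_cv^2))
    noise <- matrix(exp(rnorm(n * ns, -sig^2 / 2, sig)), n, ns)
  } else {
    noise <- 1
  }
  tpm <- baseline * 2^lfc * noise
  dimnames(tpm) <- list(ids, design$sample_id)
  structure(list(tpm = tpm, design = design), class = "tpm_expression")
}

#' Simulate small-RNA reads enriched in pair overlap regions
#'
#' Read starts are Poisson with the background rate genome-wide and
#' `smrna_overlap_enrichment` times that rate inside the overlap regions of
#' enriched pairs (extra reads are placed fully inside the region). Lengths
#' are drawn from `smrna_len_weights` over 18--30 nt so both qualifying
#' (20--24 nt) and disqualifying lengths occur; strand is uniform.
#'
#' @inheritParams simulate_expression
#' @return stranded `GRanges` of reads with `name` and `score` columns.
#' @export
simulate_smrna <- function(sim, cfg = sim$cfg) {
  set.seed(cfg$seed + 3L)
  lens_support <- 18:30
  w <- cfg$smrna_len_weights
  rows <- list()
  for (chrom in names(cfg$chrom_sizes)) {
    size <- cfg$chrom_sizes[[chrom]]
    n_bg <- rpois(1, cfg$smrna_background_rate * size / 1000)
    if (n_bg > 0) {
      rows[[length(rows) + 1L]] <- tibble(
        chrom = chrom,
        start = sample.int(size - 30L, n_bg, replace = TRUE),
        len = sample(lens_support, n_bg, replace = TRUE, prob = w),
        strand = sample(c("+", "-"), n_bg, replace = TRUE))
    }
  }
  enr <- sim$truth$pairs |> filter(smrna_enriched)
  extra_rate <- (cfg$smrna_overlap_enrichment - 1) * cfg$smrna_background_rate
  if (nrow(enr) > 0 && extra_rate > 0) {
    for (k in seq_len(nrow(enr))) {
      rl <- enr$overlap_end[k] - enr$overlap_start[k] + 1L
      n_e <- rpois(1, extra_rate * rl / 1000)
      if (n_e == 0) next
      len <- sample(lens_support, n_e, replace = TRUE, prob = w)
      start <- enr$overlap_start[k] +
        vapply(pmax(1L, rl - len + 1L),
               function(m) sample.int(m, 1) - 1L, integer(1))
      rows[[length(rows) + 1L]] <- tibble(
        chrom = enr$chrom[k], start = start, len = len,
        strand = sample(c("+", "-"), n_e, replace = TRUE))
    }
  }
  d <- bind_rows(rows) |> arrange(chrom, start, len)
  gr <- GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(d$start, width = d$len), strand = d$strand)
  gr$name <- sprintf("sr%06d", seq_along(gr))
  gr$score <- 0L
  gr
}

#' Simulate histone-mark peaks and methylation tables
#'
#' Each mark independently places a +/-150-bp peak at the TSS of a
#' `frac_tss_marked` share of all transcripts. Methylation sites are
#' scattered over each pair member's gene body plus 1-kb promoter;
#' per-cytosine levels are Beta-distributed around the context mean, with a
#' planted per-gene shift of +/-`meth_shift` at heated timepoints
#' (`frac_meth_down` of genes shift down).
#'
#' @inheritParams simulate_expression
#' @return list with `peaks` (named list of `GRanges`, one per mark),
#'   `methylation` (tibble `chrom`, `pos`, `context`, `level`,
#'   `timepoint_h`), `peak_truth` and `meth_truth` tibbles.
#' @export
simulate_chromatin <- function(sim, cfg = sim$cfg) {
  set.seed(cfg$seed + 4L)
  tx <- sim$annotation$transcripts
  sizes <- cfg$chrom_sizes
  all_tss <- tss_of(tx)
  all_chrom <- as.character(GenomicRanges::seqnames(tx))

  pp <- mark_probs(cfg)
  peaks <- list(); peak_truth <- list()
  for (m in cfg$marks) {
    marked <- runif(length(tx)) < pp[[m]]
    peaks[[m]] <- GenomicRanges::GRanges(
      all_chrom[marked],
      IRanges::IRanges(pmax(1L, all_tss[marked] - 150L),
                       pmin(sizes[all_chrom[marked]], all_tss[marked] + 150L)))
    peak_truth[[m]] <- tibble(transcript_id = tx$transcript_id,
                              mark = m, marked = marked)
  }

  members <- sim$truth$transcripts |> filter(!is.na(pair_id))
  mgr <- tx[match(members$transcript_id, tx$transcript_id)]
  chrom <- as.character(GenomicRanges::seqnames(mgr))
  meth <- list(); meth_truth <- list()
  ctx_names <- names(cfg$methylation_context_means)
  for (k in seq_along(mgr)) {
    st <- as.character(BiocGenerics::strand(mgr[k]))
    rs <- if (st == "+") BiocGenerics::start(mgr[k]) - 1000L else BiocGenerics::start(mgr[k])
    re <- if (st == "+") BiocGenerics::end(mgr[k]) else BiocGenerics::end(mgr[k]) + 1000L
    rs <- max(1L, rs); re <- min(sizes[[chrom[k]]], re)
    n_sites <- max(3L, as.integer(round((re - rs + 1L) / 1000 * cfg$meth_sites_per_kb)))
    pos <- sort(sample(rs:re, n_sites))
    ctx <- sample(names(cfg$meth_context_probs), n_sites, replace = TRUE,
                  prob = cfg$meth_context_probs)
    dir <- if (runif(1) < cfg$frac_meth_down) -1 else 1
    meth_truth[[k]] <- tibble(transcript_id = members$transcript_id[k],
                              direction = dir)
    for (tp in cfg$meth_timepoints) {
      mu <- cfg$methylation_context_means[ctx] +
        (tp > 0) * dir * cfg$meth_shift
      mu <- pmin(0.99, pmax(0.01, mu))
      meth[[length(meth) + 1L]] <- tibble(
        chrom = chrom[k], pos = pos, context = ctx,
        level = rbeta(n_sites, mu * cfg$meth_conc, (1 - mu) * cfg$meth_conc),
        timepoint_h = tp)
    }
  }
  list(peaks = peaks,
       methylation = if (length(meth)) bind_rows(meth) else
         tibble(chrom = character(), pos = integer(), context = character(),
                level = numeric(), timepoint_h = numeric()),
       peak_truth = bind_rows(peak_truth),
       meth_truth = bind_rows(meth_truth))
}

#' Simulate promoter sequences with planted heat-shock elements
#'
#' Random ACGT promoters for every pair sense member; a `frac_hse` share of
#' responsive sense promoters receives one planted HSE (canonical double,
#' canonical triple or non-canonical, consensus sequence) at a recorded
#' position.
#'
#' @inheritParams simulate_expression
#' @return list with `promoters` (`DNAStringSet` named by transcript id) and
#'   `planted` (tibble `transcript_id`, `start`, `kind`).
#' @export
simulate_promoters <- function(sim, cfg = sim$cfg) {
  set.seed(cfg$seed + 5L)
  # consensus realisations of nGAAnnTTCn, nGAAnnTTCnnGAAn, nGAAnnnnTTCn
  motifs <- c(canonical_double = "TGAACTTTCA",
              canonical_triple = "TGAACTTTCATGAAT",
              non_canonical = "TGAACAGTTTCA")
  senses <- sim$truth$pairs$sense_id
  resp <- sim$truth$pairs$responsive
  seqs <- character(length(senses))
  planted <- list()
  pad <- "CCCCC"   # insulator flanks: C runs cannot extend a planted
                   # element into a longer HSE variant
  for (k in seq_along(senses)) {
    s <- paste(sample(c("A", "C", "G", "T"), cfg$promoter_len, replace = TRUE),
               collapse = "")
    if (resp[k] && runif(1) < cfg$frac_hse) {
      kind <- sample(names(motifs), 1)
      mo <- paste0(pad, motifs[[kind]], pad)
      pos <- sample.int(cfg$promoter_len - nchar(mo) + 1L, 1)
      substr(s, pos, pos + nchar(mo) - 1L) <- mo
      planted[[length(planted) + 1L]] <- tibble(
        transcript_id = senses[k], start = pos + nchar(pad), kind = kind)
    }
    seqs[k] <- s
  }
  proms <- Biostrings::DNAStringSet(setNames(seqs, senses))
  list(promoters = proms,
       planted = if (length(planted)) bind_rows(planted) else
         tibble(transcript_id = character(), start = integer(),
                kind = character()))
}

#' Write a complete synthetic dataset to disk
#'
#' Runs every simulation stage and writes GTF annotation, chromosome sizes,
#' blacklist BED, coding labels, conservation scores, expression and design
#' TSVs, small-RNA BED, per-mark peak BEDs, methylation TSV, promoter FASTA,
#' the truth tables, and a ready-to-run pipeline `config.yaml` pointing at
#' all of them. Output is byte-deterministic for a fixed config.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the generated objects and file `paths`.
#' @export
simulate_dataset <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  sim <- generate_annotation(cfg)
  expr <- simulate_expression(sim)
  reads <- simulate_smrna(sim)
  chromatin <- simulate_chromatin(sim)
  promoters <- simulate_promoters(sim)

  write_gtf(sim$annotation, p("annotation.gtf"))
  write_tsv_atomic(tibble(chrom = names(cfg$chrom_sizes),
                          length = unname(cfg$chrom_sizes)),
                   p("chrom_sizes.tsv"))
  write_bed(sim$blacklist, p("blacklist.bed"))
  write_tsv_atomic(sim$coding_labels, p("coding_labels.tsv"))
  write_tsv_atomic(sim$conservation, p("conservation.tsv"))
  write_tsv_atomic(
    as_tibble(expr$tpm, rownames = "transcript_id"), p("expression.tsv"))
  write_tsv_atomic(expr$design, p("design.tsv"))
  write_bed(reads, p("smrna.bed"))
  peak_paths <- character(0)
  for (m in names(chromatin$peaks)) {
    pa <- p(sprintf("peaks_%s.bed", m))
    write_bed(chromatin$peaks[[m]], pa)
    peak_paths[m] <- pa
  }
  write_tsv_atomic(chromatin$methylation, p("methylation.tsv"))
  Biostrings::writeXStringSet(promoters$promoters, p("promoters.fa"))
  write_tsv_atomic(sim$truth$transcripts, p("truth_transcripts.tsv"))
  write_tsv_atomic(sim$truth$pairs, p("truth_pairs.tsv"))
  write_tsv_atomic(sim$truth$planted_lfc, p("truth_lfc.tsv"))
  write_tsv_atomic(chromatin$meth_truth, p("truth_methylation.tsv"))
  write_tsv_atomic(chromatin$peak_truth, p("truth_peaks.tsv"))
  write_tsv_atomic(promoters$planted, p("truth_hse.tsv"))

  config <- list(
    inputs = list(
      annotation = p("annotation.gtf"),
      chrom_sizes = p("chrom_sizes.tsv"),
      blacklist = p("blacklist.bed"),
      coding_labels = p("coding_labels.tsv"),
      conservation = p("conservation.tsv"),
      expression = p("expression.tsv"),
      design = p("design.tsv"),
      smrna = p("smrna.bed"),
      peaks = as.list(peak_paths),
      methylation = p("methylation.tsv"),
      promoters = p("promoters.fa")),
    thresholds = default_thresholds(),
    outdir = p("results"),
    seed = cfg$seed)
  yaml::write_yaml(config, p("config.yaml"))

  invisible(list(sim = sim, expr = expr, reads = reads,
                 chromatin = chromatin, promoters = promoters,
                 config = config,
                 paths = c(list(config = p("config.yaml")),
                           lapply(config$inputs, identity))))
}

#' Read an expression matrix and sample design from TSV
#'
#' @param expression_path TSV with a `transcript_id` column followed by one
#'   column per sample.
#' @param design_path TSV with `sample_id`, `tissue`, `timepoint_h`,
#'   `replicate`.
#' @return a `tpm_expression` list (`tpm` matrix, `design` tibble).
#' @export
read_expression <- function(expression_path, design_path) {
  e <- read_tsv_quiet(expression_path)
  design <- read_tsv_quiet(design_path)
  tpm <- as.matrix(e[, -1])
  rownames(tpm) <- e$transcript_id
  if (!all(design$sample_id %in% colnames(tpm))) {
    stop("validation error: design samples missing from expression matrix",
         call. = FALSE)
  }
  tpm <- tpm[, design$sample_id, drop = FALSE]
  if (any(tpm < 0)) stop("validation error: negative TPM", call. = FALSE)
  structure(list(tpm = tpm, design = design), class = "tpm_expression")
}
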