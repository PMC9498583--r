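# Histone-peak association, TSS metaprofiles, methylation summaries and the
# HSE promoter scanner.

test_that("peak association saturates, vanishes and tracks binomial sampling", {
  # isolated genes only: TSSs are farther apart than window + peak half-width,
  # so a gene associates iff its own TSS was marked
  sim <- generate_annotation(sim_config(seed = 29, n_gene_loci = 400,
                                        chrom_sizes = c(chr1 = 3e6,
                                                        chr2 = 3e6),
                                        frac_with_antisense = 0,
                                        n_lincrna = 0, n_incrna = 0,
                                        n_short_decoys = 0,
                                        n_blacklist_decoys = 0,
                                        n_coding_decoys = 0))
  ids <- sim$annotation$transcripts$transcript_id
  classes <- list(gene = ids)
  n <- length(ids)
  ch <- simulate_chromatin(sim)   # frac_tss_marked = 0.5
  assoc <- peak_association(ch$peaks, sim$annotation, classes)
  se3 <- 3 * sqrt(0.5 * 0.5 / n)
  expect_true(all(abs(assoc$fraction - 0.5) < se3))
  # association reproduces the truth flags exactly on isolated genes
  marked_frac <- ch$peak_truth |>
    dplyr::group_by(mark) |>
    dplyr::summarise(f = mean(marked))
  expect_equal(assoc$fraction[order(assoc$mark)],
               marked_frac$f[order(marked_frac$mark)])

  # permutation of the peak list changes nothing
  pk <- ch$peaks[[1]]
  set.seed(1)
  o <- sample(length(pk))
  assoc1 <- peak_association(list(H3K4me3 = pk), sim$annotation, classes)
  assoc2 <- peak_association(list(H3K4me3 = pk[o]), sim$annotation, classes)
  expect_identical(assoc1$fraction, assoc2$fraction)

  # unknown mark names are a configuration error
  expect_error(peak_association(list(H3K9ac = pk), sim$annotation, classes),
               "unknown mark")
})

test_that("TSS metaprofiles are flat for uniform tracks and peak at planted TSS", {
  df <- tibble::tibble(chrom = "chr1",
                       start = c(5000L, 20000L, 40000L),
                       end = c(7000L, 22000L, 42000L),
                       strand = c("+", "-", "+"),
                       transcript_id = c("g1", "g2", "g3"),
                       biotype = "mRNA")
  ann <- mk_annotation(df, chrom_sizes = c(chr1 = 100000L))
  uniform <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
  prof <- tss_metaprofile(uniform, ann, df$transcript_id)
  expect_true(all(prof$mean_signal == 1))
  expect_true(all(prof$n_genes == 3))

  tss <- c(5000L, 22000L, 40000L)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(tss - 25, tss + 25))
  prof2 <- tss_metaprofile(peaks, ann, df$transcript_id)
  # the planted peak makes offset 0 a (shared) maximum of the profile
  expect_equal(prof2$mean_signal[prof2$offset == 0], max(prof2$mean_signal))
  expect_equal(max(prof2$mean_signal), 1)
  expect_true(all(prof2$mean_signal[abs(prof2$offset) > 500] == 0))

  # a single plus-strand gene reproduces the raw track slice
  sl <- tss_metaprofile(peaks, ann, "g1")
  cov <- GenomicRanges::coverage(peaks)$chr1
  raw <- as.numeric(cov[(5000 - 1000):(5000 + 999)])
  expect_equal(sl$mean_signal, raw)

  # chromosome-clipped positions drop out of numerator and denominator
  df_edge <- tibble::tibble(chrom = "chr1", start = 300L, end = 1500L,
                            strand = "+", transcript_id = "edge",
                            biotype = "mRNA")
  ann_e <- mk_annotation(df_edge, chrom_sizes = c(chr1 = 100000L))
  pe <- tss_metaprofile(uniform, ann_e, "edge")
  expect_true(all(pe$n_genes[pe$offset < -299] == 0))
  expect_true(all(is.na(pe$mean_signal[pe$offset < -299])))
})

test_that("methylation change partitions genes and recovers the planted shift", {
  sim <- generate_annotation(sim_config(seed = 37, n_gene_loci = 150,
                                        frac_with_antisense = 1))
  classes <- list(sense = sim$truth$pairs$sense_id,
                  antisense = sim$truth$pairs$antisense_id)
  ch <- simulate_chromatin(sim)
  for (tp in c(6, 12, 24)) {
    mc <- methylation_change(ch$methylation, sim$annotation, classes, tp)
    s <- mc$summary
    expect_true(all(abs(s$frac_up + s$frac_down - 1) < 1e-12))
    n <- sum(s$n_up + s$n_down)
    down <- sum(s$n_down) / n
    expect_lt(abs(down - 0.6), 3 * sqrt(0.6 * 0.4 / n))
    # the planted per-gene direction is mostly recovered; pair members share
    # cytosines where their regions overlap, so a partner with the opposite
    # planted direction dilutes some genes' signal
    j <- dplyr::inner_join(mc$per_gene, ch$meth_truth, by = "transcript_id")
    expect_gt(mean(sign(j$delta) == j$direction), 0.85)
  }

  # identical levels at both timepoints: every gene ties and is excluded
  flat <- ch$methylation |> dplyr::filter(timepoint_h == 0)
  flat2 <- dplyr::bind_rows(flat, dplyr::mutate(flat, timepoint_h = 6))
  mc0 <- methylation_change(flat2, sim$annotation, classes, 6)
  expect_true(all(mc0$per_gene$delta == 0))
  expect_identical(nrow(mc0$summary), 0L)
})

test_that("HSE scanning matches the worked examples", {
  # exact canonical double
  h <- scan_hse("TGAACTTTCA")
  expect_identical(nrow(h), 1L)
  expect_identical(h$kind, "canonical_double")
  expect_identical(h$start, 1L)
  expect_identical(h$n_mismatches, 0L)
  # one exchanged adenine: still a hit, one mismatch
  h1 <- scan_hse("TGTACTTTCA")
  expect_identical(h1$kind, "canonical_double")
  expect_identical(h1$n_mismatches, 1L)
  # two exchanges in the same unit kill the hit
  expect_identical(nrow(scan_hse("TGTTCTTTCA")), 0L)
  # one exchange per unit is allowed (two total)
  h2 <- scan_hse("TGTACTTACA")
  expect_identical(h2$n_mismatches, 2L)
  # the invariant G is not exchangeable
  expect_identical(nrow(scan_hse("TCAACTTTCA")), 0L)
  # non-canonical spacing
  h3 <- scan_hse("TGAACAGTTTCA")
  expect_true("non_canonical" %in% h3$kind)
  # triple suppresses its contained double
  h4 <- scan_hse("TGAACTTTCATGAAT")
  expect_true("canonical_triple" %in% h4$kind)
  expect_false(any(h4$kind == "canonical_double" &
                     h4$start >= 1 & h4$end <= 15))
  # invalid characters rejected, case folded
  expect_error(scan_hse("TGAACTTTXA"), "input error")
  expect_identical(nrow(scan_hse("tgaactttca")), 1L)
})

test_that("HSE hits mirror under reverse complement", {
  set.seed(51)
  s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
             collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h <- scan_hse(s); hr <- scan_hse(rc)
  L <- nchar(s)
  mirrored <- tibble::tibble(start = L - hr$end + 1L, end = L - hr$start + 1L,
                             kind = hr$kind, n_mismatches = hr$n_mismatches)
  expect_identical(
    dplyr::arrange(mirrored, start, end, kind, n_mismatches),
    dplyr::arrange(tibble::tibble(start = h$start, end = h$end, kind = h$kind,
                                  n_mismatches = h$n_mismatches),
                   start, end, kind, n_mismatches))
})

test_that("HSE scanner equals the sliding-window oracle with planted motifs", {
  set.seed(61)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
             collapse = "")
  # C flanks keep the random background from extending a planted element
  substr(s, 395, 414) <- "CCCCCTGAACTTTCACCCCC"
  substr(s, 895, 919) <- "CCCCCTGAACTTTCATGAATCCCCC"
  substr(s, 1495, 1516) <- "CCCCCTGAACAGTTTCACCCCC"
  got <- scan_hse(s)
  exp <- oracle_hse(s)
  expect_equal(
    as.data.frame(got[, c("start", "end", "kind", "n_mismatches")]),
    exp[, c("start", "end", "kind", "n_mismatches")],
    ignore_attr = TRUE)
  expect_true(any(got$kind == "canonical_double" & got$start == 400))
  expect_true(any(got$kind == "canonical_triple" & got$start == 900))
  expect_true(any(got$kind == "non_canonical" & got$start == 1500))
})

test_that("planted promoter motifs are found with matching kinds", {
  sim <- generate_annotation(sim_config(seed = 43, n_gene_loci = 120,
                                        frac_heat_responsive = 1,
                                        frac_hse = 1))
  pr <- simulate_promoters(sim)
  hits <- scan_hse_set(pr$promoters)
  for (i in seq_len(nrow(pr$planted))) {
    pl <- pr$planted[i, ]
    expect_true(any(hits$sequence_id == pl$transcript_id &
                      hits$start == pl$start & hits$kind == pl$kind),
                info = sprintf("planted %s at %d in %s", pl$kind, pl$start,
                               pl$transcript_id))
  }
})
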