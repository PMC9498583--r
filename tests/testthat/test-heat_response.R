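# TPM normalisation, the Welch fold-change test, pair response rules,
# concordance and the bookkeeping partitions.

test_that("compute_tpm normalises rates to a million per sample", {
  counts <- matrix(c(10L, 20L), 2, 1,
                   dimnames = list(c("a", "b"), "s1"))
  tpm <- compute_tpm(counts, c(a = 1000, b = 2000))
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))

  single <- matrix(c(7L, 0L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(compute_tpm(single, c(a = 500, b = 800))[, 1]),
               c(1e6, 0))

  set.seed(3)
  rc <- matrix(rpois(120, 30), 20, 6,
               dimnames = list(paste0("t", 1:20), paste0("s", 1:6)))
  lens <- setNames(sample(200:3000, 20), paste0("t", 1:20))
  expect_equal(unname(colSums(compute_tpm(rc, lens))), rep(1e6, 6),
               tolerance = 1e-9)

  rc[, 2] <- 0L
  expect_warning(tpm0 <- compute_tpm(rc, lens), "all-zero")
  expect_true(all(tpm0[, 2] == 0))
})

test_that("diff_test reproduces the reference Welch computation", {
  design <- mk_design(tissues = "Root", timepoints = c(0, 1))
  tpm <- matrix(c(4, 5, 6, 40, 50, 60), 1, 6,
                dimnames = list("tx", design$sample_id))
  expr <- structure(list(tpm = tpm, design = design),
                    class = "tpm_expression")
  d <- diff_test(expr, timepoints = 1)
  expect_equal(d$log2fc, log2(51 / 6), tolerance = 1e-12)
  ref <- stats::t.test(log2(c(40, 50, 60) + 1), log2(c(4, 5, 6) + 1))
  expect_equal(d$p, ref$p.value, tolerance = 1e-12)
  expect_identical(d$status, "up")

  # identical groups: fold change 0, not significant
  tpm2 <- matrix(c(4, 5, 6, 4, 5, 6), 1, 6,
                 dimnames = list("tx", design$sample_id))
  expr2 <- structure(list(tpm = tpm2, design = design),
                     class = "tpm_expression")
  d2 <- diff_test(expr2, timepoints = 1)
  expect_identical(d2$log2fc, 0)
  expect_identical(d2$status, "ns")

  # missing group is named in the error
  expect_error(diff_test(expr, timepoints = 5), "Root.*5")
})

test_that("row-wise Welch agrees with stats::t.test across random cases", {
  set.seed(11)
  x <- matrix(rnorm(300, 5, 2), 100, 3)
  y <- matrix(rnorm(300, 5.5, 1), 100, 3)
  w <- natheat:::welch_rows(x, y)
  for (i in seq(1, 100, by = 7)) {
    ref <- stats::t.test(x[i, ], y[i, ])
    expect_equal(w$p[i], ref$p.value, tolerance = 1e-10)
    expect_equal(unname(w$stat[i]), unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("log2fc is antisymmetric and status obeys its invariant", {
  design <- mk_design(tissues = c("Root", "Shoot"), timepoints = c(0, 1, 5))
  set.seed(21)
  tpm <- matrix(rexp(50 * nrow(design), 1 / 20), 50, nrow(design),
                dimnames = list(paste0("t", 1:50), design$sample_id))
  expr <- structure(list(tpm = tpm, design = design),
                    class = "tpm_expression")
  d <- diff_test(expr)
  expect_true(all((d$status == "up") ==
                    (d$log2fc >= 1 & d$p < 0.05)))
  expect_true(all((d$status == "down") ==
                    (d$log2fc <= -1 & d$p < 0.05)))

  # swap control and treated labels: log2fc flips sign, p unchanged
  design_sw <- design
  design_sw$timepoint_h[design$timepoint_h == 0] <- 1
  design_sw$timepoint_h[design$timepoint_h == 1] <- 0
  expr_sw <- structure(list(tpm = tpm, design = design_sw),
                       class = "tpm_expression")
  d_sw <- diff_test(expr_sw, timepoints = 1)
  d_1 <- d[d$timepoint_h == 1, ]
  expect_equal(d_sw$log2fc, -d_1$log2fc, tolerance = 1e-12)
  expect_equal(d_sw$p, d_1$p, tolerance = 1e-12)
})

test_that("pairs respond only when both members share a qualifying contrast", {
  pairs <- tibble::tibble(pair_id = c("p1", "p2"),
                          sense_id = c("s1", "s2"),
                          antisense_id = c("a1", "a2"))
  contrasts <- c("Root@1", "Root@5", "RL@1", "RL@5")
  diff <- mk_diff(
    lfc_by_tx = list(s1 = c(2, 0, 0, 0), a1 = c(1.5, 0, 0, 0),
                     s2 = c(2, 0, 0, 0), a2 = c(0, 0, 0, 3)),
    p_by_tx = list(s1 = c(0.01, 1, 1, 1), a1 = c(0.02, 1, 1, 1),
                   s2 = c(0.01, 1, 1, 1), a2 = c(1, 1, 1, 0.001)),
    contrasts = contrasts)
  res <- call_responsive_pairs(pairs, diff)
  expect_identical(res$responsive, c(TRUE, FALSE))
  expect_identical(res$qualifying[1], "Root@1h")
  expect_identical(res$n_qualifying, c(1L, 0L))
  # down-regulation qualifies too
  diff2 <- mk_diff(list(s1 = c(-2, 0, 0, 0), a1 = c(-1, 0, 0, 0),
                        s2 = c(0, 0, 0, 0), a2 = c(0, 0, 0, 0)),
                   list(s1 = c(0.01, 1, 1, 1), a1 = c(0.04, 1, 1, 1),
                        s2 = c(1, 1, 1, 1), a2 = c(1, 1, 1, 1)),
                   contrasts)
  expect_identical(call_responsive_pairs(pairs, diff2)$responsive,
                   c(TRUE, FALSE))
})

test_that("concordance follows the sign of the fold-change correlation", {
  pairs <- tibble::tibble(pair_id = paste0("p", 1:4),
                          sense_id = paste0("s", 1:4),
                          antisense_id = paste0("a", 1:4))
  contrasts <- c("Root@1", "Shoot@1", "RL@1")
  s <- c(1, 2, 3)
  diff <- mk_diff(
    list(s1 = s, a1 = 2 * s,
         s2 = s, a2 = -s,
         s3 = c(1, 0, 2), a3 = c(0, 1, 1),
         s4 = s, a4 = c(0, 0, 0)),
    rep(list(c(0.01, 0.01, 0.01)), 8) |>
      setNames(c("s1", "a1", "s2", "a2", "s3", "a3", "s4", "a4")),
    contrasts)
  cc <- pair_concordance(pairs, diff)
  expect_equal(cc$r, c(1, -1, 0, NA_real_), tolerance = 1e-12)
  expect_identical(cc$concordance, c("concordant", "discordant",
                                     "unclassified", "unclassified"))
})

test_that("tissue specificity partitions responsive pairs by qualifying tissues", {
  responses <- tibble::tibble(
    pair_id = paste0("p", 1:5),
    responsive = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    n_qualifying = c(1L, 2L, 2L, 3L, 0L),
    qualifying = c("Root@1h", "Root@1h;Root@5h", "Root@1h;Shoot@5h",
                   "Bud@1h;OF@1h;Bud@5h", ""))
  ts <- tissue_specificity(responses)
  expect_identical(ts$n_responsive, 4L)
  expect_identical(sum(ts$counts$n), 4L)
  cn <- setNames(ts$counts$n, ts$counts$subset)
  expect_identical(cn[["Root"]], 2L)
  expect_identical(cn[["Root+Shoot"]], 1L)
  expect_identical(cn[["Bud+OF"]], 1L)
  expect_identical(ts$tissue_specific_n, 2L)
  expect_equal(ts$tissue_specific_pct, 50)
})

test_that("shared DE fractions are intersection over union", {
  sets <- list(Root = c("a", "b", "c"), Shoot = c("b", "c", "d"),
               RL = c("b", "c", "e"))
  sh <- shared_de_fraction(sets)
  expect_identical(sh$n_shared, 2L)
  expect_identical(sh$n_union, 5L)
  expect_equal(sh$pct, 40)
  same <- list(A = c("x", "y"), B = c("x", "y"))
  expect_equal(shared_de_fraction(same)$pct, 100)
  expect_equal(shared_de_fraction(list(A = "x", B = "y"))$pct, 0)
  expect_warning(out <- shared_de_fraction(list(A = character(),
                                                B = character())),
                 "empty union")
  expect_true(is.na(out$pct))
})

test_that("null simulations are calibrated and planted effects recovered", {
  # type-I: no planted effects, p<0.05 rate near nominal
  cfg0 <- sim_config(seed = 5, n_gene_loci = 400,
                     chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                     frac_with_antisense = 0, frac_heat_responsive = 0,
                     n_lincrna = 0, n_incrna = 0, n_short_decoys = 0,
                     n_blacklist_decoys = 0, n_coding_decoys = 0)
  sim0 <- generate_annotation(cfg0)
  d0 <- diff_test(simulate_expression(sim0))
  expect_gt(mean(d0$p < 0.05), 0.02)
  expect_lt(mean(d0$p < 0.05), 0.08)

  # planted effects: strong recovery at log2FC = 3, CV = 0.2
  cfg <- sim_config(seed = 9, n_gene_loci = 150,
                    planted_log2fc_range = c(3, 3), replicate_cv = 0.2)
  sim <- generate_annotation(cfg)
  expr <- simulate_expression(sim)
  calls <- filter_candidates(sim$annotation, sim$blacklist, sim$coding_labels)
  keep <- calls$transcript_id[!startsWith(calls$status, "discarded")]
  pairs <- discover_nat_pairs(subset_annotation(sim$annotation, keep),
                              expr, calls, conservation = sim$conservation)
  res <- pair_response(pairs, diff_test(expr))
  truth <- sim$truth$pairs |>
    dplyr::select(sense_id, antisense_id, true_resp = responsive,
                  true_conc = concordant)
  j <- dplyr::inner_join(pairs, truth, by = c("sense_id", "antisense_id")) |>
    dplyr::inner_join(res, by = "pair_id")
  expect_gte(mean(j$responsive[j$true_resp]), 0.9)
  expect_lte(mean(j$responsive[!j$true_resp]), 0.01)
  jr <- dplyr::filter(j, true_resp, responsive)
  agree <- ifelse(jr$true_conc, jr$concordance == "concordant",
                  jr$concordance == "discordant")
  expect_gte(mean(agree), 0.95)
})
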