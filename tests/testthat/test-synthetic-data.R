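test_that("simulate_genome places non-overlapping promoter windows deterministically", {
  tss <- simulate_genome(10, 1, 1e6, seed = 1)
  expect_equal(nrow(tss), 10L)
  expect_true(all(tss$tss >= 0 & tss$tss < 1e6))
  # promoter windows (strand-aware, -5 kb/+2 kb) never overlap
  ws <- ifelse(tss$strand == "+", tss$tss - 5000, tss$tss - 2000)
  we <- ifelse(tss$strand == "+", tss$tss + 2000, tss$tss + 5000)
  ord <- order(ws)
  expect_true(all(ws[ord][-1] > we[ord][-length(we)]))
  expect_identical(simulate_genome(10, 1, 1e6, seed = 1), tss)
  expect_false(identical(simulate_genome(10, 1, 1e6, seed = 2)$tss, tss$tss))
  # greedy packing bound: 8 kb per gene
  expect_error(simulate_genome(200, 1, 1e6, seed = 1), "infeasible")
})

test_that("simulate_chipseq plants enrichment, honours HOT structure and is seed-stable", {
  tss <- simulate_genome(100, 1, 1e6, seed = 2)
  age_genes <- tss$gene_id[1:20]

  # hot_fraction 0, single TF: every peak has complexity 1
  one <- simulate_chipseq(tss, n_tfs = 1, peaks_per_experiment = 50,
                          hot_fraction = 0, seed = 3)
  # complexity may exceed 1 only through self-overlap of the same TF,
  # which still counts one distinct TF
  cx <- compute_complexity(one$peaks)
  expect_true(all(cx$complexity == 1L))

  # planted rho = 10 puts more mass on age genes than the null fraction;
  # Monte-Carlo check against the analytic sampling weight at n = 1e4
  big <- simulate_chipseq(tss, n_tfs = 2, peaks_per_experiment = 1e4,
                          planted = list(TF1 = list(rho = 10,
                                                    age_gene_ids = age_genes)),
                          hot_fraction = 0, seed = 4)
  # per-peak: does the summit fall in an age-gene promoter window?
  age_tss <- tss[tss$gene_id %in% age_genes, ]
  in_age_window <- function(sub) {
    hit <- rep(FALSE, nrow(sub))
    for (j in seq_len(nrow(age_tss))) {
      d <- if (age_tss$strand[j] == "+") sub$summit - age_tss$tss[j]
           else age_tss$tss[j] - sub$summit
      hit <- hit | (d >= -5000 & d <= 2000)
    }
    mean(hit)
  }
  # planted sampling weight: 20*10 / (20*10 + 80) = 0.714; null 0.2.
  # binomial SE at n = 1e4 is ~0.005; allow 5 SE
  expect_gt(in_age_window(big$peaks[big$peaks$tf == "TF1", ]), 0.69)
  expect_lt(in_age_window(big$peaks[big$peaks$tf == "TF2", ]), 0.23)

  expect_identical(
    simulate_chipseq(tss, n_tfs = 2, peaks_per_experiment = 100, seed = 9)$peaks,
    simulate_chipseq(tss, n_tfs = 2, peaks_per_experiment = 100, seed = 9)$peaks)
  expect_error(
    simulate_chipseq(tss, n_tfs = 2, peaks_per_experiment = 10,
                     planted = list(TF9 = list(rho = 2, age_gene_ids = age_genes))),
    "TF9")
})

test_that("HOT regions are hit by every TF and removed by the complexity filter", {
  tss <- simulate_genome(60, 1, 1e6, seed = 5)
  sim <- simulate_chipseq(tss, n_tfs = 8, peaks_per_experiment = 60,
                          hot_fraction = 0.2, n_hot_regions = 3, seed = 5)
  hot <- sim$truth$hot_regions
  cx <- compute_complexity(sim$peaks)
  in_hot <- vapply(seq_len(nrow(cx)), function(i) {
    any(cx$chrom[i] == hot$chrom & cx$summit[i] >= hot$start &
          cx$summit[i] < hot$end)
  }, logical(1))
  # every HOT region carries peaks from >= 50% of TFs
  for (h in seq_len(nrow(hot))) {
    tfs_here <- unique(cx$tf[cx$summit >= hot$start[h] &
                               cx$summit < hot$end[h]])
    expect_gte(length(tfs_here), 4)
  }
  filt <- filter_by_complexity(cx, n_tfs = 8)   # threshold ceil(4) = 4
  # HOT peaks (complexity 8) are gone, promoter peaks survive
  expect_true(all(cx$complexity[in_hot] > 4))
  expect_false(any(in_hot[match(paste(filt$start, filt$experiment_id),
                                paste(cx$start, cx$experiment_id))]))
})

test_that("simulate_expression encodes pure-GFR genes whose age slope vanishes given GFR", {
  tss_ids <- sprintf("G%03d", 1:60)
  sim <- simulate_expression(tss_ids, n_samples = 40, frac_age_genes = 0.5,
                             noise_sd = 0.2, seed = 6)
  expect_identical(simulate_expression(tss_ids, n_samples = 40,
                                       frac_age_genes = 0.5,
                                       noise_sd = 0.2, seed = 6)$expr$values,
                   sim$expr$values)
  # no planted age genes -> slopes have mean ~ 0
  null_sim <- simulate_expression(tss_ids, n_samples = 60,
                                  frac_age_genes = 0, seed = 7)
  fit <- fit_age_model(null_sim$expr)
  se_mean <- sd(fit$beta_age) / sqrt(nrow(fit))
  expect_lt(abs(mean(fit$beta_age)), 3 * se_mean)

  # closed-form OLS: a noiseless pure-GFR gene has age slope exactly 0
  # with GFR in the design and non-zero without
  zero <- simulate_expression(tss_ids[1:10], n_samples = 30,
                              frac_age_genes = 1, frac_gfr_mediated = 1,
                              noise_sd = 0, seed = 8)
  g <- zero$truth$gfr_gene_ids[1]
  with_gfr <- fit_age_model(zero$expr, include_gfr = TRUE)
  without <- fit_age_model(zero$expr, include_gfr = FALSE)
  expect_lt(abs(with_gfr$beta_age[with_gfr$gene_id == g]), 1e-10)
  expect_gt(abs(without$beta_age[without$gene_id == g]), 1e-6)
})

test_that("simulate_cytokine_response is concordance-calibrated and deterministic", {
  genes <- sprintf("G%03d", 1:80)
  slopes <- setNames(rnorm(80, 0, 0.01), genes)
  targets <- genes[1:40]
  sim <- simulate_cytokine_response(targets, slopes, concordance_c = 1,
                                    p_induced = 1, seed = 1)
  ct <- concordance_test(sim$de[sim$de$gene_id %in% targets, ],
                         sim$age_slopes)
  expect_equal(ct$concordance_pct, 100)
  expect_identical(
    simulate_cytokine_response(targets, slopes, seed = 2)$de,
    simulate_cytokine_response(targets, slopes, seed = 2)$de)
})

test_that("simulate_assoc emits exact chi-square-matched tables (round-trip oracle)", {
  sim <- simulate_assoc("NFKB1", snps_per_gene = 1, true_or = 1.2,
                        maf = 0.3, n_cases = 5000, n_controls = 50000,
                        seed = 3)
  rec <- sim$records
  back <- estimate_allelic_or(rec$p_egfr, rec$maf, rec$n_cases,
                              rec$n_controls)
  expect_lt(abs(back$or_estimate - 1.2), 1e-6)
  # null odds ratio gives zero chi-square, p = 1
  nul <- simulate_assoc("RELA", snps_per_gene = 1, true_or = 1, seed = 4)
  expect_equal(nul$records$p_egfr, 1)
  expect_identical(simulate_assoc("X", 3, seed = 5)$records,
                   simulate_assoc("X", 3, seed = 5)$records)
  # non-positive odds ratios are rejected outright (any finite positive
  # OR is attainable in an expected-count allelic table)
  expect_error(simulate_assoc("X", 1, true_or = 0, seed = 6), "true_or")
})

test_that("generator substreams are independent: adding one generator leaves others unchanged", {
  tss1 <- simulate_genome(20, 1, 1e6, seed = 42)
  # interleave an unrelated generator call; same seed must reproduce tss
  invisible(simulate_assoc("A", 2, seed = 42))
  tss2 <- simulate_genome(20, 1, 1e6, seed = 42)
  expect_identical(tss1, tss2)
})
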