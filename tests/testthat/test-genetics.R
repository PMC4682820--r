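test_that("Bonferroni threshold divides exactly and renders by truncation", {
  b <- bonferroni_threshold(217, 2)
  expect_equal(b$threshold, 0.05 / 434)
  expect_equal(b$n_tests, 434L)
  expect_equal(b$rendered, "1.1e-04")
  expect_equal(bonferroni_threshold(1, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(10, 2)$threshold, 2.5e-3)
  # threshold times the test count recovers alpha exactly
  expect_equal(b$threshold * b$n_tests, 0.05)
})

test_that("lead SNP selection takes the per-gene minimum p with lexicographic ties", {
  rec <- tibble::tibble(
    snp_id = c("rs2", "rs1", "rs9", "rsB", "rsA"),
    gene = c("NFKB1", "NFKB1", "RELA", "STAT1", "STAT1"),
    p_egfr = c(0.01, 4.4e-5, 0.2, 0.03, 0.03),
    p_ckd = c(0.5, 0.09, 0.4, 0.2, 0.1))
  thr <- bonferroni_threshold(217, 2)$threshold
  lead <- select_lead_snps(rec, "egfr", thr)
  expect_equal(lead$snp_id[lead$gene == "NFKB1"], "rs1")
  expect_true(lead$significant[lead$gene == "NFKB1"])   # 4.4e-5 < 1.15e-4
  expect_false(lead$significant[lead$gene == "RELA"])
  # tie at p = 0.03 -> lexicographically smallest snp id
  expect_equal(lead$snp_id[lead$gene == "STAT1"], "rsA")
  # phenotype switch selects the other p column
  lead_ckd <- select_lead_snps(rec, "ckd", thr)
  expect_equal(lead_ckd$snp_id[lead_ckd$gene == "STAT1"], "rsA")
})

test_that("odds-ratio reconstruction matches chi-square and pooled MAF invariants", {
  # p = 1: zero chi-square, OR exactly 1
  r0 <- estimate_allelic_or(1, 0.3, 5000, 50000)
  expect_equal(r0$or_estimate, 1)

  # forward oracle: f_case 0.22, f_ctl 0.20 at 5000/50000 alleles 2n
  t_case <- 1e4; t_ctl <- 1e5
  tab <- matrix(c(t_case * 0.22, t_case * 0.78,
                  t_ctl * 0.20, t_ctl * 0.80), 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  p <- pchisq(stat, 1, lower.tail = FALSE)
  pooled <- (t_case * 0.22 + t_ctl * 0.20) / (t_case + t_ctl)
  r <- estimate_allelic_or(p, pooled, 5000, 50000)
  or_true <- (0.22 / 0.78) / (0.20 / 0.80)
  expect_lt(abs(r$or_estimate - or_true), 1e-6)
  expect_equal(r$f_case, 0.22, tolerance = 1e-8)
  expect_equal(r$f_control, 0.20, tolerance = 1e-8)
  # invariants: implied table reproduces the target statistic and MAF
  expect_lt(abs(r$achieved_chi2 - r$target_chi2), 1e-8)
  w <- c(t_case, t_ctl) / (t_case + t_ctl)
  expect_lt(abs(w[1] * r$f_case + w[2] * r$f_control - pooled), 1e-10)

  # protective direction depletes the minor allele in cases: OR < 1
  rp <- estimate_allelic_or(p, pooled, 5000, 50000, direction = "protective")
  expect_lt(rp$or_estimate, 1)
  expect_lt(abs(rp$achieved_chi2 - rp$target_chi2), 1e-8)

  # monotone: smaller p, larger OR at fixed maf and n
  ors <- vapply(10^-(1:8), function(pp) {
    estimate_allelic_or(pp, 0.3, 5000, 50000)$or_estimate
  }, numeric(1))
  expect_true(all(diff(ors) > 0))

  # an unattainably small p for the frequency bound errors out
  expect_error(estimate_allelic_or(1e-300, 0.01, 30, 30), "unattainable")
})

test_that("OR reconstruction round-trips the generator across the parameter grid", {
  for (or in c(1.01, 1.1, 1.5, 2)) {
    for (maf in c(0.05, 0.2, 0.5)) {
      for (n in c(1e3, 1e5)) {
        sim <- simulate_assoc("G", snps_per_gene = 1, true_or = or,
                              maf = maf, n_cases = n, n_controls = 10 * n,
                              seed = 81)
        rec <- sim$records
        back <- estimate_allelic_or(rec$p_egfr, rec$maf, rec$n_cases,
                                    rec$n_controls,
                                    neg_log10_p = rec$neg_log10_p_egfr)
        expect_lt(abs(back$or_estimate - or), 1e-6)
      }
    }
  }
})

test_that("carrier mode uses Hardy-Weinberg carrier counts", {
  r <- estimate_allelic_or(1e-4, 0.3, 5000, 50000, mode = "carrier")
  # carrier frequency center: 1 - (1 - 0.3)^2 = 0.51
  w <- c(5000, 50000) / 55000
  expect_lt(abs(w[1] * r$f_case + w[2] * r$f_control - 0.51), 1e-10)
  expect_lt(abs(r$achieved_chi2 - r$target_chi2), 1e-8)
})

test_that("LD annotation applies strict R2 and half-open interval bounds", {
  ld <- data.frame(snp_id = c("rsLEAD", "rs1", "rs2", "rs3", "rs4"),
                   r2 = c(1, 0.9, 0.8, 0.81, 0.2))
  pos <- data.frame(snp_id = c("rsLEAD", "rs1", "rs2", "rs3", "rs4"),
                    chrom = "chr4", pos = c(500L, 1000L, 1100L, 1200L, 1300L))
  ann <- data.frame(type = c("DNase", "H3K4me1"), chrom = "chr4",
                    start = c(900L, 1200L), end = c(1001L, 1250L))
  out <- annotate_linked_snps("rsLEAD", ld, 0.8, ann, pos)
  # r2 = 0.8 exactly excluded; 0.81 and 0.9 included (plus the lead)
  expect_setequal(unique(out$snp_id), c("rsLEAD", "rs1", "rs3"))
  # rs1 at 1000 inside [900, 1001); rs3 at 1200 inside [1200, 1250)
  expect_equal(out$annotation_type[out$snp_id == "rs1"], "DNase")
  expect_equal(out$annotation_type[out$snp_id == "rs3"], "H3K4me1")
  # boundary: SNP at an interval end coordinate is outside (half-open)
  pos2 <- pos; pos2$pos[pos2$snp_id == "rs1"] <- 1001L
  out2 <- annotate_linked_snps("rsLEAD", ld, 0.8, ann, pos2)
  expect_true(is.na(out2$annotation_type[out2$snp_id == "rs1"]))
  expect_error(annotate_linked_snps("rsX", ld, 0.8, ann, pos), "absent")
})

test_that("LD annotation agrees with a brute-force all-pairs scan", {
  set.seed(82)
  n_snp <- 40; n_ann <- 25
  ld <- data.frame(snp_id = c("lead", sprintf("s%02d", 1:n_snp)),
                   r2 = c(1, runif(n_snp)))
  pos <- data.frame(snp_id = ld$snp_id, chrom = "chr1",
                    pos = sample.int(5000, n_snp + 1))
  st <- sample.int(5000, n_ann)
  ann <- data.frame(type = sample(c("peak", "DNase"), n_ann, TRUE),
                    chrom = "chr1", start = st,
                    end = st + sample(50:300, n_ann, TRUE))
  got <- annotate_linked_snps("lead", ld, 0.8, ann, pos)
  got <- got[!is.na(got$annotation_type), ]
  want <- list()
  for (i in seq_len(nrow(ld))) {
    if (ld$r2[i] <= 0.8) next
    p <- pos$pos[pos$snp_id == ld$snp_id[i]]
    for (j in seq_len(n_ann)) {
      if (ann$start[j] <= p && p < ann$end[j]) {
        want[[length(want) + 1]] <- paste(ld$snp_id[i], ann$start[j])
      }
    }
  }
  expect_setequal(paste(got$snp_id, got$annotation_start), unlist(want))
})
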