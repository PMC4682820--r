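test_that("direct targets are the bound-and-responsive intersection", {
  de <- tibble::tibble(gene_id = c("A", "B", "C", "D"),
                       log2fc = c(1, -0.5, 2, 1), p = c(0.01, 0.2, 0.04, 0.3),
                       perturbation = "TNFa", degenerate = FALSE)
  dt <- define_direct_targets(c("A", "B", "C"), de, tf = "NFKB")
  expect_setequal(dt$genes, c("A", "C"))
  # p_max 1 keeps every bound gene
  expect_setequal(define_direct_targets(c("A", "B", "C"), de, p_max = 1)$genes,
                  c("A", "B", "C"))
  expect_warning(define_direct_targets("Z", de, tf = "X"), "no direct targets")
})

test_that("planted targets are recovered up to DE false negatives", {
  genes <- sprintf("G%03d", 1:200)
  slopes <- setNames(rnorm(200, 0, 0.01), genes)
  targets <- genes[1:50]
  sim <- simulate_cytokine_response(targets, slopes, p_induced = 1, seed = 61)
  dt <- define_direct_targets(targets, sim$de, tf = "T")
  # generator draws target DE p-values strictly below 0.05: exact recovery
  expect_setequal(dt$genes, targets)
  # non-targets enter only via their U(0,1) p-values, never here
  expect_length(setdiff(dt$genes, targets), 0)
})

test_that("exclusive target sets are pairwise disjoint", {
  mk <- function(tf, genes) {
    structure(list(tf = tf, genes = genes, source = list(), exclusive = FALSE),
              class = "direct_target_set")
  }
  sets <- list(T1 = mk("T1", c("A", "B")), T2 = mk("T2", c("B", "C")))
  ex <- exclusive_targets(sets)
  expect_equal(ex$T1$genes, "A")
  expect_equal(ex$T2$genes, "C")
  # disjoint sets unchanged
  sets2 <- list(T1 = mk("T1", c("A", "B")), T2 = mk("T2", c("C", "D")))
  ex2 <- exclusive_targets(sets2)
  expect_equal(ex2$T1$genes, c("A", "B"))
  # a gene shared by all three sets survives in none
  sets3 <- list(T1 = mk("T1", c("A", "X")), T2 = mk("T2", c("B", "X")),
                T3 = mk("T3", c("C", "X")))
  ex3 <- exclusive_targets(sets3)
  all_genes <- unlist(lapply(ex3, `[[`, "genes"))
  expect_false("X" %in% all_genes)
  expect_false(any(duplicated(all_genes)))
  # selective filtering: only flagged sets are pruned
  ex4 <- exclusive_targets(sets, exclusive_tfs = "T1")
  expect_equal(ex4$T1$genes, "A")
  expect_equal(ex4$T2$genes, c("B", "C"))
})

test_that("binomial concordance matches exhaustive enumeration and the printed worked example", {
  # exhaustive: sum over all 2^n outcomes for n <= 12
  for (n in c(5, 9, 12)) {
    for (k in c(0, 3, n)) {
      enum <- sum(vapply(0:(2^n - 1), function(x) {
        sum(as.integer(intToBits(x))[1:n]) >= k
      }, logical(1))) / 2^n
      expect_equal(concordance_from_counts(k, n)$p_binomial, enum,
                   tolerance = 1e-12)
    }
  }
  # 35 of 40 induced targets concordant: 87.5% (printed 88%), p ~ 6.9e-7
  r <- concordance_from_counts(35, 40)
  expect_equal(r$concordance_pct, 87.5)
  expect_equal(round(r$concordance_pct), 88)
  expect_equal(r$p_binomial, 6.913060133e-07, tolerance = 1e-9)
  expect_lt(r$p_binomial, 1e-5)
  # 20 of 40: coin-flip territory
  expect_equal(concordance_from_counts(20, 40)$p_binomial, 0.5626853438,
               tolerance = 1e-9)
  # all concordant: p = 2^-n
  expect_equal(concordance_from_counts(10, 10)$p_binomial, 2^-10)
})

test_that("concordance_test counts induced targets with positive age slopes", {
  de <- tibble::tibble(gene_id = c("A", "B", "C", "D"),
                       log2fc = c(2, 1, -1, 0.5), p = 0.01,
                       perturbation = "x", degenerate = FALSE)
  slopes <- c(A = 0.02, B = -0.01, C = 0.05, D = 0)
  r <- concordance_test(de, slopes)
  # induced: A, B, D; concordant: A only (zero slope counts against)
  expect_equal(r$n_induced, 3L)
  expect_equal(r$n_concordant, 1L)
  expect_error(concordance_test(de, slopes[1:3]), "no age slope")
  de_rep <- de; de_rep$log2fc <- -abs(de_rep$log2fc)
  expect_error(concordance_test(de_rep, slopes), "no induced")
})

test_that("profile correlation matches the t transform and rescaling invariance", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(profile_correlation(x, 2 * x)$r, 1)
  expect_equal(profile_correlation(x, 2 * x)$p, 0)
  set.seed(62)
  y <- -x + rnorm(5, 0, 1e-8)
  expect_lt(profile_correlation(x, y)$r, -0.999999)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  r <- profile_correlation(a, b)
  ref <- cor.test(a, b)
  expect_equal(r$r, unname(ref$estimate))
  expect_equal(r$p, ref$p.value)
  # affine rescaling leaves r unchanged (sign follows the scale)
  expect_equal(profile_correlation(3 * a + 7, b)$r, r$r)
  expect_equal(profile_correlation(-a, b)$r, -r$r)
  expect_error(profile_correlation(rep(1, 5), rnorm(5)), "constant")
})

test_that("cytokine concordance drives a positive aging-profile correlation", {
  set.seed(63)
  genes <- sprintf("G%03d", 1:60)
  slopes <- setNames(rnorm(60, 0, 0.01), genes)
  rs <- replicate(50, {
    sim <- simulate_cytokine_response(genes[1:40], slopes,
                                      concordance_c = 0.875, p_induced = 1,
                                      seed = sample.int(1e6, 1))
    sub <- sim$de[sim$de$gene_id %in% genes[1:40], ]
    profile_correlation(sub$log2fc, sim$age_slopes[sub$gene_id])$r
  })
  expect_gt(mean(rs), 0)
  expect_gt(t.test(rs)$statistic, 3)
})

test_that("cross-species overlap: perfect agreement, null calibration, degenerate margin", {
  genes_h <- sprintf("H%03d", 1:100)
  genes_r <- sprintf("R%03d", 1:100)
  map <- data.frame(human = genes_h, other = genes_r)
  slopes <- setNames(seq(-0.05, 0.05, length.out = 100), genes_h)

  # identical significance calls and proportional profiles
  de_r <- tibble::tibble(gene_id = genes_r, log2fc = unname(slopes) * 10,
                         p = ifelse(abs(slopes) > 0.03, 0.001, 0.5),
                         perturbation = "age", degenerate = FALSE)
  sig_h <- genes_h[abs(slopes) > 0.03]
  r <- cross_species_overlap(genes_h, slopes, map, de_r,
                             other_sig_p = 0.05, human_sig_genes = sig_h)
  expect_equal(r$r, 1)
  expect_equal(r$n_shared_sig, length(sig_h))
  # perfect overlap: fold = universe / |sig|
  expect_equal(r$fold, 100 / length(sig_h))
  expect_false(r$degenerate_margin)

  # independent random calls give fold ~ 1 on average
  set.seed(64)
  folds <- replicate(300, {
    de_null <- tibble::tibble(gene_id = genes_r,
                              log2fc = rnorm(100),
                              p = runif(100), perturbation = "age",
                              degenerate = FALSE)
    cross_species_overlap(genes_h, slopes, map, de_null,
                          other_sig_p = 0.3,
                          human_sig_genes = sample(genes_h, 40))$fold
  })
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 1), 3 * se)

  # one margin = whole universe is flagged degenerate
  rd <- cross_species_overlap(genes_h, slopes, map, de_r,
                              other_sig_p = 0.05, human_sig_genes = genes_h)
  expect_true(rd$degenerate_margin)
  # many-to-many orthologs rejected
  bad <- rbind(map, data.frame(human = "H001", other = "R999"))
  expect_error(cross_species_overlap(genes_h, slopes, bad, de_r),
               "one-to-one")
})
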