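## Candidate-gene SNP analysis: Bonferroni threshold over SNP x phenotype
## tests, per-gene lead-SNP selection, allelic odds-ratio reconstruction
## from summary statistics by chi-square matching, and functional
## annotation of LD-linked SNPs.

#' Bonferroni per-test threshold over SNPs and phenotypes
#'
#' @param n_snps,n_phenotypes counts of tested SNPs and phenotypes.
#' @param alpha family-wise error rate; default 0.05.
#' @return list: threshold (alpha / (n_snps * n_phenotypes)), n_tests,
#'   rendered (string with the mantissa truncated to 2 significant
#'   figures, the convention for reporting significance cut-offs, e.g.
#'   0.05/434 renders as "1.1e-04").
#' @export
bonferroni_threshold <- function(n_snps, n_phenotypes = 1, alpha = 0.05) {
  stopifnot(n_snps >= 1, n_phenotypes >= 1, alpha > 0)
  n_tests <- n_snps * n_phenotypes
  thr <- alpha / n_tests
  e <- floor(log10(thr))
  mant <- floor(thr / 10^e * 10) / 10    # truncate, never round up
  list(threshold = thr, n_tests = n_tests,
       rendered = sprintf("%.1fe%+03d", mant, e))
}

#' Select the lead SNP per candidate gene
#'
#' The lead SNP of a gene is the SNP with the smallest association
#' p-value for the given phenotype; ties break to the lexicographically
#' smallest SNP id.  The lead is flagged significant iff its p-value is
#' below the (Bonferroni) threshold.
#'
#' @param records association tibble from \code{\link{read_assoc}} (or
#'   \code{\link{simulate_assoc}}).
#' @param phenotype \code{"egfr"} or \code{"ckd"} (selects column
#'   \code{p_egfr}/\code{p_ckd}).
#' @param threshold per-test significance threshold.
#' @return tibble: gene, snp_id, p, significant — one row per gene.
#' @export
select_lead_snps <- function(records, phenotype = "egfr", threshold) {
  col <- paste0("p_", phenotype)
  if (!col %in% names(records)) stop_msg("no column %s in records", col)
  p <- records[[col]]
  ord <- order(records$gene, p, records$snp_id)
  rec <- records[ord, , drop = FALSE]
  keep <- !duplicated(rec$gene)
  tibble::tibble(gene = rec$gene[keep], snp_id = rec$snp_id[keep],
                 p = rec[[col]][keep],
                 significant = rec[[col]][keep] < threshold)
}

## Pearson chi-square (1 df, no continuity correction) of the allelic or
## carrier 2x2 table implied by case/control minor frequencies.
implied_chisq <- function(f_case, f_ctl, t_case, t_ctl) {
  tab <- matrix(c(t_case * f_case, t_case * (1 - f_case),
                  t_ctl * f_ctl, t_ctl * (1 - f_ctl)),
                nrow = 2, byrow = TRUE)
  chisq_stat_2x2(tab)
}

#' Reconstruct an allelic odds ratio from summary statistics
#'
#' Given only an association p-value, case/control sample sizes and the
#' pooled minor-allele frequency, finds the 2x2 allele-count table whose
#' Pearson chi-square statistic (1 df, no continuity correction)
#' reproduces the p-value while keeping the pooled minor-allele frequency
#' fixed, and reports its odds ratio.  The case/control minor-allele
#' frequencies are displaced in opposite directions weighted by the other
#' group's share of alleles (f_case = maf + delta w_ctl,
#' f_ctl = maf - delta w_case), which preserves the pooled frequency
#' exactly; delta >= 0 is found by root bisection so that the statistic
#' matches qchisq(1 - p, 1) to within 1e-10.  \code{direction =
#' "protective"} displaces the frequencies the other way (minor allele
#' depleted in cases), yielding an odds ratio below 1.  In carrier mode
#' the table counts minor-allele carriers (frequency
#' 1 - (1 - maf)^2 under Hardy-Weinberg) out of n individuals per group
#' instead of alleles out of 2n.
#'
#' @param p association p-value in (0, 1].  May be NULL when
#'   \code{neg_log10_p} is given.
#' @param maf pooled minor-allele frequency in (0, 0.5].
#' @param n_cases,n_controls cohort sizes (individuals).
#' @param direction \code{"risk"} (minor allele enriched in cases) or
#'   \code{"protective"}.
#' @param mode \code{"allelic"} (default) or \code{"carrier"}.
#' @param neg_log10_p optional -log10 p, taking precedence over \code{p};
#'   the log-scale channel keeps full precision for associations whose
#'   linear-scale p-value underflows (p below ~1e-308).
#' @return list of class \code{or_reconstruction}: snp-independent fields
#'   target_chi2, or_estimate, f_case, f_control, delta, mode, direction.
#' @export
estimate_allelic_or <- function(p, maf, n_cases, n_controls,
                                direction = c("risk", "protective"),
                                mode = c("allelic", "carrier"),
                                neg_log10_p = NULL) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  if (is.null(neg_log10_p)) {
    stopifnot(p > 0, p <= 1)
  } else {
    stopifnot(neg_log10_p >= 0)
    p <- 10^-min(neg_log10_p, 307)
  }
  stopifnot(maf > 0, maf <= 0.5, n_cases > 0, n_controls > 0)
  if (mode == "allelic") {
    t_case <- 2 * n_cases; t_ctl <- 2 * n_controls
    f0 <- maf
  } else {
    t_case <- n_cases; t_ctl <- n_controls
    f0 <- 1 - (1 - maf)^2            # carrier frequency under HWE
  }
  w_case <- t_case / (t_case + t_ctl)
  w_ctl <- t_ctl / (t_case + t_ctl)
  sgn <- if (direction == "risk") 1 else -1
  freqs <- function(delta) {
    c(case = f0 + sgn * delta * w_ctl, ctl = f0 - sgn * delta * w_case)
  }
  ## upper-tail quantile keeps full precision for very small p; the
  ## log-scale channel goes further still
  target <- if (is.null(neg_log10_p)) {
    qchisq(p, df = 1, lower.tail = FALSE)
  } else {
    qchisq(-neg_log10_p * log(10), df = 1, lower.tail = FALSE, log.p = TRUE)
  }
  if (target == 0) {
    delta <- 0
  } else {
    ## delta must keep both frequencies inside (0, 1)
    d_max <- if (sgn > 0) min(f0 / w_case, (1 - f0) / w_ctl)
             else min(f0 / w_ctl, (1 - f0) / w_case)
    g <- function(d) {
      f <- freqs(d)
      implied_chisq(f["case"], f["ctl"], t_case, t_ctl) - target
    }
    hi <- d_max * (1 - 1e-12)
    if (g(hi) < 0) {
      stop_msg("p = %.3g unattainable at maf %.3g with these cohort sizes",
               p, maf)
    }
    delta <- uniroot(g, c(0, hi), tol = 1e-14, maxiter = 500)$root
    ## polish by bisection to drive the statistic residual below 1e-10
    lo <- max(0, delta - 1e-6); hi2 <- min(hi, delta + 1e-6)
    if (g(lo) <= 0 && g(hi2) >= 0) {
      for (i in 1:200) {
        mid <- (lo + hi2) / 2
        if (abs(g(mid)) < 1e-12) { delta <- mid; break }
        if (g(mid) < 0) lo <- mid else hi2 <- mid
        delta <- mid
      }
    }
  }
  f <- freqs(delta)
  or <- (f["case"] / (1 - f["case"])) / (f["ctl"] / (1 - f["ctl"]))
  structure(list(target_chi2 = target, or_estimate = unname(or),
                 f_case = unname(f["case"]), f_control = unname(f["ctl"]),
                 delta = delta, mode = mode, direction = direction,
                 achieved_chi2 = implied_chisq(f["case"], f["ctl"],
                                               t_case, t_ctl)),
            class = "or_reconstruction")
}

#' Annotate SNPs linked to a lead SNP with functional intervals
#'
#' Returns every SNP whose LD with the lead exceeds \code{r2_min}
#' (strictly) together with the functional annotation intervals covering
#' its position (point-in-interval on 0-based half-open intervals):
#' TF binding peaks, DNase hypersensitivity, H3K4me1/H3K27ac and the
#' like.
#'
#' @param lead_snp lead SNP id; must appear in the LD table.
#' @param ld_table data frame with columns \code{snp_id}, \code{r2}
#'   (LD with the lead; include the lead itself with r2 = 1).
#' @param r2_min LD threshold, strict; default 0.8.
#' @param annotations data frame with columns \code{type}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open).
#' @param snp_positions data frame with columns \code{snp_id},
#'   \code{chrom}, \code{pos}; required for every linked SNP.
#' @return tibble: snp_id, r2_with_lead, chrom, pos, annotation_type,
#'   annotation_start, annotation_end; one row per (SNP, overlapping
#'   annotation), SNPs without overlap keep one row with NA annotation.
#' @export
annotate_linked_snps <- function(lead_snp, ld_table, r2_min = 0.8,
                                 annotations, snp_positions) {
  if (!lead_snp %in% ld_table$snp_id) {
    stop_msg("lead SNP %s absent from LD table", lead_snp)
  }
  linked <- ld_table[ld_table$r2 > r2_min, , drop = FALSE]
  missing <- setdiff(linked$snp_id, snp_positions$snp_id)
  if (length(missing)) {
    stop_msg("no position for linked SNP(s): %s",
             paste(missing, collapse = ", "))
  }
  pos <- snp_positions[match(linked$snp_id, snp_positions$snp_id), ]
  rows <- lapply(seq_len(nrow(linked)), function(i) {
    hit <- annotations$chrom == pos$chrom[i] &
      annotations$start <= pos$pos[i] & pos$pos[i] < annotations$end
    if (any(hit)) {
      ann <- annotations[hit, , drop = FALSE]
      tibble::tibble(snp_id = linked$snp_id[i], r2_with_lead = linked$r2[i],
                     chrom = pos$chrom[i], pos = pos$pos[i],
                     annotation_type = ann$type,
                     annotation_start = ann$start, annotation_end = ann$end)
    } else {
      tibble::tibble(snp_id = linked$snp_id[i], r2_with_lead = linked$r2[i],
                     chrom = pos$chrom[i], pos = pos$pos[i],
                     annotation_type = NA_character_,
                     annotation_start = NA_integer_,
                     annotation_end = NA_integer_)
    }
  })
  do.call(rbind, rows)
}
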