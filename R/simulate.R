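## Synthetic-data generators emulating the statistical structure of the
## study inputs: a gene annotation, a TF x cell-line ChIP-seq compendium
## with HOT regions and planted age-gene-enriched regulators, an aging
## kidney expression matrix with age- and GFR-driven genes, cytokine
## DE tables with tunable direction concordance, and candidate-gene SNP
## association tables built from exact 2x2 allele tables.
##
## Every generator is deterministic given its seed; one global seed fans
## out to per-generator substreams keyed by stable labels, and each
## generator returns its ground truth alongside the data.  Pipeline code
## never reads the truth; only tests do.

## Each gene reserves an 8 kb promoter footprint (5 kb upstream + 2 kb
## downstream) plus a 1 kb pad so windows never overlap across strands.
GENE_FOOTPRINT <- 8000L

#' Simulate a gene annotation (TSS table)
#'
#' Places \code{n_genes} transcription start sites uniformly across
#' \code{n_chrom} chromosomes without promoter-window overlap; strands
#' are Bernoulli(0.5).
#'
#' @param n_genes number of genes (>= 1).
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param seed integer seed.
#' @return TSS tibble (gene_id, chrom, strand, tss) with a \code{truth}
#'   attribute recording the seed.
#' @export
simulate_genome <- function(n_genes, n_chrom = 1, chrom_length = 1e6,
                            seed = 1) {
  stopifnot(n_genes >= 1, n_chrom >= 1)
  per_chrom <- ceiling(n_genes / n_chrom)
  if (per_chrom * GENE_FOOTPRINT > chrom_length) {
    stop_msg("infeasible gene density: %d genes x %d bp footprint > %g bp",
             per_chrom, GENE_FOOTPRINT, chrom_length)
  }
  with_substream(seed, "genome", {
    chrom <- rep(paste0("chr", seq_len(n_chrom)), length.out = n_genes)
    chrom <- sort(chrom)
    strand <- ifelse(runif(n_genes) < 0.5, "+", "-")
    tss <- integer(n_genes)
    slot <- integer(n_genes)
    i <- 1L
    for (ch in unique(chrom)) {
      k <- sum(chrom == ch)
      ## uniform slot bases with guaranteed 8 kb spacing: sample offsets
      ## in the slack left after reserving k footprints, then stack them
      slack <- chrom_length - k * GENE_FOOTPRINT
      offs <- sort(floor(runif(k, 0, slack)))
      base <- offs + (seq_len(k) - 1L) * GENE_FOOTPRINT
      ## the 7 kb promoter window sits at the slot start whatever the
      ## strand: TSS 5 kb in for + genes, 2 kb in for - genes, leaving a
      ## 1 kb pad at the slot end so windows never overlap across strands
      idx <- i:(i + k - 1L)
      tss[idx] <- as.integer(base + ifelse(strand[idx] == "+", 5000L, 2000L))
      slot[idx] <- as.integer(base)
      i <- i + k
    }
    out <- tss_table(sprintf("G%04d", seq_len(n_genes)), chrom, strand, tss)
    attr(out, "truth") <- list(seed = seed, chrom_length = chrom_length,
                               slot_start = slot)
    out
  })
}

#' Simulate a ChIP-seq compendium with HOT regions and planted regulators
#'
#' For each TF and cell line, generates one experiment of
#' \code{peaks_per_experiment} peaks.  A fixed fraction of each
#' experiment's peaks (\code{round(hot_fraction * peaks_per_experiment)})
#' is placed inside shared HOT (high-occupancy) regions, assigned
#' round-robin so that every TF hits every HOT region whenever that count
#' reaches the number of regions; the rest summit inside a uniformly
#' chosen gene's promoter window.  A planted regulator chooses age genes
#' with probability proportional to its enrichment factor rho relative to
#' non-age genes.  Peak lengths are >= 20 bp and -log10 significances
#' >= 5, matching the compendium's inclusion filters.
#'
#' @param tss TSS tibble from \code{\link{simulate_genome}}.
#' @param n_tfs number of transcription factors.
#' @param cell_lines_per_tf experiments per TF.
#' @param peaks_per_experiment peaks per experiment.
#' @param planted named list \code{tf -> list(rho =, age_gene_ids =)};
#'   TF names must be among the simulated TFs (TF1..TFn).
#' @param hot_fraction fraction of peaks placed in HOT regions, in [0, 1).
#' @param n_hot_regions number of HOT regions; default 3.
#' @param seed integer seed.
#' @return list: \code{peaks} (one combined \code{peak_set}),
#'   \code{truth} (planted_regulators, hot_regions, seed).
#' @export
simulate_chipseq <- function(tss, n_tfs, cell_lines_per_tf = 1,
                             peaks_per_experiment = 200,
                             planted = list(), hot_fraction = 0,
                             n_hot_regions = 3, seed = 1) {
  stopifnot(hot_fraction >= 0, hot_fraction < 1, n_tfs >= 1)
  tf_names <- paste0("TF", seq_len(n_tfs))
  for (nm in names(planted)) {
    if (!nm %in% tf_names) stop_msg("planted TF %s not among the %d TFs",
                                    nm, n_tfs)
    if (planted[[nm]]$rho < 1) stop_msg("planted rho must be >= 1")
  }
  chrom_len <- attr(tss, "truth")$chrom_length
  if (is.null(chrom_len)) chrom_len <- max(tss$tss) + 10000

  with_substream(seed, "chipseq", {
    ## HOT regions: 600 bp intervals parked in the 1 kb pad at the end of
    ## a gene slot, guaranteed clear of every promoter window; summits
    ## cluster tightly so co-bound peaks mutually overlap
    hot <- NULL
    n_hot <- if (hot_fraction > 0) n_hot_regions else 0L
    if (n_hot > 0) {
      slot <- attr(tss, "truth")$slot_start
      if (is.null(slot)) slot <- tss$tss - ifelse(tss$strand == "+",
                                                  5000L, 2000L)
      ch1 <- tss$chrom[1]
      on1 <- which(tss$chrom == ch1)
      anchors <- sort(sample(slot[on1], min(n_hot, length(on1))))
      hot_start <- as.integer(anchors + 7100L)
      hot <- tibble::tibble(chrom = ch1, start = hot_start,
                            end = hot_start + 600L)
      n_hot <- nrow(hot)
    }
    n_genes <- nrow(tss)
    age_mask <- stats::setNames(rep(FALSE, n_genes), tss$gene_id)

    all_peaks <- vector("list", n_tfs * cell_lines_per_tf)
    idx <- 0L
    for (ti in seq_len(n_tfs)) {
      tf <- tf_names[ti]
      w <- rep(1, n_genes)
      if (tf %in% names(planted)) {
        sel <- tss$gene_id %in% planted[[tf]]$age_gene_ids
        w[sel] <- planted[[tf]]$rho
      }
      w <- w / sum(w)
      for (cl in seq_len(cell_lines_per_tf)) {
        idx <- idx + 1L
        n_hot_peaks <- if (n_hot > 0) {
          as.integer(round(hot_fraction * peaks_per_experiment))
        } else 0L
        n_prom <- peaks_per_experiment - n_hot_peaks

        gi <- sample.int(n_genes, n_prom, replace = TRUE, prob = w)
        ## summit uniform in the strand-aware promoter window
        d <- floor(runif(n_prom, -5000, 2001))
        summ_prom <- ifelse(tss$strand[gi] == "+", tss$tss[gi] + d,
                            tss$tss[gi] - d)
        chrom_prom <- tss$chrom[gi]

        if (n_hot_peaks > 0) {
          hri <- ((seq_len(n_hot_peaks) - 1L) %% n_hot) + 1L
          centre <- (hot$start[hri] + hot$end[hri]) %/% 2
          summ_hot <- centre + floor(runif(n_hot_peaks, -40, 41))
          chrom_hot <- hot$chrom[hri]
        } else {
          summ_hot <- integer(); chrom_hot <- character()
        }
        summit <- as.integer(c(summ_prom, summ_hot))
        chrom <- c(chrom_prom, chrom_hot)
        len <- as.integer(floor(runif(length(summit), 100, 401)))
        off <- as.integer(floor(len / 2))
        start <- pmax(0L, summit - off)
        end <- start + len
        sig <- 5 + rexp(length(summit), rate = 1 / 3)
        all_peaks[[idx]] <- peak_set(
          chrom, start, end, summit, sig, tf,
          cell_line = paste0("CL", cl),
          experiment_id = sprintf("%s_CL%d", tf, cl))
      }
    }
    peaks <- do.call(rbind, all_peaks)
    class(peaks) <- c("peak_set", "tbl_df", "tbl", "data.frame")
    list(peaks = peaks,
         truth = list(
           planted_regulators = planted,
           hot_regions = hot,
           tf_names = tf_names,
           seed = seed))
  })
}

#' Simulate an aging-kidney expression matrix
#'
#' Ages are uniform over \code{age_range}; GFR declines linearly with age
#' plus noise.  A fraction of genes is age-driven (expression =
#' mu + beta_age * age + noise, beta_age ~ N(0, beta_age_sd)); of those,
#' a fraction is GFR-mediated instead (expression =
#' mu + beta_gfr * gfr + noise), so their marginal age slope attenuates
#' once GFR enters the regression.  The remaining genes are pure noise.
#'
#' @param genes gene ids (or a TSS tibble, whose gene_id column is used).
#' @param n_samples number of samples; the study profiled 73 renal cortex
#'   samples.
#' @param age_range ages in years, default c(27, 92).
#' @param frac_age_genes fraction of genes that are age-related.
#' @param beta_age_sd SD of planted age slopes (expression units/year).
#' @param gfr_model list(intercept, slope_vs_age, noise_sd) for the GFR
#'   trajectory; defaults to a realistic adult decline
#'   (130 - 0.9/yr, SD 12).
#' @param frac_gfr_mediated fraction of the age-related genes driven by
#'   GFR rather than age directly; the default 0.5 reproduces the study's
#'   observation that the age coefficient attenuates for roughly three
#'   quarters of age-related genes once GFR enters the model (mediated
#'   genes always attenuate, direct ones do so half the time by chance).
#' @param noise_sd residual expression SD.
#' @param detection_rate fraction of genes detectably expressed (their
#'   detection p-values are < 0.01 in every sample; the rest are uniform).
#' @param seed integer seed.
#' @return list: \code{expr} (an \code{ExpressionMatrix}) and
#'   \code{truth} (age_gene_ids, gfr_gene_ids, beta_age, beta_gfr, seed).
#' @export
simulate_expression <- function(genes, n_samples = 73,
                                age_range = c(27, 92),
                                frac_age_genes = 0.1,
                                beta_age_sd = 0.01,
                                gfr_model = list(intercept = 130,
                                                 slope_vs_age = -0.9,
                                                 noise_sd = 12),
                                frac_gfr_mediated = 0.5,
                                noise_sd = 0.3,
                                detection_rate = 1,
                                seed = 1) {
  if (is.data.frame(genes)) genes <- genes$gene_id
  genes <- unique(as.character(genes))
  stopifnot(age_range[1] > 0, age_range[2] < 120,
            frac_age_genes >= 0, frac_age_genes <= 1,
            frac_gfr_mediated >= 0, frac_gfr_mediated <= 1)
  n_genes <- length(genes)
  with_substream(seed, "expression", {
    age <- runif(n_samples, age_range[1], age_range[2])
    gfr <- gfr_model$intercept + gfr_model$slope_vs_age * age +
      rnorm(n_samples, 0, gfr_model$noise_sd)
    gfr <- pmax(gfr, 5)

    n_age <- round(frac_age_genes * n_genes)
    age_idx <- if (n_age > 0) sample.int(n_genes, n_age) else integer()
    n_gfr <- round(frac_gfr_mediated * n_age)
    gfr_idx <- if (n_gfr > 0) age_idx[seq_len(n_gfr)] else integer()
    dir_idx <- setdiff(age_idx, gfr_idx)

    beta_age <- setNames(rep(0, n_genes), genes)
    beta_gfr <- setNames(rep(0, n_genes), genes)
    beta_age[dir_idx] <- rnorm(length(dir_idx), 0, beta_age_sd)
    ## scale GFR betas so the induced marginal age effect is comparable
    beta_gfr[gfr_idx] <- rnorm(length(gfr_idx), 0,
                               beta_age_sd / abs(gfr_model$slope_vs_age))

    mu <- rnorm(n_genes, 8, 1)
    vals <- matrix(rnorm(n_genes * n_samples, 0, noise_sd),
                   nrow = n_genes)
    vals <- vals + mu +
      outer(beta_age, age) + outer(beta_gfr, gfr)
    rownames(vals) <- genes
    colnames(vals) <- sprintf("S%03d", seq_len(n_samples))

    det <- matrix(runif(n_genes * n_samples, 0, 0.009), nrow = n_genes,
                  dimnames = dimnames(vals))
    if (detection_rate < 1) {
      undet <- sample.int(n_genes, round((1 - detection_rate) * n_genes))
      det[undet, ] <- runif(length(undet) * n_samples, 0.01, 1)
    }
    expr <- expression_matrix(vals, age, gfr = gfr, detection_p = det)
    list(expr = expr,
         truth = list(age_gene_ids = genes[dir_idx],
                      gfr_gene_ids = genes[gfr_idx],
                      beta_age = beta_age, beta_gfr = beta_gfr,
                      seed = seed))
  })
}

#' Simulate a cytokine-stimulation DE table with tunable concordance
#'
#' Each target gene is induced with probability \code{p_induced}
#' (positive log2 fold-change, |N(effect_mu, effect_sd)|), otherwise
#' repressed; with probability \code{concordance_c} an induced target's
#' age slope is set positive (else negative).  An induced target's slope
#' magnitude scales with its induction strength (stronger cytokine
#' induction, steeper aging trend), so the expected Pearson correlation
#' between fold-change and age slope is positive whenever c > 0.5 and
#' grows with c.  DE p-values for targets are drawn below 0.05,
#' non-targets uniform on (0, 1).
#'
#' @param target_genes gene ids of the TF's bound targets.
#' @param age_slopes named numeric vector of age slopes over a gene
#'   universe including the targets; non-target genes pass through.
#' @param concordance_c probability an induced target ages upward.
#' @param effect_mu,effect_sd log2 fold-change magnitude parameters.
#' @param p_induced probability a target is induced rather than
#'   repressed.
#' @param perturbation label for the DE table.
#' @param seed integer seed.
#' @return list: \code{de} (DE table over the full slope universe),
#'   \code{age_slopes} (the adjusted slopes), \code{truth}
#'   (true_concordance, induced_targets, seed).
#' @export
simulate_cytokine_response <- function(target_genes, age_slopes,
                                       concordance_c = 0.875,
                                       effect_mu = 1, effect_sd = 0.5,
                                       p_induced = 0.8,
                                       perturbation = "cytokine",
                                       seed = 1) {
  stopifnot(concordance_c >= 0, concordance_c <= 1,
            all(target_genes %in% names(age_slopes)))
  with_substream(seed, paste0("cytokine_", perturbation), {
    universe <- names(age_slopes)
    is_target <- universe %in% target_genes
    n <- length(universe)
    log2fc <- rnorm(n, 0, 0.1)
    p <- runif(n)
    induced <- rep(FALSE, n)
    ti <- which(is_target)
    induced[ti] <- runif(length(ti)) < p_induced
    mag <- abs(rnorm(length(ti), effect_mu, effect_sd)) + 1e-6
    log2fc[ti] <- ifelse(induced[ti], mag, -mag)
    p[ti] <- runif(length(ti), 0, 0.05)

    slopes <- age_slopes
    ind_idx <- which(induced)
    up <- runif(length(ind_idx)) < concordance_c
    ## slope magnitude proportional to induction strength, rescaled into
    ## the ambient slope units (median |slope| per unit of effect_mu)
    slope_scale <- stats::median(abs(age_slopes[age_slopes != 0]))
    if (!is.finite(slope_scale) || slope_scale == 0) slope_scale <- 0.01
    mag_slope <- abs(log2fc[ind_idx]) * slope_scale / max(effect_mu, 1e-6)
    slopes[ind_idx] <- pmax(mag_slope, 1e-9) * ifelse(up, 1, -1)

    de <- tibble::tibble(gene_id = universe, log2fc = log2fc, p = p,
                         perturbation = perturbation,
                         degenerate = FALSE)
    list(de = de, age_slopes = slopes,
         truth = list(true_concordance = concordance_c,
                      induced_targets = universe[induced],
                      target_genes = target_genes, seed = seed))
  })
}

## Forward construction shared with estimate_allelic_or's parameterization:
## given pooled minor frequency and an odds ratio, solve for the
## case/control frequency split that keeps the pooled frequency exact.
or_to_freqs <- function(or, maf, n_cases, n_controls) {
  t_case <- 2 * n_cases; t_ctl <- 2 * n_controls
  w_case <- t_case / (t_case + t_ctl)
  w_ctl <- t_ctl / (t_case + t_ctl)
  if (or == 1) return(c(case = maf, ctl = maf))
  sgn <- if (or > 1) 1 else -1
  d_max <- if (sgn > 0) min(maf / w_case, (1 - maf) / w_ctl)
           else min(maf / w_ctl, (1 - maf) / w_case)
  g <- function(d) {
    fc <- maf + sgn * d * w_ctl
    f0 <- maf - sgn * d * w_case
    (fc / (1 - fc)) / (f0 / (1 - f0)) - or
  }
  if (g(d_max * (1 - 1e-9)) * sgn < 0) {
    stop_msg("odds ratio %.3g incompatible with maf %.3g", or, maf)
  }
  d <- uniroot(g, c(0, d_max * (1 - 1e-9)), tol = 1e-14)$root
  c(case = maf + sgn * d * w_ctl, ctl = maf - sgn * d * w_case)
}

#' Simulate candidate-gene SNP association records
#'
#' Builds, per SNP, the exact expected-count 2x2 allele table with the
#' requested pooled minor-allele frequency and allelic odds ratio,
#' computes its Pearson chi-square p-value (1 df, no continuity
#' correction) and emits a summary-statistics record.  Within a gene the
#' first SNP carries the full odds ratio (the intended lead); the others
#' carry effects attenuated toward 1.
#'
#' @param genes candidate gene names.
#' @param snps_per_gene SNPs per gene.
#' @param true_or per-gene allelic odds ratio for eGFR (recycled);
#'   the CKD phenotype uses \code{true_or_ckd} (default 1: null).
#' @param true_or_ckd per-gene odds ratio for the CKD phenotype.
#' @param maf pooled minor-allele frequency, either a scalar used as the
#'   center of a U(maf - 0.05, maf + 0.05) draw per SNP or a vector.
#' @param n_cases,n_controls cohort sizes.
#' @param seed integer seed.
#' @return list: \code{records} (association tibble as from
#'   \code{\link{read_assoc}}, plus \code{neg_log10_p_*} columns carrying
#'   full precision where the linear p-value underflows) and \code{truth}
#'   (per-SNP true ORs, seed).
#' @export
simulate_assoc <- function(genes, snps_per_gene = 5, true_or = 1.2,
                           true_or_ckd = 1, maf = 0.3,
                           n_cases = 5000, n_controls = 50000, seed = 1) {
  stopifnot(all(true_or > 0), all(maf > 0), all(maf <= 0.5))
  true_or <- rep(true_or, length.out = length(genes))
  true_or_ckd <- rep(true_or_ckd, length.out = length(genes))
  with_substream(seed, "assoc", {
    rows <- list(); or_truth <- list()
    snp_counter <- 0L
    for (gi in seq_along(genes)) {
      for (si in seq_len(snps_per_gene)) {
        snp_counter <- snp_counter + 1L
        snp_id <- sprintf("rs%06d", snp_counter)
        m <- if (length(maf) > 1) maf[((snp_counter - 1) %% length(maf)) + 1]
             else min(0.5, max(0.01, maf + runif(1, -0.05, 0.05)))
        atten <- if (si == 1) 1 else runif(1, 0.1, 0.7)
        or_e <- 1 + (true_or[gi] - 1) * atten
        or_c <- 1 + (true_or_ckd[gi] - 1) * atten
        p_e <- or_to_pvalue(or_e, m, n_cases, n_controls)
        p_c <- or_to_pvalue(or_c, m, n_cases, n_controls)
        rows[[snp_counter]] <- tibble::tibble(
          snp_id = snp_id, gene = genes[gi],
          p_egfr = p_e$p, p_ckd = p_c$p,
          neg_log10_p_egfr = p_e$neg_log10_p,
          neg_log10_p_ckd = p_c$neg_log10_p,
          major = "C", minor = "T", maf = m,
          n_cases = n_cases, n_controls = n_controls)
        or_truth[[snp_counter]] <- tibble::tibble(
          snp_id = snp_id, gene = genes[gi],
          true_or_egfr = or_e, true_or_ckd = or_c, maf = m)
      }
    }
    records <- validate_assoc(do.call(rbind, rows))
    list(records = records,
         truth = list(or = do.call(rbind, or_truth), seed = seed))
  })
}

## chi-square p-value of the exact expected-count allele table at a
## given odds ratio; linear p capped into (0, 1], -log10 p kept at full
## precision for associations whose linear p underflows
or_to_pvalue <- function(or, maf, n_cases, n_controls) {
  f <- or_to_freqs(or, maf, n_cases, n_controls)
  stat <- implied_chisq(f["case"], f["ctl"], 2 * n_cases, 2 * n_controls)
  lp <- pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE)
  p <- min(max(exp(lp), .Machine$double.xmin), 1)
  list(p = p, neg_log10_p = -lp / log(10))
}
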