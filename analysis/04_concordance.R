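#!/usr/bin/env Rscript

## Stage 4: cytokine-response direct targets and aging concordance.
##
## Defines direct targets (bound in ChIP-seq and differentially
## expressed on cytokine stimulation), restricts to TF-exclusive sets,
## and quantifies how the induced targets behave during kidney aging:
## direction concordance (one-sided binomial against 0.5) and the
## Pearson correlation between induction log2 fold-change and age slope.

suppressMessages(library(renalage))
simdir <- "results/sim"
seed <- 1

fit_age <- read.delim("results/age_model.tsv")
slopes <- setNames(fit_age$beta_age, fit_age$gene_id)

tm <- read.delim("results/screen_experiments.tsv")   # experiment metadata
targets_tbl <- {
  peaks <- read_peaks(file.path(simdir, "compendium.narrowPeak"))
  tss <- read_tss(file.path(simdir, "tss.tsv"))
  cx <- compute_complexity(peaks)
  assign_peaks_to_genes(filter_by_complexity(cx, n_tfs = length(unique(peaks$tf))),
                        tss)
}

## three cytokine stimulations drive the top three screened TFs
tf_summary <- read.delim("results/screen_tf_summary.tsv")
tfs <- tf_summary$tf[1:3]
cytokine_of <- setNames(c("TNFa", "IFNg", "IL6"), tfs)

sets <- list(); de_tables <- list()
for (tf in tfs) {
  bound <- unique(targets_tbl$gene_id[targets_tbl$tf == tf])
  sim <- simulate_cytokine_response(bound, slopes, concordance_c = 0.875,
                                    p_induced = 0.8,
                                    perturbation = cytokine_of[tf],
                                    seed = seed + match(tf, tfs))
  de_tables[[tf]] <- sim$de
  slopes <- sim$age_slopes            # slopes now carry the planted signs
  sets[[tf]] <- define_direct_targets(bound, sim$de, p_max = 0.05, tf = tf)
}
sets <- exclusive_targets(sets)

rows <- list()
for (tf in tfs) {
  genes <- sets[[tf]]$genes
  de_t <- de_tables[[tf]][de_tables[[tf]]$gene_id %in% genes, ]
  ct <- concordance_test(de_t, slopes)
  pc <- profile_correlation(de_t$log2fc, slopes[de_t$gene_id])
  rows[[tf]] <- data.frame(tf = tf, cytokine = cytokine_of[tf],
                           n_direct = length(genes),
                           n_induced = ct$n_induced,
                           concordance_pct = ct$concordance_pct,
                           p_binomial = ct$p_binomial,
                           r = pc$r, p_r = pc$p)
  cat(sprintf("%s (%s): %d direct targets, %d induced, %.0f%% concordant (p = %.2g), r = %.2f\n",
              tf, cytokine_of[tf], length(genes), ct$n_induced,
              ct$concordance_pct, ct$p_binomial, pc$r))
}
write.table(do.call(rbind, rows), "results/concordance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## long-format table for heat-map rendering (gene, log2fc, age slope)
long <- do.call(rbind, lapply(tfs, function(tf) {
  g <- sets[[tf]]$genes
  data.frame(tf = tf, gene_id = g,
             log2fc = de_tables[[tf]]$log2fc[match(g, de_tables[[tf]]$gene_id)],
             age_slope = unname(slopes[g]))
}))
write.table(long, "results/targets_long.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## cross-species comparison against a simulated rat old-vs-young profile:
## orthologs share the human direction for most genes
set.seed(seed + 11)
hum_genes <- fit_age$gene_id
map <- data.frame(human = hum_genes, other = paste0("r", hum_genes))
rat_fc <- 30 * slopes[hum_genes] * ifelse(runif(length(hum_genes)) < 0.8, 1, -1) +
  rnorm(length(hum_genes), 0, 0.03)
## rat significance follows the effect size, as a real DE test's would
rat_de <- data.frame(gene_id = map$other, log2fc = unname(rat_fc),
                     p = 2 * pnorm(-abs(rat_fc) / 0.06),
                     perturbation = "rat_aging")
xs <- cross_species_overlap(hum_genes, slopes, map, rat_de,
                            other_sig_p = 0.05,
                            human_sig_genes = fit_age$gene_id[fit_age$p_age < 0.05])
cat(sprintf("cross-species: r = %.2f (p = %.2g), %d/%d shared significant, fold %.2f (p = %.2g)\n",
            xs$r, xs$p_r, xs$n_shared_sig, xs$n_universe, xs$fold, xs$p_hyper))
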