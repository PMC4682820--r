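#!/usr/bin/env Rscript

## Stage 5: TF activity scores and macrophage-marker covariation.
##
## Scores per-sample activity of each TF as the mean z-score of its
## direct targets, removes the age trend by OLS residuals, and clusters
## the age-adjusted activity profiles together with a macrophage
## marker-abundance score (Pearson correlation, average linkage).  In a
## latent "inflammatory infiltration" factor world the TF activities
## covary with the marker score beyond what age alone explains.

suppressMessages(library(renalage))
simdir <- "results/sim"
seed <- 1

expr <- read_expression(file.path(simdir, "expression.tsv"),
                        file.path(simdir, "samples.tsv"))
targets_long <- read.delim("results/targets_long.tsv")
tfs <- unique(targets_long$tf)

## plant a shared infiltration factor plus TF-specific factors into the
## target genes, and the shared factor alone into three marker
## transcripts, so the covariation stage has realistic structure: TF
## activities correlate with each other and with the marker score
## without saturating at r = 1
set.seed(seed + 21)
n_s <- length(expr$samples)
latent <- rnorm(n_s)
l_shared <- sqrt(0.5)                  # shared-factor loading
l_tf <- sqrt(0.2)                      # TF-specific loading
vals <- expr$values
marker_genes <- c("CD163", "CD14", "TYROBP")
markers <- l_shared * matrix(rep(latent, 3), 3, byrow = TRUE,
                             dimnames = list(marker_genes, expr$samples)) +
  matrix(rnorm(3 * n_s, 0, sqrt(0.5)), 3) + 7
for (tf in tfs) {
  g <- intersect(targets_long$gene_id[targets_long$tf == tf], rownames(vals))
  f_tf <- rnorm(n_s)
  vals[g, ] <- vals[g, ] +
    matrix(rep(l_shared * latent + l_tf * f_tf, length(g)),
           length(g), byrow = TRUE)
}
expr2 <- expression_matrix(rbind(vals, markers), expr$age, gfr = expr$gfr)

profiles <- lapply(tfs, function(tf) {
  g <- intersect(targets_long$gene_id[targets_long$tf == tf], expr2$genes)
  activity_profile(expr2, g, tf)
})
profiles <- c(profiles, list(marker_abundance_score(expr2, marker_genes)))

cv <- covariation(profiles)
write.table(round(cv$r, 4), "results/activity_correlation.tsv",
            sep = "\t", quote = FALSE)
long <- do.call(rbind, lapply(profiles, function(p) {
  data.frame(label = p$label, sample = p$samples,
             raw = unname(p$raw), adjusted = unname(p$adjusted))
}))
write.table(long, "results/activity_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("age-adjusted activity correlations:\n")
print(round(cv$r, 2))
cat("dendrogram leaf order:", paste(cv$leaf_order, collapse = " | "), "\n")
mk <- "macrophage_markers"
r_marker <- cv$r[setdiff(rownames(cv$r), mk), mk]
cat(sprintf("TF activity vs macrophage markers: r in [%.2f, %.2f]\n",
            min(r_marker), max(r_marker)))
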