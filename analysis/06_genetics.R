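#!/usr/bin/env Rscript

## Stage 6: candidate-gene SNP analysis.
##
## Bonferroni threshold over SNP x phenotype tests, per-gene lead SNPs,
## allelic odds-ratio reconstruction from summary statistics by
## chi-square matching, and functional annotation of SNPs in strong LD
## (R^2 > 0.8) with a lead SNP.

suppressMessages(library(renalage))
simdir <- "results/sim"
seed <- 1

rec <- read_assoc(file.path(simdir, "assoc.tsv"))
n_snps <- nrow(rec)
b <- bonferroni_threshold(n_snps = n_snps, n_phenotypes = 2)
cat(sprintf("%d SNPs x 2 phenotypes: per-test threshold %s (exact %.3g)\n",
            n_snps, b$rendered, b$threshold))

leads <- list()
for (ph in c("egfr", "ckd")) {
  ld <- select_lead_snps(rec, ph, b$threshold)
  ld$phenotype <- ph
  leads[[ph]] <- ld
  for (i in seq_len(nrow(ld))) {
    cat(sprintf("  %s lead for %s: %s, p = %.3g%s\n", ph, ld$gene[i],
                ld$snp_id[i], ld$p[i],
                if (ld$significant[i]) " *" else ""))
  }
}
leads <- do.call(rbind, leads)

## reconstruct the allelic odds ratio of each significant lead from its
## summary statistics alone
ors <- lapply(which(leads$significant), function(i) {
  row <- rec[rec$snp_id == leads$snp_id[i], ]
  est <- estimate_allelic_or(row[[paste0("p_", leads$phenotype[i])]],
                             row$maf, row$n_cases, row$n_controls)
  data.frame(snp_id = row$snp_id, gene = row$gene,
             phenotype = leads$phenotype[i],
             or = est$or_estimate, f_case = est$f_case,
             f_control = est$f_control)
})
ors <- do.call(rbind, ors)
if (!is.null(ors)) {
  write.table(ors, "results/lead_snp_or.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(ors))) {
    cat(sprintf("  reconstructed allelic OR for %s (%s): %.3f\n",
                ors$snp_id[i], ors$gene[i], ors$or[i]))
  }
}
write.table(leads, "results/lead_snps.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## LD neighbourhood of the top lead: annotate strongly linked SNPs with
## regulatory intervals (synthetic LD table and annotation intervals)
set.seed(seed + 31)
lead <- leads$snp_id[which.min(leads$p)]
nbr <- paste0(lead, letters[1:10])
ld_tab <- data.frame(snp_id = c(lead, nbr),
                     r2 = c(1, round(runif(10, 0.3, 0.99), 2)))
pos <- data.frame(snp_id = c(lead, nbr), chrom = "chr4",
                  pos = as.integer(103420000 + seq(0, 45000, length.out = 11)))
ann_start <- as.integer(103420000 + seq(2000, 44000, by = 3500))
ann <- data.frame(type = rep(c("TF_peak", "DNase", "H3K4me1", "H3K27ac"),
                             length.out = length(ann_start)),
                  chrom = "chr4", start = ann_start, end = ann_start + 2500L)
linked <- annotate_linked_snps(lead, ld_tab, 0.8, ann, pos)
write.table(linked, "results/linked_snp_annotations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d SNPs in LD R^2 > 0.8 with %s; %d carry regulatory annotations\n",
            length(unique(linked$snp_id)), lead,
            length(unique(linked$snp_id[!is.na(linked$annotation_type)]))))
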