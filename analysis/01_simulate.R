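#!/usr/bin/env Rscript

## Stage 1: generate the synthetic study inputs.
##
## Emulates the structure of the real data: a gene annotation, a ChIP-seq
## compendium (15 TFs x 2 cell lines here; the full study screened 961
## experiments for 161 TFs) with HOT regions and one planted age-gene
## regulator, a 73-sample aging-kidney expression matrix with age- and
## GFR-driven genes, a cytokine-response DE table, and a candidate-gene
## SNP association table.  Writes everything under results/sim/ in the
## pipeline's standard formats, ground truth as JSON sidecars.

suppressMessages(library(renalage))
seed <- 1
outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

tss <- simulate_genome(400, n_chrom = 2, chrom_length = 4e6, seed = seed)
write.table(tss, file.path(outdir, "tss.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

set.seed(seed + 101)
age_genes <- sort(sample(tss$gene_id, 80))
writeLines(age_genes, file.path(outdir, "age_genes.txt"))

chip <- simulate_chipseq(tss, n_tfs = 15, cell_lines_per_tf = 2,
                         peaks_per_experiment = 250,
                         planted = list(TF1 = list(rho = 8,
                                                   age_gene_ids = age_genes)),
                         hot_fraction = 0.15, seed = seed + 1)
write_peaks(chip$peaks, file.path(outdir, "compendium.narrowPeak"))

expr <- simulate_expression(tss$gene_id, n_samples = 73, seed = seed + 2)
m <- expr$expr
write.table(data.frame(gene = m$genes, m$values, check.names = FALSE),
            file.path(outdir, "expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = m$samples, age = m$age, gfr = m$gfr),
            file.path(outdir, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

assoc <- simulate_assoc(c("NFKB1", "RELA", "STAT1", "STAT3"),
                        snps_per_gene = 55, true_or = c(1.15, 1.2, 1.02, 1.02),
                        true_or_ckd = c(1.02, 1.09, 1.0, 1.0),
                        seed = seed + 3)
write.table(assoc$records, file.path(outdir, "assoc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- list(
  seed = seed,
  planted_regulator = "TF1", rho = 8,
  age_genes = age_genes,
  hot_regions = as.data.frame(chip$truth$hot_regions),
  expression = expr$truth[c("age_gene_ids", "gfr_gene_ids")],
  assoc_or = as.data.frame(assoc$truth$or))
writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
           file.path(outdir, "truth.json"))

cat(sprintf("wrote %s: %d genes, %d peaks across %d experiments, %d samples, %d SNPs\n",
            outdir, nrow(tss), nrow(chip$peaks),
            length(unique(chip$peaks$experiment_id)),
            length(m$samples), nrow(assoc$records)))
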