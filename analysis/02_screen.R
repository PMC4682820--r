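#!/usr/bin/env Rscript

## Stage 2: complexity-filtered ChIP-seq target-enrichment screen.
##
## Reads the simulated compendium, drops high-occupancy (HOT) sites
## (complexity above 50% of the compendium's TF count), assigns the
## surviving peaks to genes through the -5 kb/+2 kb promoter window
## around each TSS, and screens every experiment's target set for
## overlap enrichment with the age-related genes (chi-square or Fisher,
## Bonferroni over experiments, fold > 1.5).

suppressMessages(library(renalage))
simdir <- "results/sim"

peaks <- read_peaks(file.path(simdir, "compendium.narrowPeak"),
                    sig_threshold = 1e-5, min_length = 20)
tss <- read_tss(file.path(simdir, "tss.tsv"))
age_genes <- readLines(file.path(simdir, "age_genes.txt"))

n_tfs <- length(unique(peaks$tf))
cx <- compute_complexity(peaks)
filt <- filter_by_complexity(cx, n_tfs = n_tfs)
cat(sprintf("complexity filter (<= %d of %d TFs): %d of %d peaks kept\n",
            ceiling(0.5 * n_tfs), n_tfs, nrow(filt), nrow(cx)))

tm <- assign_peaks_to_genes(filt, tss)
scr <- screen_experiments(tm, age_genes, universe = unique(tss$gene_id))

write.table(scr$results, "results/screen_experiments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(scr$tf_summary, "results/screen_tf_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("screened %d experiments; Bonferroni p threshold %.3g\n",
            nrow(scr$results), scr$p_threshold))
cat("candidate regulators:", paste(scr$candidates, collapse = ", "), "\n")
top <- scr$tf_summary[1, ]
cat(sprintf("top TF %s: fold %.2f, p %.3g (%s)\n",
            top$tf, top$best_fold, top$best_p, top$best_experiment))

## specificity control: the candidate should not light up for unrelated
## gene sets; screen 5 random query sets of the same size
set.seed(7)
universe <- unique(tss$gene_id)
res_sets <- c(list(age = scr$results),
              setNames(lapply(1:5, function(i) {
                screen_experiments(tm, sample(universe, length(age_genes)),
                                   universe)$results
              }), paste0("random", 1:5)))
spec <- specificity_filter(res_sets, tf = top$tf)
write.table(spec, "results/screen_specificity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("specificity: %s flagged in %d of %d query sets\n",
            top$tf, sum(tapply(spec$flagged, spec$query_set, any)),
            length(res_sets)))
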