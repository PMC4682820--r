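# renalage

Identifying transcription-factor drivers of the kidney-aging
transcriptome.

Human kidneys accumulate stereotyped gene-expression changes with age,
and those changes track renal function (glomerular filtration rate,
GFR) and histopathology, not just chronological age. `renalage`
implements the computational program for finding the upstream
regulators of that signature and is aimed at computational biologists
working with regulatory compendia, aging transcriptomes and GWAS
summary statistics:

1. **ChIP-seq target-enrichment screen** — peaks filtered by
   significance (q < 10⁻⁵, −log10 scale) and length (≥ 20 bp),
   high-occupancy ("HOT") sites removed by a binding-complexity filter
   (keep peaks bound by ≤ ⌈0.5·N_TF⌉ distinct factors; 81 of 161 at
   compendium scale), summits assigned to genes through a strand-aware
   −5 kb/+2 kb promoter window, and each experiment's target set tested
   for overlap with the age-related genes: χ² (1 df, no continuity
   correction) when all expected counts exceed 5, otherwise a one-sided
   Fisher exact (hypergeometric upper tail), with candidates requiring
   fold > 1.5 and Bonferroni-corrected p, exclusion of general
   DNA-binding machinery, and a top-5% specificity control across
   unrelated gene sets.
2. **Age/GFR expression regression** — per-gene OLS of log2 expression
   on age (± GFR), and the attenuation analysis: for what fraction of
   age-related genes does |β_age| shrink when GFR enters the model?
3. **Cytokine-response concordance** — direct targets = bound ∧
   differentially expressed on stimulation (p < 0.05); among induced
   targets, concordance = share with positive age slope, tested against
   a binomial(n, ½) upper tail; Pearson correlation of induction log2FC
   with age slopes; cross-species (human–rat) overlap by hypergeometric
   enrichment within an ortholog universe.
4. **TF activity covariation** — per-sample activity = mean target-gene
   z-score (sample sd), age-adjusted by OLS residuals, clustered with
   macrophage marker scores (CD163/CD14/TYROBP) by 1 − r distance,
   average linkage.
5. **Candidate-gene genetics** — Bonferroni threshold over SNP ×
   phenotype tests, per-gene lead SNPs, allelic odds-ratio
   reconstruction from summary statistics by χ² matching (find the 2×2
   allele table reproducing the association p at fixed pooled MAF), and
   functional annotation of SNPs in strong LD (R² > 0.8) with a lead.

A synthetic-data module generates all of these inputs with known
ground truth — planted enriched regulators, HOT regions, age- and
GFR-driven genes, tunable direction concordance, exact χ²-matched
association tables — so the full pipeline runs and is validated
without any external data.

## Worked example

```r
library(renalage)

# multiple-testing threshold for 217 candidate-gene SNPs x 2 phenotypes
b <- bonferroni_threshold(n_snps = 217, n_phenotypes = 2, alpha = 0.05)
b$threshold   # 0.0001152074
b$rendered    # "1.1e-04"

# 35 of 40 cytokine-induced NFkB targets are also induced with age
cc <- concordance_from_counts(35, 40)
cc$concordance_pct   # 87.5  (prints as 88%)
cc$p_binomial        # 6.91306e-07  -- far below 1e-5

# reconstruct an allelic odds ratio from summary statistics alone
or <- estimate_allelic_or(p = 8.0e-5, maf = 0.2,
                          n_cases = 5807, n_controls = 61286)
or$or_estimate   # 1.098093
or$f_case        # 0.2139924  implied case minor-allele frequency
or$f_control     # 0.1986742  implied control minor-allele frequency
```

The threshold is the per-test cut-off that makes 0.05 family-wise over
434 tests; the concordance p-value is the exact binomial tail, so a
result like 35/40 is overwhelmingly unlikely under direction symmetry;
the reconstructed odds ratio is the unique allelic 2×2 table whose
Pearson χ² reproduces the input p-value at the given pooled
minor-allele frequency and cohort sizes.

## The analysis workflow

`analysis/` contains the pipeline as numbered drivers over the package
functions, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # synthetic genome, compendium, expression, SNPs
Rscript analysis/02_screen.R      # complexity filter + enrichment screen + specificity
Rscript analysis/03_expression.R  # age/GFR regression and attenuation
Rscript analysis/04_concordance.R # direct targets, concordance, cross-species
Rscript analysis/05_activity.R    # activity scores, macrophage covariation
Rscript analysis/06_genetics.R    # lead SNPs, odds ratios, LD annotation
```

On the default seed the screen recovers the planted regulator at rank
1 (fold 2.85, p ≈ 9e-35, flagged in the age gene set and in none of
five random control sets), the attenuation stage reports the age
coefficient shrinking for 65% of the planted age-related genes when
GFR is added, the concordance stage finds 83–89% direction concordance
with binomial p down to 2e-8, the activity stage reports age-adjusted
TF–macrophage correlations around 0.71–0.72, and the genetics stage
reconstructs the planted odds ratios (1.150 and 1.200) from the
emitted summary statistics.

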