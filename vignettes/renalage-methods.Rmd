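---
title: "Methods: screening for transcription-factor drivers of the kidney-aging transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for transcription-factor drivers of the kidney-aging transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalage)
```

# The scientific problem

Gene expression in the human kidney changes with age in a reproducible
way: hundreds of transcripts rise or fall with chronological age, and
those changes track renal histopathology and function (glomerular
filtration rate, GFR) rather than age alone.  The question this package
addresses is *what drives* that transcriptional program.  Its strategy
is the one large regulatory compendia make possible: if a transcription
factor's ChIP-seq binding targets are strongly over-represented among
the age-related genes, that factor is a candidate upstream regulator,
and its candidacy can then be probed with cytokine-stimulation
experiments, per-sample activity scores and human genetic association
data.

The package implements every computational stage of that program as
reusable functions, and pairs them with a synthetic-data generator that
reproduces the statistical structure of the real inputs so the whole
pipeline can be exercised, tested and calibrated without any external
downloads.  The `analysis/` scripts run the stages in order on
generated data; the functions are equally usable on real peak files,
expression matrices and association tables in the standard formats.

# Stage by stage

## Peak filtering and promoter-window assignment

ChIP-seq peaks enter through `read_peaks()`, which applies the
compendium's inclusion filters: a peak-caller significance of
q (or p) < 1e-5 — applied on the `-log10`-scaled narrowPeak columns,
q when non-negative, else p — and a minimum length of 20 bp (length
≥ 20 is kept; shorter peaks are discarded).  Coordinates are BED
convention throughout: 0-based, half-open `[start, end)`.

A gene is a *target* of an experiment (`assign_peaks_to_genes()`) iff
some peak's summit — the position of maximum read density, never the
whole interval — falls within 5 kb upstream to 2 kb downstream of one
of the gene's transcription start sites, strand-aware.  The window is
inclusive at both ends (−5000 ≤ d ≤ 2000 in signed promoter
coordinates): "within" does not specify the boundary, so the package
pins one convention and the test suite asserts it at every edge.  A
gene with several annotated TSS matches if any of them does; the TSS
reader deliberately keeps duplicate gene ids for this reason.

## Binding-site complexity (HOT regions)

Regulatory compendia contain high-occupancy (HOT) regions bound by a
large fraction of all assayed factors; overlap screens that ignore them
reward promiscuous binding rather than specific regulation.
`compute_complexity()` scores each peak by the number of *distinct*
transcription factors with a significant site overlapping it by ≥ 1 bp
(its own factor included; replicate cell lines of one factor count
once).  `filter_by_complexity()` then retains peaks with complexity
≤ `ceiling(max_fraction * n_tfs)`.  At the compendium scale of 161
factors and the default 50% fraction this threshold is 81 — "bound by
81 or fewer factors".  A threshold of 81-or-fewer versus
strictly-below-81 differs by one unit; the package follows the
or-fewer convention and exposes `max_fraction` so either reading is a
one-argument change.

## The enrichment screen

`overlap_enrichment()` forms the 2×2 membership table of target set ×
query set over a gene universe.  Test selection follows the classical
validity rule: the Pearson chi-square test (1 df, no continuity
correction) when all four *expected* cell counts exceed 5, otherwise
the one-sided Fisher exact test.  The Fisher tail is one-sided in the
enrichment direction — the screen looks for over-representation only —
computed as the hypergeometric upper tail.  The chi-square statistic is
inherently two-sided; a depleted experiment can therefore produce a
small chi-square p, but it can never satisfy the fold criterion, so the
candidate logic is unaffected.  Fold enrichment is observed over
expected overlap, expected = |targets|·|query|/|universe|.  The default
universe is the set of genes represented on the expression platform.

`screen_experiments()` ranks experiments by p and calls a factor a
candidate iff (a) it is not on the exclusion list (non-specific
DNA-binding machinery — polymerase-associated factors, CTCF, RAD21,
TAF1, p300 and the like — which would otherwise dominate any screen),
(b) it is on the epithelial-expression allow-list when one is supplied
(factors expressed only in infiltrating immune cells would otherwise
appear enriched), and (c) its best experiment shows fold > 1.5 at
Bonferroni-corrected significance.  The Bonferroni denominator is the
number of experiments tested; with 961 experiments at family-wise
α = 0.05 the per-test threshold is conventionally printed as 5e-5, and
a literal override argument reproduces exactly that printed cut-off
when desired.

`specificity_filter()` is the control for the converse worry — a
factor that lights up for *any* differentially-regulated gene set is
not a kidney-aging regulator.  For each query gene set screened against
the compendium, an experiment is flagged only if it passes fold > 1.5,
p < 5e-5 *and* ranks in the top 5% of experiments for that set
(ties: larger fold, then lexicographic experiment id).

## Expression statistics

`detection_filter()` keeps genes with detection p < 0.01 in at least
one sample.  `differential_expression()` is the classical
pooled-variance (Student, not Welch) two-sided t-test per gene, with
log2 fold-change as the difference of group means on already-log2
data; the degenerate zero-variance cases are defined explicitly (equal
means → p = 1; unequal means with zero variance → smallest
representable p, flagged).  `collapse_probes()` resolves multi-probe
genes to the most differentially expressed probe (smallest p, ties by
|log2fc|, then probe id).  `fit_age_model()` fits per-gene OLS of
expression on intercept + age, optionally + GFR, returning the age
slope (expression units per year), its standard error and p-value; the
fits are computed by a single shared-design closed form across genes
and are tested to agree with `lm()` per gene.

`gfr_attenuation()` compares the two fits: for genes informative of
renal function the age-coefficient magnitude shrinks when GFR enters
the model.  Equal magnitudes count as not reduced.  The headline
fraction on real data (74% of age-related genes) depends on the
external microarray data and is not reproduced here; the synthetic
substitute plants a known mixture of directly age-driven and
GFR-mediated genes and verifies the closed-form behaviour (a noiseless
GFR-mediated gene has age slope exactly 0 once GFR is included) and
the null calibration (an independent covariate attenuates a fair-coin
fraction of genes).

## Direct targets, concordance, cross-species overlap

A *direct target* (`define_direct_targets()`) is a gene bound in
ChIP-seq and differentially expressed (p < 0.05, any direction) upon
activating the factor with its cytokine (TNFα for NFκB, IFNγ for
STAT1, IL-6 for STAT3 in the motivating experiments).
`exclusive_targets()` removes genes shared between factors so each
activity score tracks one factor; which sets are exclusivity-filtered
is an argument, defaulting to all supplied sets.

`concordance_test()` asks whether cytokine-induced targets are also
induced during aging: among targets with positive log2 fold-change, it
counts positive age slopes and tests against a direction-symmetric
binomial null (success probability 0.5, one-sided upper tail).  The
null probability is not stated in the motivating analysis; 0.5 is the
only natural direction-symmetric choice and reproduces the published
worked example (35 of 40 induced targets concordant: 87.5%, printed as
88%, exact tail 6.9e-7 < 1e-5).  A zero age slope counts as
non-concordant — a measure-zero event in continuous data that still
needs a deterministic rule.  `profile_correlation()` is the Pearson
correlation of induction fold-changes with age slopes, p from the
t-transform on n − 2 df.

`cross_species_overlap()` restricts to one-to-one orthologs analyzed
in both species, correlates human age slopes with the other species'
old-versus-young fold-changes, and tests the overlap of significance
calls by hypergeometric upper tail, with fold relative to the
independence expectation *within the ortholog universe*.  The
background for the published 6.7-fold human–rat enrichment is not
printed; the universe is therefore an explicit argument, and the
function flags the degenerate case where one margin is the whole
universe (as happens when the universe itself is an age-related gene
list).

## TF activity and macrophage covariation

`zscore_genes()` standardizes each gene across samples using the
sample (n − 1) standard deviation; `activity_scores()` averages member
z-scores per sample; `age_adjust()` removes the age trend by OLS
residuals, which are exactly uncorrelated with age.
`marker_abundance_score()` applies the same composition to
monocyte/macrophage transcripts (CD163, CD14, TYROBP by default;
any marker set can be supplied).  `covariation()` computes pairwise
Pearson correlations of the age-adjusted profiles and clusters with
distance 1 − r and average linkage.  The clustering linkage is not
specified in the motivating analysis; average linkage is the common
default of the heat-map tools of that era and is configurable.  Using
1 − r (not 1 − |r|) keeps anti-correlated profiles apart.  Profiles
are sorted lexicographically by label before clustering so the leaf
order is invariant to input order.

The published activity–macrophage correlations (r = 0.66–0.81) are
real-data results; the synthetic substitute plants a latent
"inflammatory infiltration" factor with loading λ into m genes per
module and verifies that the mean module-score correlation recovers
the analytic expectation λ²/(λ² + (1 − λ²)/m) within Monte-Carlo
error.

## Candidate-gene genetics

`bonferroni_threshold()` computes α/(n_snps · n_phenotypes); for 217
SNPs × 2 phenotypes at α = 0.05 that is 0.05/434 = 1.152e-4, rendered
"1.1e-04" by mantissa truncation (the convention used when such
cut-offs are printed).  `select_lead_snps()` takes the per-gene minimum
p for a phenotype, ties to the lexicographically smallest SNP id.

`estimate_allelic_or()` reconstructs an allelic odds ratio from the
summary statistics alone — association p, case/control sizes, pooled
minor-allele frequency — by chi-square matching: it finds the 2×2
allele-count table whose Pearson chi-square (1 df, no continuity
correction) reproduces the p-value while holding the pooled
minor-allele frequency fixed.  The case and control frequencies are
displaced in opposite directions weighted by the other group's allele
share, which preserves the pooled frequency identically; the
displacement is found by root bisection to a statistic residual below
1e-10.  "Distribution of minor allele carriers" is ambiguous between
allele counts and carrier counts; the default is allelic (as the
published odds ratios are labelled), and a carrier mode
(Hardy–Weinberg carrier frequency 1 − (1 − maf)², totals n instead of
2n) is provided.  For very strong associations the linear-scale
p-value underflows double precision near 1e-308; the function
therefore also accepts −log10 p, the standard GWAS summary-statistic
convention, and the generator emits both.

`annotate_linked_snps()` reports every SNP in strong LD with a lead
(R² strictly greater than 0.8) together with the functional annotation
intervals (TF peaks, DNase, H3K4me1, H3K27ac, …) containing its
position, point-in-interval on half-open intervals.  LD is consumed
from a table, never computed from genotypes.

# The synthetic-data generator

Every generator is deterministic given its seed; a single global seed
fans out to per-generator substreams keyed by stable labels, so adding
a generator never shifts the streams of the others.  Each generator
returns its ground truth alongside the data; pipeline code never reads
the truth — only tests and the recovery analyses do.

* `simulate_genome()` packs genes into 8 kb slots (the 7 kb promoter
  window plus a 1 kb pad), with the TSS offset inside its slot by
  strand so that windows never overlap even across strands — naive
  uniform placement with 8 kb spacing does not guarantee that, since a
  minus-strand window reaches 5 kb downstream.  Density above one gene
  per 8 kb is rejected.
* `simulate_chipseq()` emulates the compendium's two binding regimes:
  promoter-proximal peaks whose summits fall in a uniformly chosen
  gene's window — with a planted regulator choosing age genes with
  probability proportional to its enrichment factor ρ — and HOT
  regions, 600 bp intervals parked in slot pads, into which each
  experiment deterministically places `round(hot_fraction × peaks)`
  peaks round-robin, so every factor hits every HOT region whenever
  that count reaches the region count.  HOT summits cluster within
  ±40 bp of the region centre so co-bound peaks mutually overlap and
  carry full complexity.  Peak lengths are ≥ 20 bp and −log10
  significances ≥ 5, matching the inclusion filters.
* `simulate_expression()` mirrors the study shape — 73 samples aged
  27–92 by default — with GFR declining linearly in age
  (130 − 0.9/yr, residual SD 12, a realistic adult trajectory) plus
  noise.  Age-related genes split into directly age-driven
  (β_age ~ N(0, 0.01)/yr on log2 expression) and GFR-mediated
  (expression follows GFR, so the marginal age slope attenuates once
  GFR is a covariate).  The default GFR-mediated fraction is 0.5,
  chosen from the reported prevalence of renal-function-informative
  genes: mediated genes attenuate with probability ~1 and direct ones
  ~0.5 by chance, putting the expected attenuation fraction near
  three quarters.  The observed fraction on generated data also
  depends on the effect-to-noise ratio, since attenuation of a weak
  mediated gene is diluted by estimation noise.
* `simulate_cytokine_response()` induces each target with probability
  `p_induced`; an induced target's age slope is positive with
  probability c (the tunable concordance) and its magnitude scales
  with the induction strength — without that coupling the
  fold-change/age-slope correlation would have zero expectation
  regardless of c, contradicting what direction-concordant real data
  show.
* `simulate_assoc()` builds, per SNP, the *exact* expected-count 2×2
  allele table with the requested pooled MAF and odds ratio and emits
  its chi-square p (and −log10 p), so odds-ratio reconstruction can be
  verified as an exact round trip rather than a statistical one.

What the generator does not emulate: read-level ChIP-seq signal and
peak calling; array normalization (inputs are assumed normalized, as
the real pipeline assumed after rank-invariant normalization);
probe-level structure unless supplied; genotype-level LD (LD enters as
a table); confounders such as batch, sex or medication.  Passing tests
on synthetic data therefore demonstrate the correctness and
calibration of the statistical machinery under the stated model, not
robustness to everything real microarrays and cohorts contain.

# Numerical choices

* All interval logic is 0-based half-open; summit fallback for
  narrowPeak offset −1 is the floored midpoint.
* Significance retention uses the −log10 scale: kept iff
  −log10(sig) ≥ −log10(threshold), making the boundary exact.
* The shared-design OLS refuses (near-)collinear designs at condition
  number 1e12, reporting it; constant genes get slope 0, p 1.
* Chi-square tests never use continuity correction, matching the
  test-selection rule's expected-count guard.
* Odds-ratio bisection brackets the frequency displacement inside the
  open unit interval, tolerance 1e-10 on the statistic, ≤ 200
  iterations after an initial root find; a p-value unattainable within
  the frequency bounds errors rather than saturating.
* p-values are clamped into (0, 1] at the smallest representable
  double where underflow is possible; the genetics stage carries
  −log10 p alongside for exactness.

# Problem sizes

The shipped tests and the acceptance script run the simulation-based
checks at sizes chosen to make their statistical tolerances meaningful
while keeping a full run in tens of seconds: 100 screen-recovery
seeds at a 10,000-gene universe; 2,000 null experiments for chi-square
calibration; exhaustive Fisher-vs-hypergeometric enumeration over all
tables with universes up to 60 plus thousands of random larger tables;
500 concordance-calibration seeds; 300-gene × 73-sample regression
recovery; 200 latent-factor seeds; a 36-cell odds-ratio grid.  The
`analysis/` workflow uses a 400-gene genome, 30 ChIP-seq experiments
over 15 factors and 220 SNPs — the full study-scale shape (161
factors, 961 experiments) is a parameter change, not a code change.

# Known limitations

* The screen treats experiments as exchangeable under Bonferroni;
  correlated experiments (same factor, related cell lines) make the
  correction conservative.
* OLS age models assume homoscedastic Gaussian noise per gene; no
  empirical-Bayes moderation is applied, by design.
* The odds-ratio reconstruction presumes the published association p
  came from an (approximately) allelic chi-square; logistic-regression
  p-values with covariates will reconstruct slightly different tables.
* The concordance binomial treats targets as independent; co-regulated
  targets share noise, making small p-values optimistic.
* Hierarchical-clustering leaf order is only defined up to the stated
  tie-breaks; different linkage choices reorder leaves without
  changing the correlation matrix.
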