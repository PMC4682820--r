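## Direct-target definition from ChIP-seq binding plus cytokine-response
## differential expression, direction-concordance and profile-correlation
## statistics against the aging kidney, and the cross-species overlap
## analysis.

#' Define the direct targets of a transcription factor
#'
#' A gene is a direct target iff it is bound by the TF in ChIP-seq (after
#' promoter-window assignment) and is differentially expressed
#' (p < \code{p_max}, any direction) upon activating that TF with its
#' cytokine.
#'
#' @param chip_targets character vector of bound gene ids.
#' @param de DE table for the cytokine stimulation (must cover the bound
#'   genes that were DE-tested).
#' @param p_max DE significance cut-off; default 0.05.
#' @param tf TF label.
#' @param induced_only keep only induced (log2fc > 0) targets?
#' @return a \code{direct_target_set}: list with tf, genes, source,
#'   exclusive flag.  An empty intersection is valid and warned about.
#' @export
define_direct_targets <- function(chip_targets, de, p_max = 0.05,
                                  tf = NA_character_, induced_only = FALSE) {
  stopifnot(p_max > 0, p_max <= 1)
  sub <- de[de$gene_id %in% chip_targets & de$p < p_max, , drop = FALSE]
  if (induced_only) sub <- sub[sub$log2fc > 0, , drop = FALSE]
  genes <- unique(sub$gene_id)
  if (!length(genes)) {
    warning(sprintf("no direct targets for %s at p < %g", tf, p_max),
            call. = FALSE)
  }
  structure(list(tf = tf, genes = genes,
                 source = list(de_perturbation = unique(de$perturbation)),
                 exclusive = FALSE),
            class = "direct_target_set")
}

#' Restrict direct-target sets to TF-exclusive genes
#'
#' For each set flagged for exclusivity, removes genes present in any
#' other TF's direct-target set, so downstream activity scores measure
#' one factor rather than shared inflammatory targets.  The resulting
#' flagged sets are pairwise disjoint.
#'
#' @param sets named list of \code{direct_target_set} objects (>= 2).
#' @param exclusive_tfs names of sets to filter; by default all of them.
#' @return the list with filtered sets marked \code{exclusive = TRUE}.
#' @export
exclusive_targets <- function(sets, exclusive_tfs = names(sets)) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  out <- sets
  for (nm in names(sets)) {
    if (!nm %in% exclusive_tfs) next
    others <- unique(unlist(lapply(sets[setdiff(names(sets), nm)],
                                   `[[`, "genes")))
    out[[nm]]$genes <- setdiff(sets[[nm]]$genes, others)
    out[[nm]]$exclusive <- TRUE
  }
  out
}

#' Direction concordance between cytokine induction and kidney aging
#'
#' Among the targets induced by the cytokine (log2fc > 0), counts those
#' whose age slope is also positive and tests the count against the
#' direction-symmetric null (binomial, success probability 0.5,
#' one-sided upper tail).  A zero age slope counts as non-concordant.
#'
#' @param de DE table restricted to the TF's direct targets.
#' @param age_slopes named numeric vector of per-gene age slopes (from
#'   \code{\link{fit_age_model}}); every target must have a slope.
#' @param induced_only restrict the denominator to induced targets
#'   (default TRUE; FALSE scores sign agreement of all targets).
#' @return list: n_induced, n_concordant, concordance_pct, p_binomial.
#' @export
concordance_test <- function(de, age_slopes, induced_only = TRUE) {
  missing <- setdiff(de$gene_id, names(age_slopes))
  if (length(missing)) {
    stop_msg("no age slope for target(s): %s",
             paste(utils::head(missing, 5), collapse = ", "))
  }
  slopes <- age_slopes[de$gene_id]
  if (induced_only) {
    sel <- de$log2fc > 0
    concordant <- slopes[sel] > 0
  } else {
    sel <- rep(TRUE, nrow(de))
    concordant <- sign(slopes) == sign(de$log2fc) & slopes != 0
  }
  n <- sum(sel)
  if (n == 0) stop_msg("no induced targets: concordance undefined")
  k <- sum(concordant)
  p <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(n_induced = n, n_concordant = k,
       concordance_pct = 100 * k / n,
       p_binomial = min(max(p, .Machine$double.xmin), 1))
}

#' Binomial concordance from printed counts
#'
#' The same one-sided binomial direction test as
#' \code{\link{concordance_test}}, taken directly from counts.
#'
#' @param n_concordant,n_total counts, n_concordant <= n_total.
#' @return list: n_induced, n_concordant, concordance_pct, p_binomial.
#' @export
concordance_from_counts <- function(n_concordant, n_total) {
  stopifnot(n_total >= 1, n_concordant >= 0, n_concordant <= n_total)
  p <- pbinom(n_concordant - 1, n_total, 0.5, lower.tail = FALSE)
  list(n_induced = n_total, n_concordant = n_concordant,
       concordance_pct = 100 * n_concordant / n_total,
       p_binomial = p)
}

#' Pearson correlation of cytokine response with the aging profile
#'
#' Correlates the per-target log2 fold-changes upon stimulation with the
#' per-target age slopes; p from the t transform
#' t = r sqrt((n-2)/(1-r^2)) on n - 2 df, two-sided.
#'
#' @param de_log2fc,age_slopes numeric vectors over the same targets
#'   (n >= 3, both non-constant).
#' @return list: r, p, n.
#' @export
profile_correlation <- function(de_log2fc, age_slopes) {
  stopifnot(length(de_log2fc) == length(age_slopes))
  n <- length(de_log2fc)
  if (n < 3) stop_msg("need >= 3 targets")
  if (sd(de_log2fc) == 0 || sd(age_slopes) == 0) {
    stop_msg("constant vector: correlation undefined")
  }
  r <- cor(de_log2fc, age_slopes)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' Cross-species overlap of age-related expression changes
#'
#' Restricts to one-to-one orthologs analyzed in both species, correlates
#' the human age slopes with the other species' old-vs-young log2
#' fold-changes, and tests the overlap of significance calls: fold
#' enrichment is observed shared-significant genes over the expectation
#' under independence given both margins within the ortholog universe,
#' with a hypergeometric upper-tail p.
#'
#' @param human_age_genes human gene ids analyzed (the ortholog universe
#'   on the human side).
#' @param human_slopes named numeric vector of human age slopes.
#' @param ortholog_map data frame with columns \code{human}, \code{other};
#'   must be one-to-one on the analyzed genes.
#' @param other_species_de DE table for the other species (old vs young),
#'   gene ids on the other species' side.
#' @param other_sig_p significance cut-off for the other species.
#' @param human_sig_genes human genes called significantly age-related;
#'   defaults to all of \code{human_age_genes} (the usual degenerate case
#'   when the universe itself is an age-related list).
#' @return list: r, p_r, n_universe, n_sig_human, n_sig_other,
#'   n_shared_sig, expected, fold, p_hyper, degenerate_margin.
#' @export
cross_species_overlap <- function(human_age_genes, human_slopes,
                                  ortholog_map, other_species_de,
                                  other_sig_p = 0.05,
                                  human_sig_genes = human_age_genes) {
  if (anyDuplicated(ortholog_map$human) || anyDuplicated(ortholog_map$other)) {
    stop_msg("ortholog map must be one-to-one; resolve many-to-many pairs first")
  }
  map <- ortholog_map[ortholog_map$human %in% human_age_genes &
                        ortholog_map$other %in% other_species_de$gene_id, ,
                      drop = FALSE]
  if (nrow(map) < 3) stop_msg("fewer than 3 shared orthologs")
  de <- other_species_de[match(map$other, other_species_de$gene_id), ]
  hs <- human_slopes[map$human]
  corr <- profile_correlation(de$log2fc, hs)

  N <- nrow(map)
  sig_h <- map$human %in% human_sig_genes
  sig_o <- de$p < other_sig_p
  k <- sum(sig_h & sig_o)
  expected <- sum(sig_h) * sum(sig_o) / N
  fold <- if (expected > 0) k / expected else NA_real_
  p_hyper <- phyper(k - 1, sum(sig_o), N - sum(sig_o), sum(sig_h),
                    lower.tail = FALSE)
  list(r = corr$r, p_r = corr$p, n_universe = N,
       n_sig_human = sum(sig_h), n_sig_other = sum(sig_o),
       n_shared_sig = k, expected = expected, fold = fold,
       p_hyper = p_hyper,
       degenerate_margin = sum(sig_h) == N || sum(sig_o) == N)
}
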