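## Per-sample transcription-factor activity inference: target-gene
## z-scores, averaged activity scores, age adjustment by OLS residuals,
## and covariation of activity profiles with leukocyte marker scores
## (Pearson correlation + average-linkage clustering).

#' Convert expression values to per-gene z-scores
#'
#' Each gene's values are centered and scaled across samples using the
#' sample standard deviation (n - 1 denominator), so every row has mean 0
#' and sd 1.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param gene_subset genes to transform (default: all).
#' @return numeric matrix of z-scores, genes x samples.
#' @export
zscore_genes <- function(expr, gene_subset = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  genes <- if (is.null(gene_subset)) expr$genes else gene_subset
  missing <- setdiff(genes, expr$genes)
  if (length(missing)) {
    stop_msg("gene(s) absent from matrix: %s", paste(missing, collapse = ", "))
  }
  m <- expr$values[genes, , drop = FALSE]
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  if (any(s == 0)) {
    stop_msg("zero-variance gene(s): %s",
             paste(genes[s == 0], collapse = ", "))
  }
  (m - mu) / s
}

#' Average z-score activity of a gene set per sample
#'
#' @param z z-score matrix from \code{\link{zscore_genes}}.
#' @param member_genes nonempty subset of the matrix rows.
#' @return named numeric vector, one score per sample.
#' @export
activity_scores <- function(z, member_genes = rownames(z)) {
  if (!length(member_genes)) stop_msg("empty member gene set")
  missing <- setdiff(member_genes, rownames(z))
  if (length(missing)) {
    stop_msg("member gene(s) absent from z-matrix: %s",
             paste(missing, collapse = ", "))
  }
  colMeans(z[member_genes, , drop = FALSE])
}

#' Age-adjust per-sample scores by OLS residuals
#'
#' Regresses the scores on an intercept plus age and returns the
#' residuals, which are exactly uncorrelated with age.
#'
#' @param scores per-sample numeric vector.
#' @param ages per-sample ages; must vary; >= 3 samples.
#' @return numeric vector of residuals (same names as scores).
#' @export
age_adjust <- function(scores, ages) {
  stopifnot(length(scores) == length(ages))
  if (length(scores) < 3) stop_msg("need >= 3 samples")
  if (sd(ages) == 0) stop_msg("age does not vary")
  fit <- stats::lm.fit(cbind(1, ages), scores)
  res <- fit$residuals
  names(res) <- names(scores)
  res
}

#' Build an activity profile for a labelled gene set
#'
#' Composes z-scoring, score averaging and age adjustment for one TF
#' target set or marker set.
#'
#' @param expr an \code{ExpressionMatrix}.
#' @param member_genes gene ids of the set.
#' @param label profile name.
#' @return object of class \code{activity_profile}: list(label, samples,
#'   raw, adjusted).
#' @export
activity_profile <- function(expr, member_genes, label) {
  z <- zscore_genes(expr, member_genes)
  raw <- activity_scores(z, member_genes)
  adjusted <- age_adjust(raw, expr$age)
  structure(list(label = label, samples = expr$samples,
                 raw = raw, adjusted = adjusted),
            class = "activity_profile")
}

#' Macrophage/monocyte marker-abundance profile
#'
#' The marker-set analogue of a TF activity profile, defaulting to
#' transcripts specific to or strongly enriched in monocytes/macrophages
#' (CD163, CD14, TYROBP).  Tracks interstitial macrophage abundance per
#' sample after removing the age trend.
#'
#' @param expr an \code{ExpressionMatrix}.
#' @param marker_genes marker transcripts; all must be present.
#' @param label profile name.
#' @return an \code{activity_profile}.
#' @export
marker_abundance_score <- function(expr,
                                   marker_genes = c("CD163", "CD14", "TYROBP"),
                                   label = "macrophage_markers") {
  missing <- setdiff(marker_genes, expr$genes)
  if (length(missing)) {
    stop_msg("marker gene(s) absent from matrix: %s",
             paste(missing, collapse = ", "))
  }
  activity_profile(expr, marker_genes, label)
}

#' Covariation of activity profiles
#'
#' Pairwise Pearson correlation of age-adjusted scores across profiles,
#' followed by agglomerative clustering with distance 1 - r and average
#' linkage.  Profiles are ordered lexicographically by label before
#' clustering so the leaf order is stable under input permutation.
#'
#' @param profiles list of \code{activity_profile} objects over identical
#'   samples (>= 2).
#' @param use \code{"adjusted"} (default) or \code{"raw"} scores.
#' @return list: r (correlation matrix), dist (1 - r), hclust, leaf_order
#'   (labels), merge_heights.
#' @export
covariation <- function(profiles, use = c("adjusted", "raw")) {
  use <- match.arg(use)
  stopifnot(length(profiles) >= 2)
  labels <- vapply(profiles, `[[`, "", "label")
  if (anyDuplicated(labels)) stop_msg("duplicate profile labels")
  samp <- profiles[[1]]$samples
  for (p in profiles) {
    if (!identical(p$samples, samp)) {
      stop_msg("profiles span different samples")
    }
  }
  ord <- order(labels)
  profiles <- profiles[ord]
  labels <- labels[ord]
  m <- vapply(profiles, `[[`, numeric(length(samp)), use)
  colnames(m) <- labels
  r <- cor(m)
  d <- as.dist(1 - r)
  hc <- hclust(d, method = "average")
  list(r = r, dist = d, hclust = hc,
       leaf_order = labels[hc$order],
       merge_heights = hc$height)
}
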