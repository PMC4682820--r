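## Expression-side statistics: detection filtering, two-group differential
## expression, probe-to-gene collapsing, per-gene age(/GFR) regression and
## the GFR coefficient-attenuation analysis.

## Vectorized OLS of every gene (row of Y) on a shared design matrix X.
## Returns per-gene coefficients, standard errors and two-sided p-values.
ols_rows <- function(Y, X) {
  n <- ncol(Y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, n > p)
  XtX <- crossprod(X)
  cond <- kappa(XtX, exact = TRUE)
  if (!is.finite(cond) || cond > 1e12) {
    stop_msg("design matrix is (near-)collinear: condition number %.3g", cond)
  }
  XtX_inv <- solve(XtX)
  B <- Y %*% X %*% XtX_inv               # genes x p coefficients
  fitted <- B %*% t(X)
  rss <- rowSums((Y - fitted)^2)
  df <- n - p
  sigma2 <- rss / df
  se <- sqrt(outer(sigma2, diag(XtX_inv)))
  tstat <- B / se
  pval <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  ## a flat gene has se 0 on every coefficient: define beta 0, p 1
  flat <- rss < .Machine$double.eps * n &
    abs(B[, -1, drop = FALSE]) < sqrt(.Machine$double.eps)
  for (j in seq_len(p - 1)) {
    idx <- which(flat[, j])
    pval[idx, j + 1] <- 1
    B[idx, j + 1] <- 0
  }
  list(coef = B, se = se, p = pval, df = df)
}

#' Filter genes by detection p-value
#'
#' Keeps genes detectably expressed (detection p < \code{alpha}) in at
#' least one sample; the standard pre-filter before differential
#' expression on bead-array data.
#'
#' @param expr an \code{\link{expression_matrix}} with detection p-values.
#' @param alpha detection threshold; default 0.01.
#' @return the filtered \code{ExpressionMatrix}.
#' @export
detection_filter <- function(expr, alpha = 0.01) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (is.null(expr$detection_p)) {
    stop_msg(paste("no detection p-values present; omit detection_filter()",
                   "explicitly if the platform provides none"))
  }
  keep <- rowSums(expr$detection_p < alpha) >= 1
  expression_matrix(expr$values[keep, , drop = FALSE], expr$age,
                    gfr = expr$gfr,
                    detection_p = expr$detection_p[keep, , drop = FALSE])
}

#' Two-group differential expression by unpaired Student's t-test
#'
#' Classical pooled-variance (not Welch) two-sided t-test per gene;
#' log2 fold-change is mean(treated) - mean(control), the inputs being on
#' log2 scale already.  Genes with zero variance in both groups get p = 1
#' and log2fc = 0 when the means agree; when they differ the p-value is
#' set to the smallest representable double and the gene is flagged in the
#' \code{degenerate} column.
#'
#' @param expr_treated,expr_control numeric matrices (genes x samples) on
#'   log2 scale with matching row names, or \code{ExpressionMatrix}
#'   objects; >= 2 samples per group.
#' @param perturbation label stored with the result.
#' @return a DE table: tibble with gene_id, log2fc, p, perturbation,
#'   degenerate.
#' @export
differential_expression <- function(expr_treated, expr_control,
                                    perturbation = "treatment") {
  tr <- if (inherits(expr_treated, "ExpressionMatrix")) expr_treated$values
        else as.matrix(expr_treated)
  ct <- if (inherits(expr_control, "ExpressionMatrix")) expr_control$values
        else as.matrix(expr_control)
  stopifnot(ncol(tr) >= 2, ncol(ct) >= 2)
  if (!identical(rownames(tr), rownames(ct))) {
    common <- intersect(rownames(tr), rownames(ct))
    if (!length(common)) stop_msg("no shared genes between groups")
    tr <- tr[common, , drop = FALSE]
    ct <- ct[common, , drop = FALSE]
  }
  n1 <- ncol(tr); n2 <- ncol(ct)
  m1 <- rowMeans(tr); m2 <- rowMeans(ct)
  ss1 <- rowSums((tr - m1)^2); ss2 <- rowSums((ct - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  log2fc <- m1 - m2
  tstat <- log2fc / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  zero_var <- sp2 < .Machine$double.eps
  degenerate <- zero_var & abs(log2fc) > 0
  p[zero_var & !degenerate] <- 1
  log2fc[zero_var & !degenerate] <- 0
  p[degenerate] <- .Machine$double.xmin
  tibble::tibble(gene_id = rownames(tr), log2fc = unname(log2fc),
                 p = unname(p), perturbation = perturbation,
                 degenerate = unname(degenerate))
}

#' Collapse probe-level DE results to gene level
#'
#' For genes represented by multiple probes, keeps the most differentially
#' expressed probe: smallest p, ties broken by larger |log2fc|, remaining
#' ties by lexicographically smallest probe id.  Unmapped probes are
#' dropped with a message stating the count.
#'
#' @param de probe-level DE table (gene_id column holds probe ids).
#' @param probe_to_gene named character vector (names = probe ids, values
#'   = gene ids) or a two-column data frame (probe_id, gene_id); each
#'   probe maps to at most one gene.
#' @return gene-level DE table with one row per mapped gene and a
#'   \code{probe_id} column recording the winner.
#' @export
collapse_probes <- function(de, probe_to_gene) {
  if (is.data.frame(probe_to_gene)) {
    map <- setNames(as.character(probe_to_gene[[2]]),
                    as.character(probe_to_gene[[1]]))
  } else {
    map <- probe_to_gene
  }
  if (anyDuplicated(names(map))) stop_msg("a probe maps to more than one gene")
  gene <- unname(map[de$gene_id])
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    message(sprintf("collapse_probes: dropping %d unmapped probe(s)",
                    sum(unmapped)))
  }
  de <- de[!unmapped, , drop = FALSE]
  gene <- gene[!unmapped]
  probe <- de$gene_id
  ord <- order(gene, de$p, -abs(de$log2fc), probe)
  de <- de[ord, , drop = FALSE]
  probe <- probe[ord]; gene <- gene[ord]
  keep <- !duplicated(gene)
  out <- de[keep, , drop = FALSE]
  out$probe_id <- probe[keep]
  out$gene_id <- gene[keep]
  out
}

#' Per-gene linear regression of expression on age (and optionally GFR)
#'
#' Ordinary least squares of each gene's log-scale expression on an
#' intercept plus chronological age, with glomerular filtration rate as a
#' second covariate when \code{include_gfr} is set.  The age coefficient
#' (the "age slope", expression units per year) and its standard error and
#' two-sided p-value are returned per gene; constant genes get beta 0,
#' p 1.
#'
#' @param expr an \code{\link{expression_matrix}}; >= 3 samples, age must
#'   vary, and GFR must be present and not collinear with age when
#'   requested.
#' @param include_gfr add GFR as a covariate?
#' @return tibble: gene_id, beta_age, se_age, p_age, beta_gfr, se_gfr,
#'   p_gfr (NA without GFR), model.
#' @export
fit_age_model <- function(expr, include_gfr = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  n <- length(expr$samples)
  if (n < 3) stop_msg("need >= 3 samples")
  if (sd(expr$age) == 0) stop_msg("age does not vary")
  if (include_gfr) {
    if (is.null(expr$gfr)) stop_msg("GFR requested but absent from metadata")
    X <- cbind(1, expr$age, expr$gfr)
  } else {
    X <- cbind(1, expr$age)
  }
  fit <- ols_rows(expr$values, X)
  tibble::tibble(
    gene_id = expr$genes,
    beta_age = unname(fit$coef[, 2]),
    se_age = unname(fit$se[, 2]),
    p_age = unname(fit$p[, 2]),
    beta_gfr = if (include_gfr) unname(fit$coef[, 3]) else NA_real_,
    se_gfr = if (include_gfr) unname(fit$se[, 3]) else NA_real_,
    p_gfr = if (include_gfr) unname(fit$p[, 3]) else NA_real_,
    model = if (include_gfr) "age_plus_gfr" else "age_only")
}

#' Age-coefficient attenuation when GFR enters the model
#'
#' For genes informative of renal function the magnitude of the age
#' coefficient shrinks once GFR is added as a covariate.  Reports the
#' fraction of genes whose |beta_age| is strictly smaller in the
#' age-plus-GFR model (equal magnitudes count as not reduced) and the
#' per-gene comparison table.
#'
#' @param results_with age-model results fitted with GFR.
#' @param results_without age-model results fitted without GFR.
#' @return list with \code{fraction_reduced} and \code{table} (gene_id,
#'   beta_with, beta_without, reduced).
#' @export
gfr_attenuation <- function(results_with, results_without) {
  if (!setequal(results_with$gene_id, results_without$gene_id)) {
    stop_msg("gene sets differ between the two model fits")
  }
  results_without <- results_without[
    match(results_with$gene_id, results_without$gene_id), ]
  reduced <- abs(results_with$beta_age) < abs(results_without$beta_age)
  list(fraction_reduced = mean(reduced),
       table = tibble::tibble(gene_id = results_with$gene_id,
                              beta_with = results_with$beta_age,
                              beta_without = results_without$beta_age,
                              reduced = reduced))
}

#' Split samples into young and old groups by age cut-offs
#'
#' Convenience for two-group comparisons of an aging cohort (young < 45,
#' old > 65 by default); the groups feed
#' \code{\link{differential_expression}} with old as "treated".
#'
#' @param expr an \code{ExpressionMatrix}.
#' @param young_max,old_min age cut-offs in years.
#' @return list of two matrices, \code{old} and \code{young}.
#' @export
age_groups <- function(expr, young_max = 45, old_min = 65) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  list(old = expr$values[, expr$age > old_min, drop = FALSE],
       young = expr$values[, expr$age < young_max, drop = FALSE])
}
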