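## Gene-set overlap enrichment screen over the ChIP-seq experiment
## compendium: per-experiment 2x2 tests with the chi-square/Fisher
## switch, Bonferroni-corrected candidate calling with exclusion and
## expression allow-lists, and the specificity control over unrelated
## query gene sets.

#' Screen configuration
#'
#' @param fold_min minimum fold enrichment for a candidate call; default 1.5.
#' @param alpha family-wise error rate before Bonferroni division; 0.05.
#' @param bonferroni_n number of experiments tested (the Bonferroni
#'   denominator); defaults to the number of experiments screened.
#' @param excluded_tfs TFs never called as candidates (non-specific
#'   DNA-binding machinery such as POL2-associated factors, CTCF, RAD21,
#'   TAF1, p300).
#' @param epithelial_expressed_tfs optional allow-list: when supplied,
#'   only TFs with detectable renal epithelial expression can be called.
#' @param p_threshold_override optional literal per-test p threshold that
#'   replaces alpha/bonferroni_n (e.g. 5e-5 for a compendium of 961
#'   experiments at alpha 0.05, as conventionally printed).
#' @return a list of class \code{screen_config}.
#' @export
screen_config <- function(fold_min = 1.5, alpha = 0.05, bonferroni_n = NULL,
                          excluded_tfs = character(),
                          epithelial_expressed_tfs = NULL,
                          p_threshold_override = NULL) {
  stopifnot(fold_min > 0, alpha > 0, alpha < 1)
  if (!is.null(bonferroni_n)) stopifnot(bonferroni_n >= 1)
  structure(list(fold_min = fold_min, alpha = alpha,
                 bonferroni_n = bonferroni_n,
                 excluded_tfs = excluded_tfs,
                 epithelial_expressed_tfs = epithelial_expressed_tfs,
                 p_threshold_override = p_threshold_override),
            class = "screen_config")
}

#' Overlap enrichment of a target set with a query set
#'
#' Builds the 2x2 membership table of \code{targets} x \code{query} over
#' \code{universe} and tests for enrichment.  When all four expected cell
#' counts exceed 5 the Pearson chi-square test (1 df, no continuity
#' correction) is used; otherwise the one-sided Fisher exact test
#' (hypergeometric upper tail, enrichment direction).  Fold enrichment is
#' observed/expected overlap with expected = |targets|*|query|/|universe|.
#'
#' @param targets,query,universe character vectors of gene ids; targets
#'   and query must be subsets of universe.
#' @param experiment_id,tf,cell_line optional labels carried into the
#'   result row.
#' @return one-row tibble: experiment_id, tf, cell_line,
#'   n_targets_in_universe, n_query_in_universe, n_overlap, n_universe,
#'   expected, fold, p, test_used.
#' @export
overlap_enrichment <- function(targets, query, universe,
                               experiment_id = NA_character_,
                               tf = NA_character_,
                               cell_line = NA_character_) {
  universe <- unique(universe)
  if (!length(universe)) stop_msg("empty universe")
  targets <- unique(targets)
  query <- unique(query)
  if (length(setdiff(query, universe))) {
    stop_msg("query contains genes outside the universe")
  }
  if (length(setdiff(targets, universe))) {
    stop_msg("target set contains genes outside the universe")
  }
  N <- length(universe)
  t_n <- length(targets)
  q_n <- length(query)
  k <- length(intersect(targets, query))
  expected <- t_n * q_n / N
  fold <- if (expected > 0) k / expected else 0

  tab <- matrix(c(k, t_n - k, q_n - k, N - t_n - q_n + k), nrow = 2)
  e <- outer(rowSums(tab), colSums(tab)) / N
  if (all(e > 5)) {
    test_used <- "chisq"
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
  } else {
    test_used <- "fisher"
    ## one-sided enrichment tail: P(X >= k), X ~ Hypergeom(N, q_n, t_n)
    p <- stats::phyper(k - 1, q_n, N - q_n, t_n, lower.tail = FALSE)
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  tibble::tibble(experiment_id = experiment_id, tf = tf,
                 cell_line = cell_line,
                 n_targets_in_universe = t_n, n_query_in_universe = q_n,
                 n_overlap = k, n_universe = N,
                 expected = expected, fold = fold, p = p,
                 test_used = test_used)
}

#' Screen every ChIP-seq experiment for enrichment of a query gene set
#'
#' Runs \code{\link{overlap_enrichment}} per experiment, ranks by p-value
#' and calls candidate transcription factors: a TF is a candidate iff it
#' is not on the exclusion list, it is on the epithelial-expression
#' allow-list when one is supplied, and its best experiment exceeds the
#' fold threshold at Bonferroni-corrected significance
#' (p < alpha / bonferroni_n, or the literal override).
#'
#' @param target_maps tibble from \code{\link{assign_peaks_to_genes}}
#'   (columns experiment_id, tf, cell_line, gene_id), possibly spanning
#'   many experiments.
#' @param query,universe gene-id vectors.
#' @param config a \code{\link{screen_config}}.
#' @return list with \code{results} (per-experiment tibble sorted by p),
#'   \code{tf_summary} (per TF: best experiment, best p/fold, number of
#'   passing experiments, candidate flag) and \code{candidates}
#'   (character vector of candidate TFs, best-p order).
#' @export
screen_experiments <- function(target_maps, query, universe,
                               config = screen_config()) {
  stopifnot(nrow(target_maps) >= 1)
  target_maps <- target_maps[target_maps$gene_id %in% universe, , drop = FALSE]
  exps <- unique(target_maps[c("experiment_id", "tf", "cell_line")])
  by_exp <- split(target_maps$gene_id, target_maps$experiment_id)
  rows <- lapply(seq_len(nrow(exps)), function(i) {
    overlap_enrichment(by_exp[[exps$experiment_id[i]]], query, universe,
                       experiment_id = exps$experiment_id[i],
                       tf = exps$tf[i], cell_line = exps$cell_line[i])
  })
  results <- do.call(rbind, rows)
  results <- results[order(results$p, -results$fold, results$experiment_id), ]

  n_exp <- nrow(results)
  p_thresh <- if (!is.null(config$p_threshold_override)) {
    config$p_threshold_override
  } else {
    config$alpha / (if (is.null(config$bonferroni_n)) n_exp
                    else config$bonferroni_n)
  }
  passes <- results$fold > config$fold_min & results$p < p_thresh

  tf_rows <- lapply(split(seq_len(n_exp), results$tf), function(idx) {
    best <- idx[1L]                     # results already ranked
    tibble::tibble(tf = results$tf[best],
                   best_experiment = results$experiment_id[best],
                   best_cell_line = results$cell_line[best],
                   best_fold = results$fold[best], best_p = results$p[best],
                   n_experiments = length(idx),
                   n_passing = sum(passes[idx]))
  })
  tf_summary <- do.call(rbind, tf_rows)
  tf_summary <- tf_summary[order(tf_summary$best_p, -tf_summary$best_fold,
                                 tf_summary$tf), ]
  eligible <- !(tf_summary$tf %in% config$excluded_tfs)
  if (!is.null(config$epithelial_expressed_tfs)) {
    eligible <- eligible & tf_summary$tf %in% config$epithelial_expressed_tfs
  }
  tf_summary$candidate <- eligible &
    tf_summary$best_fold > config$fold_min & tf_summary$best_p < p_thresh
  list(results = results, tf_summary = tf_summary,
       candidates = tf_summary$tf[tf_summary$candidate],
       p_threshold = p_thresh)
}

#' Specificity control: flag enrichments across unrelated query gene sets
#'
#' For each query gene set screened against the full compendium, an
#' experiment is flagged significant iff it shows fold > \code{fold_min},
#' p < \code{p_max}, and ranks within the top \code{top_frac} (smallest p)
#' of all experiments for that query set.  Rank ties are broken by larger
#' fold, then lexicographic experiment id.  A TF with few or no flags
#' across diverse gene sets binds the age-related genes specifically
#' rather than differentially-regulated genes in general.
#'
#' @param results_by_set named list of per-experiment result tibbles (the
#'   \code{results} element of \code{\link{screen_experiments}}), one per
#'   query gene set.
#' @param tf optional TF name; restrict the report to its experiments.
#' @param fold_min,p_max,top_frac the three criteria (defaults 1.5, 5e-5,
#'   0.05).
#' @return tibble: query_set, experiment_id, tf, cell_line, fold, p, rank,
#'   n_experiments, flagged.
#' @export
specificity_filter <- function(results_by_set, tf = NULL,
                               fold_min = 1.5, p_max = 5e-5,
                               top_frac = 0.05) {
  stopifnot(length(results_by_set) >= 1)
  if (is.null(names(results_by_set))) {
    names(results_by_set) <- paste0("set", seq_along(results_by_set))
  }
  out <- lapply(names(results_by_set), function(set) {
    res <- results_by_set[[set]]
    ord <- order(res$p, -res$fold, res$experiment_id)
    res <- res[ord, , drop = FALSE]
    res$rank <- seq_len(nrow(res))
    res$n_experiments <- nrow(res)
    res$flagged <- res$fold > fold_min & res$p < p_max &
      res$rank / res$n_experiments <= top_frac
    res$query_set <- set
    if (!is.null(tf)) res <- res[res$tf %in% tf, , drop = FALSE]
    res[c("query_set", "experiment_id", "tf", "cell_line", "fold", "p",
          "rank", "n_experiments", "flagged")]
  })
  do.call(rbind, out)
}
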