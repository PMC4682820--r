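## In-code fixtures shared across test files.

## Write a narrowPeak file from component vectors; returns the path.
write_narrowpeak <- function(chrom, start, end, pval, qval, offset,
                             name = ".", path = tempfile(fileext = ".narrowPeak")) {
  df <- data.frame(chrom, start, end, name, 0L, ".", 0, pval, qval, offset)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

## Minimal hand-built expression object: genes x samples values matrix.
make_expr <- function(values, age, gfr = NULL, detection_p = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("G", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  expression_matrix(values, age, gfr = gfr, detection_p = detection_p)
}

## Brute-force hypergeometric enrichment tail via explicit log-binomials;
## independent of stats::phyper.
hyper_tail_bruteforce <- function(k, n_targets, n_query, n_universe) {
  ks <- k:min(n_targets, n_query)
  sum(exp(lchoose(n_query, ks) + lchoose(n_universe - n_query, n_targets - ks) -
            lchoose(n_universe, n_targets)))
}

## Brute-force promoter-window assignment by enumerating every (summit,
## TSS) pair against the signed-distance inequality.
assign_bruteforce <- function(peaks, tss, up = 5000, down = 2000) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(tss))) {
      if (peaks$chrom[i] != tss$chrom[j]) next
      d <- if (tss$strand[j] == "+") peaks$summit[i] - tss$tss[j]
           else tss$tss[j] - peaks$summit[i]
      if (d >= -up && d <= down) {
        out[[length(out) + 1L]] <- data.frame(
          experiment_id = peaks$experiment_id[i], gene_id = tss$gene_id[j])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(experiment_id = character(), gene_id = character()))
  }
  unique(do.call(rbind, out))
}

## Brute-force O(n^2) complexity: distinct TFs overlapping each peak on
## half-open intervals.
complexity_bruteforce <- function(peaks) {
  n <- nrow(peaks)
  vapply(seq_len(n), function(i) {
    tfs <- character()
    for (j in seq_len(n)) {
      if (peaks$chrom[i] != peaks$chrom[j]) next
      if (peaks$start[i] < peaks$end[j] && peaks$start[j] < peaks$end[i]) {
        tfs <- c(tfs, peaks$tf[j])
      }
    }
    length(unique(tfs))
  }, integer(1))
}

## Directly sampled target map for screen tests: each TF picks n_targets
## genes, the planted TF with weight rho on the query genes.
sample_target_map <- function(universe, query, n_tfs, n_targets, rho,
                              planted_tf = "TF1") {
  maps <- lapply(seq_len(n_tfs), function(ti) {
    tf <- paste0("TF", ti)
    w <- rep(1, length(universe))
    if (tf == planted_tf) w[universe %in% query] <- rho
    genes <- sample(universe, n_targets, prob = w / sum(w))
    data.frame(experiment_id = paste0(tf, "_E1"), tf = tf,
               cell_line = "CL1", gene_id = genes)
  })
  do.call(rbind, maps)
}
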