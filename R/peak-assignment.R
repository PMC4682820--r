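## Peak-to-gene assignment via promoter windows and the binding-site
## complexity (HOT-region) statistic.

#' Assign peaks to genes via promoter windows around the TSS
#'
#' A gene is a target of an experiment iff some peak's summit lies within
#' \code{up} bp upstream or \code{down} bp downstream of one of the gene's
#' annotated transcription start sites, strand-aware and inclusive at both
#' ends: with signed distance d = summit - tss on the + strand and
#' d = tss - summit on the - strand, the summit matches iff
#' \code{-up <= d <= down}.  Only the summit (position of maximum read
#' density) is used, never the full peak interval.
#'
#' @param peaks a \code{peak_set} tibble, already significance/length
#'   filtered (see \code{\link{read_peaks}}).
#' @param tss a TSS table from \code{\link{read_tss}}/\code{\link{tss_table}}.
#' @param up,down window extents in bp (defaults 5000 upstream, 2000
#'   downstream).
#' @return a target map: tibble with columns \code{experiment_id},
#'   \code{tf}, \code{cell_line}, \code{gene_id}, one row per bound gene
#'   per experiment.  Peaks on chromosomes absent from the annotation are
#'   skipped with a warning.
#' @export
assign_peaks_to_genes <- function(peaks, tss, up = 5000, down = 2000) {
  validate_peak_set(peaks)
  stopifnot(up >= 0, down >= 0)
  if (nrow(peaks) == 0L) {
    return(tibble::tibble(experiment_id = character(), tf = character(),
                          cell_line = character(), gene_id = character()))
  }
  orphan <- setdiff(unique(peaks$chrom), unique(tss$chrom))
  if (length(orphan)) {
    warning(sprintf("skipping peaks on chromosome(s) absent from annotation: %s",
                    paste(orphan, collapse = ", ")), call. = FALSE)
    peaks <- peaks[!peaks$chrom %in% orphan, , drop = FALSE]
  }
  if (nrow(peaks) == 0L) {
    return(tibble::tibble(experiment_id = character(), tf = character(),
                          cell_line = character(), gene_id = character()))
  }
  ## promoter window per TSS: [tss - up, tss + down] on +, reflected on -
  win_start <- ifelse(tss$strand == "+", tss$tss - up, tss$tss - down)
  win_end <- ifelse(tss$strand == "+", tss$tss + down, tss$tss + up)
  windows <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(start = win_start, end = win_end))
  summits <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$summit, width = 1L))
  hits <- GenomicRanges::findOverlaps(summits, windows)
  if (length(hits) == 0L) {
    return(tibble::tibble(experiment_id = character(), tf = character(),
                          cell_line = character(), gene_id = character()))
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- tibble::tibble(experiment_id = peaks$experiment_id[qi],
                        tf = peaks$tf[qi],
                        cell_line = peaks$cell_line[qi],
                        gene_id = tss$gene_id[si])
  unique(out)
}

#' Compute per-peak binding-site complexity
#'
#' The complexity of a peak is the number of distinct transcription factors
#' in the compendium with a significant binding site overlapping that
#' peak's \code{[start, end)} interval by at least 1 bp, the peak's own TF
#' included.  Overlapping sites of the same TF from multiple cell lines or
#' replicate experiments count once.
#'
#' @param all_peaksets a single combined \code{peak_set} tibble or a list
#'   of them spanning the full compendium.
#' @return the combined peak tibble with an integer \code{complexity}
#'   column appended.
#' @export
compute_complexity <- function(all_peaksets) {
  if (is.data.frame(all_peaksets)) all_peaksets <- list(all_peaksets)
  if (length(all_peaksets) == 0L) stop_msg("empty peak compendium")
  peaks <- do.call(rbind, lapply(all_peaksets, function(p) {
    validate_peak_set(p)
    p[c("chrom", "start", "end", "summit", "neg_log10_sig",
        "tf", "cell_line", "experiment_id")]
  }))
  if (nrow(peaks) == 0L) stop_msg("empty peak compendium")
  ## half-open [start, end): IRanges ends are inclusive, so end - 1
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start, end = peaks$end - 1L))
  hits <- GenomicRanges::findOverlaps(gr, gr)
  qi <- S4Vectors::queryHits(hits)
  tf_of_subject <- peaks$tf[S4Vectors::subjectHits(hits)]
  ## distinct TFs among overlappers, per query peak (self-hits included)
  key <- paste0(qi, "\r", tf_of_subject)
  first <- !duplicated(key)
  complexity <- tabulate(qi[first], nbins = nrow(peaks))
  peaks$complexity <- as.integer(complexity)
  peaks
}

#' Filter peaks by binding-site complexity
#'
#' Retains peaks bound by at most \code{ceiling(max_fraction * n_tfs)}
#' distinct transcription factors, discarding high-occupancy (HOT) sites.
#' With the compendium's 161 TFs and the default 50\% fraction the
#' threshold is 81: peaks bound by 81 or fewer TFs are kept.
#'
#' @param peaks peak tibble carrying a \code{complexity} column (from
#'   \code{\link{compute_complexity}}).
#' @param complexity optional integer vector overriding the column.
#' @param max_fraction complexity cutoff as a fraction of the compendium
#'   size; default 0.5.
#' @param n_tfs number of distinct TFs in the compendium.
#' @return the filtered peak tibble.
#' @export
filter_by_complexity <- function(peaks, complexity = peaks$complexity,
                                 max_fraction = 0.5, n_tfs) {
  if (n_tfs <= 0) stop_msg("n_tfs must be positive")
  if (is.null(complexity)) stop_msg("no complexity annotation supplied")
  stopifnot(length(complexity) == nrow(peaks))
  threshold <- ceiling(max_fraction * n_tfs)
  peaks[complexity <= threshold, , drop = FALSE]
}
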