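## Readers and writers for the file formats the pipeline touches, plus the
## core domain containers shared by all stages.
##
## Conventions: all genomic intervals are 0-based half-open [start, end)
## (BED); TSS positions are 0-based; narrowPeak significance columns are
## -log10-scaled per the ENCODE dialect.

#' Construct a peak table
#'
#' A peak table is a tibble with one row per ChIP-seq binding site and
#' columns \code{chrom}, \code{start}, \code{end} (0-based half-open),
#' \code{summit} (absolute position of maximum read density),
#' \code{neg_log10_sig} (significance as -log10 of the peak-caller q- or
#' p-value), \code{tf}, \code{cell_line} and \code{experiment_id}.
#'
#' @param chrom,start,end,summit,neg_log10_sig,tf,cell_line,experiment_id
#'   vectors of equal length (scalars are recycled).
#' @param provenance free-text source label stored as an attribute.
#' @return a tibble of class \code{peak_set}.
#' @export
peak_set <- function(chrom, start, end, summit, neg_log10_sig,
                     tf, cell_line, experiment_id, provenance = "") {
  ps <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    summit = as.integer(summit),
    neg_log10_sig = as.numeric(neg_log10_sig),
    tf = as.character(tf),
    cell_line = as.character(cell_line),
    experiment_id = as.character(experiment_id)
  )
  validate_peak_set(ps)
  attr(ps, "provenance") <- provenance
  class(ps) <- c("peak_set", class(ps))
  ps
}

validate_peak_set <- function(ps) {
  req <- c("chrom", "start", "end", "summit", "neg_log10_sig",
           "tf", "cell_line", "experiment_id")
  missing <- setdiff(req, names(ps))
  if (length(missing)) {
    stop_msg("peak table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (nrow(ps) == 0L) return(invisible(ps))
  if (any(ps$start < 0)) stop_msg("negative peak coordinates")
  if (any(ps$start >= ps$end)) stop_msg("peak with start >= end")
  bad <- ps$summit < ps$start | ps$summit >= ps$end
  if (any(bad)) stop_msg("summit outside [start, end) for %d peak(s)", sum(bad))
  if (any(ps$neg_log10_sig < 0)) stop_msg("negative -log10 significance")
  invisible(ps)
}

#' Read a narrowPeak or BED peak file with significance and length filters
#'
#' Accepts ENCODE narrowPeak (BED6+4) or BED6 with an extra significance
#' column.  For narrowPeak the q-value column is used when non-negative,
#' otherwise the p-value column (both -log10-scaled); the summit is
#' \code{start + peak offset}, falling back to the interval midpoint
#' (floor) when the offset is -1 or absent.  Peaks failing either the
#' significance threshold or the minimum length are dropped: a peak is
#' retained iff its -log10 significance is at least \code{-log10(sig_threshold)}
#' and its length is at least \code{min_length} base pairs.
#'
#' @param path file path.
#' @param sig_threshold peak-caller q- (or p-) value threshold in (0, 1);
#'   default \code{1e-5}.
#' @param min_length minimum peak length in bp kept; default 20.
#' @param tf,cell_line,experiment_id labels attached to every peak; by
#'   default parsed from a \code{tf|cell_line|experiment} name column when
#'   present, else derived from the file name.
#' @return a \code{peak_set} tibble.
#' @export
read_peaks <- function(path, sig_threshold = 1e-5, min_length = 20,
                       tf = NULL, cell_line = NULL, experiment_id = NULL) {
  stopifnot(sig_threshold > 0, sig_threshold < 1, min_length >= 1)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(nf) && length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop_msg("malformed line %d in %s: %d fields, expected %d",
             bad, path, nf[bad], nf[1L])
  }
  if (!length(nf)) {
    return(peak_set(character(), integer(), integer(), integer(),
                    numeric(), character(), character(), character(),
                    provenance = path))
  }
  ncol <- nf[1L]
  if (ncol < 6L) {
    stop_msg("malformed line 1 in %s: need >= 6 tab-separated fields", path)
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop_msg("malformed line %d in %s: non-numeric coordinates", bad, path)
  }
  if (any(start < 0)) stop_msg("negative coordinates in %s", path)

  if (ncol >= 10L) {                       # narrowPeak: BED6+4
    pval <- as.numeric(m[, 8])
    qval <- as.numeric(m[, 9])
    sig <- ifelse(qval >= 0, qval, pval)
    offset <- as.integer(m[, 10])
  } else {                                 # BED6 (+1 significance column)
    sig <- as.numeric(m[, min(7L, ncol)])
    offset <- rep(-1L, nrow(m))
  }
  summit <- ifelse(offset >= 0L, start + offset, (start + end) %/% 2L)

  name <- m[, 4]
  parsed <- strsplit(name, "|", fixed = TRUE)
  has3 <- lengths(parsed) == 3L
  base <- sub("\\.(narrowPeak|bed)(\\.gz)?$", "", basename(path))
  tf_v <- if (!is.null(tf)) tf else ifelse(has3, vapply(parsed, `[`, "", 1L), base)
  cl_v <- if (!is.null(cell_line)) cell_line else
    ifelse(has3, vapply(parsed, `[`, "", 2L), "NA")
  ex_v <- if (!is.null(experiment_id)) experiment_id else
    ifelse(has3, vapply(parsed, `[`, "", 3L), base)

  keep <- sig >= -log10(sig_threshold) & (end - start) >= min_length
  peak_set(m[keep, 1], start[keep], end[keep], as.integer(summit)[keep],
           sig[keep], tf_v[keep], cl_v[keep], ex_v[keep],
           provenance = path)
}

#' Write a peak table as narrowPeak
#'
#' Coordinates and -log10 significance round-trip bit-exactly through
#' \code{read_peaks} (the significance is written to both the p- and
#' q-value columns; TF, cell line and experiment are encoded in the name
#' column as \code{tf|cell_line|experiment}).
#'
#' @param peaks a \code{peak_set} tibble.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  validate_peak_set(peaks)
  out <- data.frame(
    peaks$chrom, peaks$start, peaks$end,
    paste(peaks$tf, peaks$cell_line, peaks$experiment_id, sep = "|"),
    0L, ".",
    0,
    format(peaks$neg_log10_sig, digits = 17, scientific = FALSE, trim = TRUE),
    format(peaks$neg_log10_sig, digits = 17, scientific = FALSE, trim = TRUE),
    peaks$summit - peaks$start
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a transcription-start-site table
#'
#' Tab-separated with columns \code{gene_id}, \code{chrom}, \code{strand},
#' \code{tss} (0-based).  Duplicate gene ids are kept: a gene may have
#' several annotated TSS and promoter-window assignment matches any of them.
#'
#' @param path file path.
#' @return tibble with columns gene_id, chrom, strand, tss.
#' @export
read_tss <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "strand", "tss")
  if (!all(req %in% names(df))) {
    stop_msg("TSS file must have columns %s", paste(req, collapse = ", "))
  }
  tss_table(df$gene_id, df$chrom, df$strand, df$tss)
}

#' @rdname read_tss
#' @param gene_id,chrom,strand,tss vectors of equal length.
#' @export
tss_table <- function(gene_id, chrom, strand, tss) {
  if (!all(strand %in% c("+", "-"))) {
    stop_msg("strand must be '+' or '-', got: %s",
             paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  }
  if (any(tss < 0)) stop_msg("TSS positions must be >= 0")
  tibble::tibble(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, tss = as.integer(tss))
}

#' Construct an expression matrix with sample metadata
#'
#' The container for normalized, log-scale expression used throughout:
#' a genes x samples matrix plus per-sample age (years), optional GFR
#' (mL/min/1.73 m^2) and an optional genes x samples detection p-value
#' matrix.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must
#'   carry row and column names.
#' @param age numeric vector of per-sample ages, matching columns.
#' @param gfr optional numeric vector of per-sample GFR.
#' @param detection_p optional matrix of detection p-values, same dim.
#' @return an object of class \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(values, age, gfr = NULL, detection_p = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_msg("expression matrix needs gene row names and sample column names")
  }
  if (length(age) != ncol(values)) stop_msg("age length != number of samples")
  if (any(age <= 0)) stop_msg("ages must be positive")
  if (!is.null(gfr) && length(gfr) != ncol(values)) {
    stop_msg("gfr length != number of samples")
  }
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(values))) {
      stop_msg("detection_p dimensions differ from expression values")
    }
    if (any(detection_p < 0 | detection_p > 1)) {
      stop_msg("detection p-values must lie in [0, 1]")
    }
  }
  structure(list(values = values, genes = rownames(values),
                 samples = colnames(values), age = as.numeric(age),
                 gfr = if (is.null(gfr)) NULL else as.numeric(gfr),
                 detection_p = detection_p),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              length(x$genes), length(x$samples)))
  cat(sprintf("  age: %.0f-%.0f yr; GFR: %s; detection p: %s\n",
              min(x$age), max(x$age),
              if (is.null(x$gfr)) "absent" else "present",
              if (is.null(x$detection_p)) "absent" else "present"))
  invisible(x)
}

#' Read an expression matrix and its sample metadata
#'
#' @param matrix_path TSV, header of sample ids, first column gene ids.
#' @param metadata_path TSV with columns \code{sample_id}, \code{age} and
#'   optionally \code{gfr}.
#' @param detection_path optional TSV of detection p-values, same layout
#'   as the matrix.
#' @return an \code{ExpressionMatrix}; metadata rows are aligned to the
#'   matrix column order.
#' @export
read_expression <- function(matrix_path, metadata_path, detection_path = NULL) {
  vals <- as.matrix(read.delim(matrix_path, row.names = 1, check.names = FALSE))
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "age") %in% names(meta))) {
    stop_msg("metadata must have columns sample_id and age")
  }
  missing <- setdiff(colnames(vals), meta$sample_id)
  extra <- setdiff(meta$sample_id, colnames(vals))
  if (length(missing) || length(extra)) {
    stop_msg("sample-id mismatch between matrix and metadata: missing [%s], extra [%s]",
             paste(missing, collapse = ", "), paste(extra, collapse = ", "))
  }
  meta <- meta[match(colnames(vals), meta$sample_id), ]
  det <- NULL
  if (!is.null(detection_path)) {
    det <- as.matrix(read.delim(detection_path, row.names = 1,
                                check.names = FALSE))
    det <- det[rownames(vals), colnames(vals), drop = FALSE]
  }
  expression_matrix(vals, meta$age,
                    gfr = if ("gfr" %in% names(meta)) meta$gfr else NULL,
                    detection_p = det)
}

#' Read a candidate-gene SNP association table
#'
#' TSV with columns \code{snp_id}, \code{gene}, \code{p_egfr}, \code{p_ckd},
#' \code{major}, \code{minor}, \code{maf}, \code{n_cases}, \code{n_controls}.
#' The minor-allele convention (maf <= 0.5) and p in (0, 1] are enforced.
#'
#' @param path file path.
#' @return tibble, one row per SNP, with p-values in columns
#'   \code{p_egfr} and \code{p_ckd}.
#' @export
read_assoc <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("snp_id", "gene", "p_egfr", "p_ckd", "major", "minor",
           "maf", "n_cases", "n_controls")
  if (!all(req %in% names(df))) {
    stop_msg("association file must have columns %s", paste(req, collapse = ", "))
  }
  validate_assoc(tibble::as_tibble(df[req]))
}

validate_assoc <- function(df) {
  p <- c(df$p_egfr, df$p_ckd)
  if (any(p <= 0 | p > 1)) stop_msg("association p-values must lie in (0, 1]")
  if (any(df$maf <= 0 | df$maf > 0.5)) {
    stop_msg("maf must lie in (0, 0.5] (minor-allele convention)")
  }
  if (any(df$n_cases <= 0 | df$n_controls <= 0)) {
    stop_msg("case/control sizes must be positive")
  }
  df
}
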