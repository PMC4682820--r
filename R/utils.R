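## Internal helpers shared across modules.

#' @importFrom tibble tibble as_tibble
#' @importFrom stats pbinom pchisq phyper pnorm pt qchisq rbinom rexp rnorm
#'   runif sd uniroot cor hclust as.dist chisq.test complete.cases setNames
#' @importFrom utils read.delim write.table
NULL

## Stable substream seed from a global seed and a generator label, so each
## synthetic-data generator draws from its own stream and adding a generator
## never shifts the others.  Polynomial string hash mod (2^31 - 1), folded
## with the global seed; always a valid 32-bit seed.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

with_substream <- function(seed, label, expr) {
  s <- substream_seed(seed, label)   # force seed before snapshotting RNG
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(s)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

stop_msg <- function(...) stop(sprintf(...), call. = FALSE)

## Pearson chi-square statistic of a 2x2 table of (possibly fractional
## expected) counts, 1 df, no continuity correction.  Used by the genetics
## module where cell counts are expected counts, not integers, so
## chisq.test() input checks do not apply.
chisq_stat_2x2 <- function(tab) {
  stopifnot(identical(dim(tab), c(2L, 2L)))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
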