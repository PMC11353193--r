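## Trimmed mean of M-values normalization: between-sample scaling factors
## from a doubly trimmed (30% on M, 5% on A), precision-weighted mean of
## per-gene log ratios against a reference sample, rescaled to geometric
## mean 1.

#' Counts per million
#' @param counts Gene x sample matrix (non-negative, possibly non-integer).
#' @param lib_size Library sizes (default column sums).
#' @param log Return log2 CPM with a prior count.
#' @param prior_count Prior added (per million-scaled) before log.
#' @return Matrix of (log2) CPM.
#' @export
cpm <- function(counts, lib_size = colSums(counts), log = FALSE,
                prior_count = 0.5) {
  if (log) {
    log2(t((t(counts) + prior_count) / (lib_size + 2 * prior_count)) * 1e6)
  } else {
    t(t(counts) / lib_size) * 1e6
  }
}

#' TMM normalization factors
#'
#' The reference sample is the one whose 75th-percentile count-to-library
#' ratio is closest to the mean across samples. For each sample, using the
#' genes positive in both it and the reference, per-gene log ratios
#' `M = log2((y/N)/(y_r/N_r))` and abundances
#' `A = 0.5 log2(y y_r/(N N_r))` are computed; the top and bottom 30% of M
#' and 5% of A (by rank) are dropped, and the factor is
#' `2^(sum(w M)/sum(w))` with inverse asymptotic binomial variance weights
#' `w = 1/(1/y - 1/N + 1/y_r - 1/N_r)`. Factors are rescaled to geometric
#' mean 1. A sample sharing no positive gene with the reference gets factor
#' 1 with a warning; so do exactly-scaled libraries (all |M| < 1e-6).
#'
#' @param counts Gene x sample matrix.
#' @param lib_size Library sizes (default column sums, must be positive).
#' @return A `norm_factors` data.frame: `sample`, `lib_size`, `factor`,
#'   `effective_lib_size`; the reference sample index is attached as an
#'   attribute.
#' @export
tmm_factors <- function(counts, lib_size = colSums(counts)) {
  assert_that(ncol(counts) >= 2, "TMM needs at least 2 samples")
  assert_that(all(lib_size > 0), "all library sizes must be positive")
  f75 <- apply(counts, 2, quantile, probs = 0.75, names = FALSE) / lib_size
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- counts[, ref]; nr <- lib_size[ref]
  fac <- vapply(seq_len(ncol(counts)), function(i) {
    y <- counts[, i]; n <- lib_size[i]
    pos <- y > 0 & yr > 0
    if (!any(pos)) {
      warning(sprintf("sample %d shares no positive genes with the reference; factor set to 1",
                      i))
      return(1)
    }
    m <- log2((y[pos] / n) / (yr[pos] / nr))
    a <- 0.5 * log2((y[pos] / n) * (yr[pos] / nr))
    if (max(abs(m)) < 1e-6) return(1)
    w <- 1 / (1 / y[pos] - 1 / n + 1 / yr[pos] - 1 / nr)
    nn <- length(m)
    lo_m <- floor(nn * 0.3) + 1; hi_m <- nn - floor(nn * 0.3)
    lo_a <- floor(nn * 0.05) + 1; hi_a <- nn - floor(nn * 0.05)
    rm_ <- rank(m); ra <- rank(a)
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
    if (!any(keep) || sum(w[keep]) <= 0) return(1)
    2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  out <- data.frame(sample = colnames(counts) %||% seq_len(ncol(counts)),
                    lib_size = lib_size, factor = fac,
                    effective_lib_size = lib_size * fac,
                    stringsAsFactors = FALSE)
  class(out) <- c("norm_factors", "data.frame")
  attr(out, "reference") <- ref
  out
}
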