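## Differential expression for two-group contrasts on (possibly
## non-integer) expected counts: abundance filtering, NB dispersion
## estimation by Cox-Reid adjusted profile likelihood with weighted-
## likelihood shrinkage, per-gene GLM fits with library-size offsets, and
## an empirical-Bayes quasi-likelihood F-test with BH adjustment.

## ---- NB fitting internals -------------------------------------------------

## Fit per-gene NB means for a one-way layout by Newton iterations on the
## group log-mean (cell-means parameterization; offsets are log effective
## library sizes). Vectorized across genes. Returns mu matrix, per-group
## coefficients and a convergence flag per gene.
nb_fit_groups <- function(y, offset, group, phi, max_iter = 50L, tol = 1e-10) {
  g_levels <- levels(group)
  G <- nrow(y)
  beta <- matrix(NA_real_, G, length(g_levels),
                 dimnames = list(NULL, g_levels))
  mu <- matrix(0, G, ncol(y))
  converged <- rep(TRUE, G)
  for (k in seq_along(g_levels)) {
    sel <- which(group == g_levels[k])
    ys <- y[, sel, drop = FALSE]
    os <- offset[sel]
    tot <- rowSums(ys)
    b <- log(pmax(tot, 1e-8) / sum(exp(os)))   # Poisson start
    active <- tot > 0
    for (it in seq_len(max_iter)) {
      if (!any(active)) break
      m <- exp(outer(b, os, "+"))
      pm <- 1 + phi * m
      score <- rowSums((ys - m) / pm)
      info <- rowSums(m * (1 + phi * ys) / pm^2)
      step <- score / pmax(info, 1e-12)
      step <- pmin(pmax(step, -5), 5)
      b_new <- pmin(pmax(b + ifelse(active, step, 0), -50), 50)
      done <- abs(b_new - b) < tol
      b <- b_new
      active <- active & !done
      if (it == max_iter && any(active)) converged[active] <- FALSE
    }
    beta[, k] <- b
    mu[, sel] <- exp(outer(b, os, "+"))
  }
  list(beta = beta, mu = mu, converged = converged)
}

## Continuous NB deviance (valid for non-integer y); phi may be per-gene.
nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu))
  2 * rowSums(t1 - t2)
}

## Continuous NB log-likelihood (Gamma-function form) summed per gene.
nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  r <- 1 / phi
  rowSums(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
          y * log(phi * mu / (1 + phi * mu)) - r * log1p(phi * mu))
}

## Cox-Reid adjusted profile log-likelihood per gene at dispersion phi
## (scalar), with means refit at that phi. For the cell-means design the
## information matrix is diagonal per group.
nb_apl <- function(y, offset, group, phi) {
  fit <- nb_fit_groups(y, offset, group, phi)
  ll <- nb_loglik(y, fit$mu, phi)
  w <- fit$mu / (1 + phi * fit$mu)
  cr <- 0
  for (k in levels(group)) {
    sel <- group == k
    cr <- cr + 0.5 * log(pmax(rowSums(w[, sel, drop = FALSE]), 1e-12))
  }
  ll - cr
}

## ---- exported operations --------------------------------------------------

#' Filter low-abundance genes
#'
#' Keeps a gene iff its CPM reaches `C = min_count / (median library size
#' in millions)` in at least `m` samples (the smallest group size) and its
#' total count is at least `min_total`.
#'
#' @param counts Gene x sample matrix (non-negative, possibly non-integer).
#' @param group Factor of group labels per sample.
#' @param min_count,min_total Filtering constants (defaults 10 and 15).
#' @return list with the filtered `counts` and the logical `keep` vector.
#' @export
filter_low_abundance <- function(counts, group, min_count = 10,
                                 min_total = 15) {
  lib <- colSums(counts)
  cutoff <- min_count / (median(lib) / 1e6)
  m <- min(table(group))
  x <- cpm(counts)
  keep <- rowSums(x >= cutoff) >= m & rowSums(counts) >= min_total
  if (!any(keep)) {
    stop_ilseq("all genes removed by the abundance filter; lower min_count/min_total")
  }
  list(counts = counts[keep, , drop = FALSE], keep = keep)
}

#' Estimate NB dispersions
#'
#' The common dispersion maximizes the Cox-Reid adjusted NB profile
#' likelihood summed over genes (1-D search on log phi in
#' `[log 1e-4, log 10]`). Per-gene dispersions are then shrunk toward the
#' common value by maximizing the weighted likelihood
#' `APL_g(phi) + (prior_df/df_res) * mean_g APL(phi)` on a log-phi grid
#' with quadratic refinement (prior weight equivalent to `prior_df` = 10
#' residual degrees of freedom by default).
#'
#' @param counts Filtered gene x sample matrix.
#' @param factors A [tmm_factors()] result (effective library sizes become
#'   GLM offsets).
#' @param group Two-level factor per sample.
#' @param prior_df Prior degrees of freedom for shrinkage.
#' @param grid_length Number of grid points for the per-gene search.
#' @return list with `common` (scalar) and `tagwise` (per-gene vector),
#'   plus the search grid diagnostics.
#' @export
estimate_dispersions <- function(counts, factors, group, prior_df = 10,
                                 grid_length = 61L) {
  y <- as.matrix(counts)
  offset <- log(factors$effective_lib_size)
  group <- droplevels(as.factor(group))
  df_res <- ncol(y) - nlevels(group)
  assert_that(df_res >= 1, "at least one residual degree of freedom required")
  lo <- log(1e-4); hi <- log(10)
  common <- tryCatch({
    opt <- optimize(function(lphi) sum(nb_apl(y, offset, group, exp(lphi))),
                    interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    exp(opt$maximum)
  }, error = function(e) {
    warning("common-dispersion search failed; falling back to method of moments: ",
            conditionMessage(e))
    mom_dispersion(y, offset, group)
  })
  grid <- seq(lo, hi, length.out = grid_length)
  apl <- vapply(grid, function(lphi) nb_apl(y, offset, group, exp(lphi)),
                numeric(nrow(y)))
  if (nrow(y) == 1) apl <- matrix(apl, nrow = 1)
  shared <- colMeans(apl)
  wl <- apl + matrix(rep((prior_df / df_res) * shared, each = nrow(y)),
                     nrow = nrow(y))
  best <- max.col(wl, ties.method = "first")
  ## quadratic interpolation around the grid maximum
  lphi <- vapply(seq_len(nrow(y)), function(g) {
    j <- best[g]
    if (j == 1L || j == grid_length) return(grid[j])
    y3 <- wl[g, (j - 1L):(j + 1L)]
    denom <- y3[1] - 2 * y3[2] + y3[3]
    if (denom >= 0) return(grid[j])
    grid[j] + 0.5 * (y3[1] - y3[3]) / denom * (grid[2] - grid[1])
  }, numeric(1))
  list(common = common, tagwise = exp(lphi), prior_df = prior_df,
       grid = grid)
}

## Method-of-moments pooled dispersion (fallback only).
mom_dispersion <- function(y, offset, group, floor_phi = 1e-4) {
  scaled <- t(t(y) / exp(offset - mean(offset)))
  phis <- unlist(lapply(levels(group), function(k) {
    s <- scaled[, group == k, drop = FALSE]
    m <- rowMeans(s); v <- apply(s, 1, var)
    (v - m) / m^2
  }))
  max(floor_phi, median(phis[is.finite(phis)], na.rm = TRUE))
}

#' Quasi-likelihood F-test for a two-group contrast
#'
#' Per gene, NB log-linear models with `log(effective library size)`
#' offsets are fit under the null (common mean) and full (group means)
#' models; the raw quasi-dispersion `s2 = residual deviance / residual df`
#' is squeezed across genes toward a scaled inverse-chi-square prior whose
#' scale `s0^2` and degrees of freedom `d0` are estimated by moment
#' matching on `log s2`; the statistic
#' `F = (deviance_null - deviance_full) / s2_post` is referred to
#' `F(1, d0 + df_res)`. The log2 fold change is the difference of fitted
#' group coefficients on the log2 scale (group2 vs group1).
#'
#' @param counts Filtered gene x sample matrix.
#' @param factors A [tmm_factors()] result.
#' @param group Two-level factor (the contrast is `levels[2]` vs
#'   `levels[1]`).
#' @param dispersions A vector of per-gene NB dispersions or the result of
#'   [estimate_dispersions()].
#' @return A `de_result` data.frame: `gene_id`, `log2fc`, `avg_log2cpm`,
#'   `f_stat`, `p_value`, `fdr`, `converged`; prior df `d0` and prior value
#'   `s0_sq` are attached as attributes.
#' @export
ql_f_test <- function(counts, factors, group, dispersions) {
  y <- as.matrix(counts)
  group <- droplevels(as.factor(group))
  assert_that(nlevels(group) == 2, "ql_f_test expects exactly two groups")
  phi <- if (is.list(dispersions)) dispersions$tagwise else dispersions
  if (length(phi) == 1) phi <- rep(phi, nrow(y))
  phi <- pmax(phi, 1e-6)
  offset <- log(factors$effective_lib_size)
  full <- nb_fit_groups(y, offset, group, phi)
  null_group <- factor(rep("all", ncol(y)))
  null <- nb_fit_groups(y, offset, null_group, phi)
  dev_full <- nb_deviance(y, full$mu, phi)
  dev_null <- nb_deviance(y, null$mu, phi)
  df_res <- ncol(y) - 2L
  s2 <- pmax(dev_full, 0) / df_res
  sq <- squeeze_var(s2, df_res)
  f_stat <- pmax(dev_null - dev_full, 0) / sq$s2_post
  p <- pf(f_stat, df1 = 1, df2 = sq$d0 + df_res, lower.tail = FALSE)
  ok <- full$converged & null$converged
  p[!ok] <- 1
  lfc <- (full$beta[, 2] - full$beta[, 1]) / log(2)
  out <- data.frame(
    gene_id = rownames(y) %||% as.character(seq_len(nrow(y))),
    log2fc = lfc,
    avg_log2cpm = rowMeans(cpm(y, factors$effective_lib_size, log = TRUE)),
    f_stat = f_stat, p_value = p, fdr = bh_adjust(p),
    converged = ok,
    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  attr(out, "d0") <- sq$d0
  attr(out, "s0_sq") <- sq$s0_sq
  out
}

## Moment-matching squeeze of per-gene variances toward a scaled
## inverse-chi-square prior (estimated on log s2). Degenerate spread gives
## d0 = Inf, whose limiting posterior is the prior value itself.
squeeze_var <- function(s2, df) {
  z <- log(s2)
  fin <- is.finite(z)
  if (sum(fin) < 2) {
    warning("too few finite quasi-dispersions; no squeezing applied")
    s0 <- if (any(fin)) exp(mean(z[fin])) else 1
    return(list(d0 = Inf, s0_sq = s0, s2_post = rep(s0, length(s2))))
  }
  e <- z[fin] - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
  } else {
    ## no excess spread beyond sampling noise: the prior-df limit d0 = Inf
    d0 <- Inf
    s0_sq <- exp(mean(e))
    s2_post <- rep(s0_sq, length(s2))
  }
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post)
}

## Solve trigamma(x) = y by Newton on the stated monotone transform.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values; `NaN`/`NA` entries propagate and are
#' excluded from the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA/NaN allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  fin <- is.finite(p)
  out[fin] <- p.adjust(p[fin], method = "BH")
  out
}

#' One full two-group DE analysis
#'
#' Chains filtering, TMM, dispersion estimation and the QL F-test for one
#' contrast.
#'
#' @param counts Gene x sample expected-count matrix.
#' @param group Two-level factor per sample (level 2 vs level 1).
#' @param fdr Significance threshold recorded in the summary attribute.
#' @param prior_df Dispersion-shrinkage prior df.
#' @return A `de_result` (see [ql_f_test()]); the kept-gene vector and the
#'   up/down summary at `fdr` are attached as attributes.
#' @export
de_analysis <- function(counts, group, fdr = 0.05, prior_df = 10) {
  group <- droplevels(as.factor(group))
  flt <- filter_low_abundance(counts, group)
  nf <- tmm_factors(flt$counts)
  disp <- estimate_dispersions(flt$counts, nf, group, prior_df = prior_df)
  res <- ql_f_test(flt$counts, nf, group, disp)
  sig <- !is.na(res$fdr) & res$fdr < fdr
  attr(res, "keep") <- flt$keep
  attr(res, "dispersion_common") <- disp$common
  attr(res, "summary") <- list(up = sum(sig & res$log2fc > 0),
                               down = sum(sig & res$log2fc < 0),
                               fdr = fdr)
  res
}

#' Run the five study contrasts
#'
#' One control-vs-parasitized DE analysis per (genotype, genome) count
#' matrix: the pure genotype against genome A, and each introgression line
#' against both genomes.
#'
#' @param matrices Named list of gene x sample matrices; names are contrast
#'   labels (e.g. `Formula_lyc`, `IL62_lyc`, `IL62_penn`, ...).
#' @param groups Named list (same names) of two-level factors per matrix.
#' @param fdr Significance threshold for the DEG summary.
#' @return list with `tables` (named `de_result` list) and `summary`
#'   (data.frame of up/down DEG counts per contrast).
#' @export
run_contrasts <- function(matrices, groups, fdr = 0.05) {
  assert_that(identical(sort(names(matrices)), sort(names(groups))),
              "matrices and groups must carry the same contrast names")
  tables <- list()
  for (nm in names(matrices)) {
    if (is.null(matrices[[nm]])) {
      stop_ilseq(sprintf("missing count matrix for contrast '%s'", nm))
    }
    tables[[nm]] <- de_analysis(matrices[[nm]], groups[[nm]], fdr = fdr)
  }
  summ <- do.call(rbind, lapply(names(tables), function(nm) {
    s <- attr(tables[[nm]], "summary")
    data.frame(contrast = nm, up = s$up, down = s$down,
               total = s$up + s$down, stringsAsFactors = FALSE)
  }))
  list(tables = tables, summary = summ)
}
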