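two_group <- function(n = 3) factor(rep(c("control", "parasitized"), each = n))

test_that("abundance filter implements the CPM/total-count rule", {
  set.seed(1)
  counts <- matrix(rnbinom(60, mu = 50, size = 5), 10, 6)
  counts[1, ] <- 0                         # all-zero: removed
  counts[2, ] <- 1e6                       # huge: kept
  flt <- filter_low_abundance(counts, two_group())
  expect_false(flt$keep[1])
  expect_true(flt$keep[2])
  ## toy: equal library sizes 1e6 => cutoff CPM 10 exactly
  m <- matrix(0, 3, 6)
  m[1, ] <- c(10, 10, 10, 0, 0, 0)         # CPM 10 in exactly m=3 samples
  m[2, ] <- rep(9.99, 6)                   # CPM 9.99 everywhere
  m[3, ] <- 1e6 / 6                        # filler so libraries ~ 1e6
  filler <- matrix(rep((1e6 - colSums(m)) , each = 1), 1)
  m <- rbind(m, filler)
  stopifnot(all(abs(colSums(m) - 1e6) < 1e-9))
  flt2 <- filter_low_abundance(m, two_group())
  expect_true(flt2$keep[1])
  expect_false(flt2$keep[2])
  ## direct rule evaluation oracle on a random matrix
  set.seed(9)
  r <- matrix(rnbinom(300, mu = 8, size = 2), 50, 6)
  r <- r[rowSums(r) > 0, ]
  flt3 <- filter_low_abundance(r, two_group(), min_count = 10, min_total = 15)
  lib <- colSums(r)
  cutoff <- 10 / (median(lib) / 1e6)
  oracle <- rowSums(t(t(r) / lib) * 1e6 >= cutoff) >= 3 & rowSums(r) >= 15
  expect_identical(unname(flt3$keep), unname(oracle))
  expect_error(filter_low_abundance(matrix(1, 2, 6), two_group()), "filter")
})

test_that("TMM factors are exact on trivial libraries and match the literal formula", {
  ident <- matrix(rep(c(5, 10, 200, 50, 3), 4), 5, 4)
  expect_equal(tmm_factors(ident)$factor, rep(1, 4))
  scaled <- cbind(c(5, 10, 200, 50, 3), 3 * c(5, 10, 200, 50, 3))
  expect_equal(tmm_factors(scaled)$factor, c(1, 1))
  set.seed(4)
  for (i in 1:10) {
    m <- matrix(rnbinom(800, mu = exp(runif(200, 1, 6)), size = 3), 200, 4)
    m <- m[rowSums(m) > 0, ]
    got <- tmm_factors(m)$factor
    expect_equal(got, oracle_tmm(m), tolerance = 1e-10)
    expect_equal(exp(mean(log(got))), 1, tolerance = 1e-12)
  }
})

test_that("TMM is invariant to rescaling a library", {
  set.seed(11)
  m <- matrix(rnbinom(600, mu = 80, size = 5), 150, 4)
  f1 <- tmm_factors(m)$factor
  m2 <- m; m2[, 3] <- m[, 3] * 7       # same composition, deeper library
  f2 <- tmm_factors(m2)$factor
  ## M, A and the trim sets are scale-free, so the factors move only
  ## through the precision weights (which see absolute counts)
  expect_equal(f1, f2, tolerance = 0.02)
  ## and the M-values themselves are exactly unchanged
  lib <- colSums(m); lib2 <- colSums(m2)
  expect_equal(log2((m[, 3] / lib[3]) / (m[, 1] / lib[1])),
               log2((m2[, 3] / lib2[3]) / (m2[, 1] / lib2[1])))
})

test_that("TMM agrees with the edgeR implementation", {
  skip_if_not_installed("edgeR")
  set.seed(21)
  m <- matrix(rnbinom(1200, mu = exp(runif(300, 1, 7)), size = 4), 300, 4)
  m <- m[rowSums(m) > 0, ]
  expect_equal(tmm_factors(m)$factor, unname(edgeR::calcNormFactors(m)),
               tolerance = 1e-10)
})

test_that("dispersion estimation recovers known truth", {
  grp <- two_group()
  ## Poisson data: common dispersion collapses to the lower bound
  cfg <- sim_config(seed = 3, n_genes = 2000, library_size_mean = 1e6,
                    de_fraction = 0, nb_dispersion = 0)
  sim <- simulate_counts(cfg)
  flt <- filter_low_abundance(sim$counts, grp)
  nf <- tmm_factors(flt$counts)
  d <- estimate_dispersions(flt$counts, nf, grp)
  expect_lte(d$common, 0.01)
  ## NB phi = 0.1: recovered within [0.08, 0.12]
  cfg2 <- sim_config(seed = 6, n_genes = 2000, library_size_mean = 1e6,
                     de_fraction = 0, nb_dispersion = 0.1)
  sim2 <- simulate_counts(cfg2)
  flt2 <- filter_low_abundance(sim2$counts, grp)
  nf2 <- tmm_factors(flt2$counts)
  d2 <- estimate_dispersions(flt2$counts, nf2, grp)
  expect_gte(d2$common, 0.08)
  expect_lte(d2$common, 0.12)
  ## shrinkage pulls per-gene values toward the common one
  mle_like <- estimate_dispersions(flt2$counts[1:50, ], nf2, grp,
                                   prior_df = 1e-6)$tagwise
  shrunk <- estimate_dispersions(flt2$counts[1:50, ], nf2, grp,
                                 prior_df = 10)$tagwise
  expect_lt(mean(abs(log(shrunk) - log(d2$common))),
            mean(abs(log(mle_like) - log(d2$common))))
})

test_that("QL F-test behaves at the fixed points", {
  grp <- two_group()
  set.seed(8)
  counts <- matrix(rnbinom(100 * 6, mu = 100, size = 10), 100, 6)
  rownames(counts) <- sprintf("g%03d", 1:100)
  counts[1, ] <- 80                       # identical group means
  nf <- tmm_factors(counts)
  res <- ql_f_test(counts, nf, grp, dispersions = rep(0.1, 100))
  expect_lt(res$f_stat[1], 0.2)
  expect_gt(res$p_value[1], 0.6)
  ## swapping group labels negates every log2FC exactly
  grp_swap <- factor(grp, levels = rev(levels(grp)))
  res2 <- ql_f_test(counts, nf, grp_swap, dispersions = rep(0.1, 100))
  expect_equal(res2$log2fc, -res$log2fc, tolerance = 1e-10)
})

test_that("a strongly planted gene is detected with high power", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    mu <- matrix(100, 200, 6)
    mu[1, 4:6] <- 400                     # log2FC = 2 in parasitized
    counts <- matrix(rnbinom(200 * 6, mu = mu, size = 20), 200, 6)
    rownames(counts) <- sprintf("g%03d", 1:200)
    res <- de_analysis(counts, two_group())
    if ("g001" %in% res$gene_id &&
        res$fdr[res$gene_id == "g001"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p_na <- c(0.01, NaN, 0.5)
  adj <- bh_adjust(p_na)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], oracle_bh(c(0.01, 0.5)))
  set.seed(2)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("run_contrasts returns one table per contrast and a DEG summary", {
  set.seed(14)
  mk <- function() {
    m <- matrix(rnbinom(600, mu = 100, size = 8), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
    m
  }
  mats <- list(c1 = mk(), c2 = mk())
  grps <- list(c1 = two_group(), c2 = two_group())
  rc <- run_contrasts(mats, grps)
  expect_named(rc$tables, c("c1", "c2"))
  expect_equal(nrow(rc$summary), 2)
  expect_equal(rc$summary$total, rc$summary$up + rc$summary$down)
  expect_error(run_contrasts(list(c1 = NULL), list(c1 = two_group())),
               "missing count matrix")
})
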