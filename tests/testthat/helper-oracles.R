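## Independent oracles used across the suite. Each is deliberately written
## from the definition (enumeration, brute force, literal formula), not by
## calling the package code it checks.

## Brute-force bundle classifier: enumerate per-genome maxima independently.
oracle_classify <- function(bundle) {
  a <- bundle$AS[bundle$genome == "A"]
  b <- bundle$AS[bundle$genome == "B"]
  if (length(a) == 0) return("PENN")
  if (length(b) == 0) return("SLYC")
  if (max(a) > max(b)) "SLYC" else if (max(b) > max(a)) "PENN" else "AMBI"
}

## Random alignment bundles: 1-6 records, scores in [-50, 200], random
## genome mix (guaranteed nonempty).
random_bundles <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(1:6, 1)
    data.frame(fragment_id = paste0("f", i),
               genome = sample(c("A", "B"), k, replace = TRUE),
               AS = sample(-50:200, k, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

## Step-up BH from the definition: adj_i = min over j with p_(j) >= p_(i)
## of min(1, m*p_(j)/j).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- pmin(1, m * p[ord] / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

## Literal TMM formula, coded independently (loop-based, no shared helpers).
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  f75 <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    f75[j] <- quantile(counts[, j], 0.75, names = FALSE) / lib[j]
  }
  r <- which.min(abs(f75 - mean(f75)))
  fac <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    y <- counts[, j]; yr <- counts[, r]
    use <- which(y > 0 & yr > 0)
    M <- log2((y[use] / lib[j]) / (yr[use] / lib[r]))
    A <- 0.5 * log2((y[use] / lib[j]) * (yr[use] / lib[r]))
    if (max(abs(M)) < 1e-6) { fac[j] <- 1; next }
    w <- 1 / (1 / y[use] - 1 / lib[j] + 1 / yr[use] - 1 / lib[r])
    n <- length(use)
    keepM <- rank(M) >= floor(0.3 * n) + 1 & rank(M) <= n - floor(0.3 * n)
    keepA <- rank(A) >= floor(0.05 * n) + 1 & rank(A) <= n - floor(0.05 * n)
    keep <- keepM & keepA
    fac[j] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  fac / exp(mean(log(fac)))
}

## Exact hypergeometric upper tail by combinatorial enumeration.
oracle_hyper <- function(N, K, n, k) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

## EM fixed point by long brute-force iteration of the stated update.
oracle_em <- function(frag_genes, genes, iters = 10000) {
  theta <- rep(1 / length(genes), length(genes))
  names(theta) <- genes
  for (i in seq_len(iters)) {
    cnt <- setNames(numeric(length(genes)), genes)
    for (cand in frag_genes) {
      w <- theta[cand] / sum(theta[cand])
      cnt[cand] <- cnt[cand] + w
    }
    theta <- cnt / sum(cnt)
  }
  cnt <- setNames(numeric(length(genes)), genes)
  for (cand in frag_genes) {
    w <- theta[cand] / sum(theta[cand])
    cnt[cand] <- cnt[cand] + w
  }
  cnt
}

## Tiny study config used by several end-to-end tests.
small_config <- function(seed = 5, ...) {
  sim_config(seed = seed, n_genes = 120, library_size_mean = 5000, ...)
}
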