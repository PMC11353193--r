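## Relative qPCR quantification by the 2^-ddCt method: technical replicates
## are collapsed, target Ct is normalized to a reference (actin-like) gene
## per biological replicate, and the parasitized-vs-control shift in dCt
## gives ddCt and fold change 2^-ddCt, with a Welch (default) or
## permutation test on the replicate dCt sets.

#' Collapse technical replicates to per-biological-replicate mean Ct
#'
#' @param ct_table Long table with `genotype`, `condition`,
#'   `biological_replicate`, `gene`, `technical_replicate`, `ct`.
#' @param sd_flag_cycles Technical SD above this value (cycles) is flagged.
#' @return data.frame with one row per (genotype, condition, replicate,
#'   gene): mean `ct`, `ct_sd`, `n_technical`, flags `high_sd` and
#'   `low_replication`.
#' @export
technical_collapse <- function(ct_table, sd_flag_cycles = 0.5) {
  assert_that(all(c("genotype", "condition", "biological_replicate",
                    "gene", "ct") %in% names(ct_table)),
              "ct_table is missing required columns")
  assert_that(all(ct_table$ct > 0), "Ct values must be positive")
  key <- list(genotype = ct_table$genotype, condition = ct_table$condition,
              biological_replicate = ct_table$biological_replicate,
              gene = ct_table$gene)
  mean_ct <- aggregate(ct_table$ct, key, mean)
  sd_ct <- aggregate(ct_table$ct, key, function(x) {
    if (length(x) > 1) sd(x) else 0
  })
  n_ct <- aggregate(ct_table$ct, key, length)
  out <- mean_ct
  names(out)[names(out) == "x"] <- "ct"
  out$ct_sd <- sd_ct$x
  out$n_technical <- n_ct$x
  out$high_sd <- out$ct_sd > sd_flag_cycles
  out$low_replication <- out$n_technical < 3
  out[order(out$genotype, out$gene, out$condition, out$biological_replicate), ] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Relative expression by 2^-ddCt for one gene and genotype
#'
#' Per biological replicate, `dCt = Ct_target - Ct_reference`; replicates
#' missing the reference are excluded with a warning. Then
#' `ddCt = mean(dCt_parasitized) - mean(dCt_control)` and
#' `fold = 2^-ddCt`. The condition comparison uses a two-sided Welch test
#' on the two dCt sets by default, or an exact permutation test on the
#' difference of means.
#'
#' @param collapsed Output of [technical_collapse()].
#' @param reference_gene,target_gene,genotype Selection of the comparison.
#' @param test `"welch"` or `"permutation"`.
#' @param alpha Significance level for the flag.
#' @return A one-row `ddct_result` data.frame: gene, genotype, per-condition
#'   mean dCt, `ddct`, `fold`, `p_value`, `significant`.
#' @export
ddct <- function(collapsed, reference_gene, target_gene, genotype,
                 test = c("welch", "permutation"), alpha = 0.05) {
  test <- match.arg(test)
  d <- collapsed[collapsed$genotype == genotype &
                 collapsed$gene %in% c(reference_gene, target_gene), ]
  ref <- d[d$gene == reference_gene, ]
  tgt <- d[d$gene == target_gene, ]
  m <- match(paste(tgt$condition, tgt$biological_replicate),
             paste(ref$condition, ref$biological_replicate))
  if (anyNA(m)) {
    warning(sprintf("%d replicate(s) without reference Ct excluded for %s/%s",
                    sum(is.na(m)), genotype, target_gene))
  }
  keep <- !is.na(m)
  dct <- tgt$ct[keep] - ref$ct[m[keep]]
  cond <- tgt$condition[keep]
  dct_c <- dct[cond == "control"]
  dct_p <- dct[cond == "parasitized"]
  assert_that(length(dct_c) >= 1 && length(dct_p) >= 1,
              "both conditions must be present")
  ddct_val <- mean(dct_p) - mean(dct_c)
  p <- NA_real_
  if (length(dct_c) >= 2 && length(dct_p) >= 2) {
    if (test == "welch") {
      p <- tryCatch(t.test(dct_p, dct_c)$p.value, error = function(e) NA_real_)
    } else {
      p <- permutation_p(dct_c, dct_p)
    }
  }
  out <- data.frame(gene = target_gene, genotype = genotype,
                    n_control = length(dct_c), n_parasitized = length(dct_p),
                    mean_dct_control = mean(dct_c),
                    mean_dct_parasitized = mean(dct_p),
                    ddct = ddct_val, fold = 2^(-ddct_val),
                    p_value = p,
                    significant = !is.na(p) & p < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("ddct_result", "data.frame")
  out
}

## Exact two-sided permutation test on the difference of group means
## (complete enumeration of group assignments when feasible).
permutation_p <- function(x, y, max_exact = 1e4) {
  n1 <- length(x); n <- n1 + length(y)
  pool <- c(x, y)
  obs <- abs(mean(y) - mean(x))
  if (choose(n, n1) <= max_exact) {
    combs <- utils::combn(n, n1)
    stats <- apply(combs, 2, function(idx) {
      abs(mean(pool[-idx]) - mean(pool[idx]))
    })
    mean(stats >= obs - 1e-12)
  } else {
    hits <- 0L; B <- as.integer(max_exact)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n1)
      if (abs(mean(pool[-idx]) - mean(pool[idx])) >= obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (B + 1)
  }
}

#' Fold-change panel across genes and genotypes
#'
#' Runs [ddct()] for every (target gene, genotype) combination present in
#' the collapsed table and assembles fold-change and significance matrices
#' (bar-plot ready); missing combinations yield NA cells.
#'
#' @param collapsed Output of [technical_collapse()].
#' @param reference_gene Reference gene id.
#' @param targets Target gene ids (default: all non-reference genes).
#' @param genotypes Genotypes (default: all present).
#' @inheritParams ddct
#' @return list with `table` (long results), `fold` and `significant`
#'   (gene x genotype matrices).
#' @export
summarize_panel <- function(collapsed, reference_gene,
                            targets = setdiff(unique(collapsed$gene),
                                              reference_gene),
                            genotypes = unique(collapsed$genotype),
                            test = "welch", alpha = 0.05) {
  rows <- list()
  fold <- matrix(NA_real_, length(targets), length(genotypes),
                 dimnames = list(targets, genotypes))
  sig <- matrix(NA, length(targets), length(genotypes),
                dimnames = list(targets, genotypes))
  for (g in targets) {
    for (geno in genotypes) {
      sub <- collapsed[collapsed$genotype == geno & collapsed$gene == g, ]
      has_ref <- any(collapsed$genotype == geno &
                     collapsed$gene == reference_gene)
      if (nrow(sub) == 0 || !has_ref) next
      r <- ddct(collapsed, reference_gene, g, geno, test = test,
                alpha = alpha)
      rows[[paste(g, geno)]] <- r
      fold[g, geno] <- r$fold
      sig[g, geno] <- r$significant
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(table)) rownames(table) <- NULL
  list(table = table, fold = fold, significant = sig)
}
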