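toy_annotation <- function() {
  data.frame(
    gene_id = c(paste0("g", 1:6, "_A"), paste0("g", c(1, 2, 7), "_B")),
    pathway_id = c("pw1", "pw1", "pw2", "pw2", "pw2", "pw3",
                   "pw1", "pw2", "pw2"),
    pathway_name = "x",
    species = c(rep("A", 6), rep("B", 3)),
    stringsAsFactors = FALSE)
}

test_that("hypergeometric p equals exact enumeration", {
  ## the N=10, K=2, n=5, k=2 case: C(2,2) C(8,3) / C(10,5) = 2/9
  universe <- paste0("u", 1:10)
  ann <- data.frame(gene_id = universe,
                    pathway_id = c("p1", "p1", rep("p2", 8)),
                    pathway_name = "x")
  de <- universe[c(1, 2, 3, 4, 5)]
  res <- hypergeom_enrich(de, universe, ann)
  expect_equal(res$p_value[res$pathway_id == "p1"], 2 / 9, tolerance = 1e-12)
  ## sweep all small configurations against the combinatorial oracle
  for (N in c(5, 12, 25)) {
    for (K in c(1, 3, N %/% 2)) {
      for (n in c(1, N %/% 3, N)) {
        for (k in 0:min(K, n)) {
          expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                       oracle_hyper(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("degenerate enrichment inputs give forced p-values", {
  universe <- paste0("u", 1:10)
  ann <- data.frame(gene_id = universe,
                    pathway_id = rep(c("p1", "p2"), each = 5),
                    pathway_name = "x")
  ## no DE gene in a pathway: p = 1
  res0 <- hypergeom_enrich(character(0), universe, ann)
  expect_true(all(res0$p_value == 1))
  ## whole universe DE: k = K, p = 1
  resN <- hypergeom_enrich(universe, universe, ann)
  expect_true(all(resN$k == resN$K))
  expect_true(all(resN$p_value == 1))
  ## p is non-increasing in k for fixed (N, K, n)
  ps <- vapply(0:5, function(k) phyper(k - 1, 5, 5, 5, lower.tail = FALSE),
               numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("separate-species analyses are independent", {
  ann <- toy_annotation()
  de_a <- data.frame(gene_id = paste0("g", 1:6, "_A"),
                     fdr = c(0.01, 0.01, 0.9, 0.9, 0.9, 0.9))
  de_b <- data.frame(gene_id = paste0("g", c(1, 2, 7), "_B"),
                     fdr = rep(0.9, 3))
  res <- enrich_separate(list(A = de_a, B = de_b), ann)
  expect_named(res, c("A", "B"))
  ## pw1 is fully DE on the A side: ranks first there
  expect_equal(res$A$pathway_id[1], "pw1")
  expect_equal(res$A$k[res$A$pathway_id == "pw1"], 2)
  ## species B has no DE genes: all p = 1
  expect_true(all(res$B$p_value == 1))
  ## empty species-B table leaves species A untouched
  res2 <- enrich_separate(list(A = de_a, B = de_b[0, ]), ann)
  expect_equal(res2$A$p_value, res$A$p_value)
  expect_equal(nrow(res2$B[res2$B$k > 0, ]), 0)
})

test_that("merged mode concatenates members without deduplication", {
  ann <- toy_annotation()
  de_a <- data.frame(gene_id = paste0("g", 1:6, "_A"), fdr = 0.9)
  de_b <- data.frame(gene_id = paste0("g", c(1, 2, 7), "_B"), fdr = 0.9)
  res <- hypergeom_enrich(character(0),
                          c(de_a$gene_id, de_b$gene_id), ann,
                          approach = "merged")
  ## pw2: K_A = 3, K_B = 2 => merged K = 5
  expect_equal(res$K[res$pathway_id == "pw2"], 5)
  ## a homolog DE in both species contributes k = 2
  de_a2 <- de_a; de_a2$fdr[1] <- 0.001
  de_b2 <- de_b; de_b2$fdr[1] <- 0.001
  resm <- enrich_merged(list(A = de_a2, B = de_b2), ann)
  expect_equal(resm$k[resm$pathway_id == "pw1"], 2)
  ## when one species contributes no members the merged p reduces to the
  ## separate one computed on the same universe
  ann3 <- ann[ann$pathway_id == "pw3" | ann$species == "A", ]
  m3 <- enrich_merged(list(A = de_a2, B = de_b2[0, ]), ann3)
  s3 <- hypergeom_enrich(de_genes <- de_a2$gene_id[de_a2$fdr < 0.05],
                         de_a2$gene_id, ann3[ann3$species == "A", ])
  expect_equal(m3$p_value[m3$pathway_id == "pw3"],
               s3$p_value[s3$pathway_id == "pw3"])
  ## stem deduplication collapses cross-species homologs
  resd <- enrich_merged(list(A = de_a2, B = de_b2), ann, dedup_by_stem = TRUE)
  expect_equal(resd$k[resd$pathway_id == "pw1"], 1)
})

test_that("a pathway built from planted DE genes ranks first", {
  cfg <- sim_config(seed = 41, n_genes = 300, library_size_mean = 1e5,
                    de_fraction = 0.1, de_log2fc = 2)
  sim <- simulate_counts(cfg)
  res <- de_analysis(sim$counts, factor(sim$design$condition))
  de_true <- sim$gene_truth$gene_id[sim$gene_truth$de]
  others <- setdiff(res$gene_id, de_true)
  set.seed(1)
  ann <- data.frame(
    gene_id = c(de_true, sample(others, 200)),
    pathway_id = c(rep("planted", length(de_true)),
                   sample(paste0("pw", 1:8), 200, replace = TRUE)),
    pathway_name = "x")
  de_obs <- res$gene_id[res$fdr < 0.05]
  enr <- hypergeom_enrich(intersect(de_obs, res$gene_id), res$gene_id, ann)
  expect_equal(enr$pathway_id[1], "planted")
  expect_lt(enr$adj_p[1], 0.05)
})

test_that("overlap summary counts shared and unique pathways", {
  mk <- function(ids, adj) {
    data.frame(pathway_id = ids, pathway_name = ids, N = 10, K = 2, n = 3,
               k = 1, p_value = adj, adj_p = adj)
  }
  a <- mk(c("p1", "p2", "p3", "p9"), c(0.01, 0.01, 0.01, 0.9))
  b <- mk(c("p3", "p4"), c(0.01, 0.01))
  ov <- summarize_overlap(a, b)
  expect_equal(ov$venn, list(unique_a = 2, shared = 1, unique_b = 1))
  ## identical significant sets
  ov2 <- summarize_overlap(a, a)
  expect_equal(ov2$venn$shared, 3)
  expect_equal(ov2$venn$unique_a + ov2$venn$unique_b, 0)
  ## top table is capped at top_n
  many <- mk(sprintf("p%02d", 1:25), seq(0.001, 0.025, length.out = 25))
  ov3 <- summarize_overlap(many, b, top_n = 20)
  expect_equal(nrow(ov3$top$a), 20)
})
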