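test_that("configuration bounds are enforced", {
  expect_error(sim_config(divergence_rate = 0.3), "divergence_rate")
  expect_error(sim_config(error_rate = 0.05), "error_rate")
  expect_error(sim_config(n_genes = 10, introgression_genes = 11), "introgression")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("genome pair divergence matches the configured rate", {
  cfg0 <- sim_config(seed = 2, n_genes = 20, divergence_rate = 0)
  p0 <- make_genome_pair(cfg0)
  expect_identical(p0$seq_a, p0$seq_b)
  expect_true(all(lengths(p0$div_sites) == 0))

  cfg <- sim_config(seed = 2, n_genes = 50, gene_length = 1000,
                    divergence_rate = 0.02)
  p <- make_genome_pair(cfg)
  nsites <- sum(lengths(p$div_sites))
  expected <- 50 * 1000 * 0.02
  sdev <- sqrt(50 * 1000 * 0.02 * 0.98)
  expect_lt(abs(nsites - expected), 3 * sdev)
  ## genome B differs from A exactly at the divergent sites
  for (i in c(1, 25, 50)) {
    a <- strsplit(p$seq_a[i], "")[[1]]
    b <- strsplit(p$seq_b[i], "")[[1]]
    expect_identical(which(a != b), as.integer(p$div_sites[[i]]))
  }
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9, n_genes = 40, library_size_mean = 2000)
  p1 <- make_genome_pair(cfg); p2 <- make_genome_pair(cfg)
  expect_identical(p1, p2)
  s1 <- simulate_counts(cfg); s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  a1 <- simulate_alignment_bundles(cfg, p1, s1, introgressed = 1:4)
  a2 <- simulate_alignment_bundles(cfg, p2, s2, introgressed = 1:4)
  expect_identical(a1$records, a2$records)
  expect_identical(a1$truth, a2$truth)
})

test_that("planted truth and library sizes behave as configured", {
  cfg0 <- sim_config(seed = 4, n_genes = 200, de_fraction = 0,
                     library_size_mean = 5e4)
  s0 <- simulate_counts(cfg0)
  expect_true(all(s0$gene_truth$true_log2fc == 0))

  cfg <- sim_config(seed = 4, n_genes = 500, de_fraction = 0.1,
                    de_log2fc = 2, library_size_mean = 5e4)
  s <- simulate_counts(cfg)
  expect_equal(sum(s$gene_truth$de), 50)
  de <- s$gene_truth[s$gene_truth$de, ]
  expect_true(all(abs(abs(de$true_log2fc) - 2) < 1e-12))
  ## expected column depth is exact; realized sums within 3 SDs
  mu <- s$mu
  expect_equal(unname(colSums(mu)), rep(5e4, ncol(mu)), tolerance = 1e-10)
  vsum <- colSums(mu + cfg$nb_dispersion * mu^2)
  expect_true(all(abs(colSums(s$counts) - 5e4) < 3 * sqrt(vsum)))
})

test_that("single-replicate conditions are rejected", {
  cfg <- sim_config(seed = 1, n_genes = 20, n_replicates = 1)
  expect_error(simulate_counts(cfg), "replicates")
})

test_that("NB sampling approaches the Poisson limit as dispersion vanishes", {
  cfg <- sim_config(seed = 8, n_genes = 1, nb_dispersion = 1e-6,
                    de_fraction = 0, library_size_mean = 1000,
                    n_replicates = 5000)
  des <- data.frame(sample = paste0("s", 1:10000),
                    condition = rep(c("control", "parasitized"), each = 5000))
  s <- simulate_counts(cfg, des)
  x <- as.numeric(s$counts)
  expect_lt(abs(var(x) / mean(x) - 1), 0.1)
})

test_that("fragment emission conserves counts and encodes origin scores", {
  cfg <- sim_config(seed = 7, n_genes = 40, library_size_mean = 3000,
                    error_rate = 0)
  pair <- make_genome_pair(cfg)
  sim <- simulate_counts(cfg)
  al <- simulate_alignment_bundles(cfg, pair, sim, introgressed = 1:6)
  ## conservation: one fragment per counted unit, per sample
  per_sample <- table(al$truth$sample)
  expect_equal(as.integer(per_sample[colnames(sim$counts)]),
               unname(colSums(sim$counts)))
  ## every fragment appears exactly once in the truth table
  expect_false(any(duplicated(al$truth$fragment_id)))
  ## with no sequencing errors: zero divergent sites covered => tied AS;
  ## >=1 site covered, origin B => higher AS on B
  rec <- al$records
  tr <- al$truth
  as_a <- rec$AS[rec$genome == "A"][match(tr$fragment_id,
            rec$fragment_id[rec$genome == "A"])]
  as_b <- rec$AS[rec$genome == "B"][match(tr$fragment_id,
            rec$fragment_id[rec$genome == "B"])]
  tied <- tr$n_div_covered == 0
  expect_true(all(as_a[tied] == as_b[tied]))
  bor <- tr$origin == "B" & tr$n_div_covered >= 1
  expect_true(all(as_b[bor] > as_a[bor]))
  aor <- tr$origin == "A" & tr$n_div_covered >= 1
  expect_true(all(as_a[aor] > as_b[aor]))
})

test_that("recorded AS agrees with mismatches recomputed from sequences", {
  cfg <- sim_config(seed = 13, n_genes = 20, library_size_mean = 1500,
                    error_rate = 0.01)
  pair <- make_genome_pair(cfg)
  sim <- simulate_counts(cfg)
  al <- simulate_alignment_bundles(cfg, pair, sim, introgressed = 1:3)
  tr <- al$truth
  rec <- al$records
  idx <- which(tr$sample == tr$sample[1])[1:200]
  for (i in idx) {
    g <- match(tr$gene[i], pair$gene_ids)
    st <- tr$gene_start_offset[i]
    win_a <- substr(pair$seq_a[g], st, st + cfg$read_length - 1)
    win_b <- substr(pair$seq_b[g], st, st + cfg$read_length - 1)
    rd <- strsplit(tr$seq[i], "")[[1]]
    mm_a <- sum(rd != strsplit(win_a, "")[[1]])
    mm_b <- sum(rd != strsplit(win_b, "")[[1]])
    ra <- rec[rec$fragment_id == tr$fragment_id[i] & rec$genome == "A", ]
    rb <- rec[rec$fragment_id == tr$fragment_id[i] & rec$genome == "B", ]
    expect_equal(ra$AS[1], cfg$read_length - 3 * mm_a)
    expect_equal(rb$AS[1], cfg$read_length - 3 * mm_b)
  }
})

test_that("divergent-site coverage of fragments rises with divergence", {
  frac_covered <- vapply(c(0.005, 0.02, 0.05), function(d) {
    cfg <- sim_config(seed = 21, n_genes = 30, library_size_mean = 2000,
                      divergence_rate = d)
    pair <- make_genome_pair(cfg)
    sim <- simulate_counts(cfg)
    al <- simulate_alignment_bundles(cfg, pair, sim)
    mean(al$truth$n_div_covered >= 1)
  }, numeric(1))
  expect_true(all(diff(frac_covered) > 0))
})

test_that("Ct tables follow the log2 expression model", {
  cfg <- sim_config(seed = 3, n_genes = 10, n_replicates = 2)
  des <- make_design(cfg, "F")
  expr <- matrix(100, 10, 4, dimnames = list(gene_ids <- sprintf("g%04d", 1:10),
                                             des$sample))
  expr[2, des$condition == "parasitized"] <- 50   # halved expression
  ct <- simulate_ct_table(cfg, expr, targets = c("g0002", "g0003"),
                          reference_gene = "g0001", design = des, sigma = 0)
  coll <- technical_collapse(ct)
  ## sigma = 0: technical replicates identical
  expect_true(all(coll$ct_sd == 0))
  g2c <- coll$ct[coll$gene == "g0002" & coll$condition == "control"]
  g2p <- coll$ct[coll$gene == "g0002" & coll$condition == "parasitized"]
  ## halved expression raises Ct by exactly one cycle
  expect_equal(unique(g2p) - unique(g2c), 1, tolerance = 1e-12)
  ## constant-expression gene: identical Ct everywhere
  g3 <- coll$ct[coll$gene == "g0003"]
  expect_true(all(abs(g3 - g3[1]) < 1e-12))
  ## zero expression is capped and flagged
  expr0 <- expr; expr0[3, ] <- 0
  ct0 <- simulate_ct_table(cfg, expr0, targets = "g0003",
                           reference_gene = "g0001", design = des, sigma = 0)
  expect_true(all(ct0$capped[ct0$gene == "g0003"]))
  expect_true(all(ct0$ct[ct0$gene == "g0003"] == cfg$ct_max))
  ## zero reference is an error
  exprr <- expr; exprr[1, ] <- 0
  expect_error(simulate_ct_table(cfg, exprr, targets = "g0002",
                                 reference_gene = "g0001", design = des),
               "reference")
})
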