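## Synthetic study generator: a diverged genome pair, introgression-line
## genotypes, negative-binomial counts with planted differential expression,
## per-fragment alignment bundles against both genomes, pathway annotations
## and qPCR Ct tables. Everything is seeded and reproducible.

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every
#' `simulate_*()` generator. Identical configurations (including `seed`)
#' produce bit-identical outputs.
#'
#' @param seed Integer seed driving all generators.
#' @param n_genes Number of genes per genome.
#' @param gene_length Gene (transcript) length in bp; genes are unspliced,
#'   gene-level models.
#' @param spacer_length Length of the intergenic spacer separating genes on
#'   the simulated chromosome.
#' @param divergence_rate Per-bp substitution rate between the two genomes;
#'   must lie in `[0, 0.25]`.
#' @param introgression_genes Integer indices (1-based) of genes whose
#'   alleles come from genome B in the introgression-line genotype.
#' @param n_replicates Biological replicates per condition.
#' @param library_size_mean Expected sequenced fragments per sample.
#' @param nb_dispersion Negative-binomial dispersion phi (0 gives Poisson).
#' @param de_fraction Fraction of genes with a planted expression effect.
#' @param de_log2fc Planted absolute log2 fold change for affected genes.
#' @param read_length Fragment/read length in nt.
#' @param error_rate Per-base sequencing substitution error rate; must lie
#'   in `[0, 0.05)`.
#' @param mismatch_penalty Per-mismatch penalty used for the alignment score
#'   `AS = matches - mismatch_penalty * mismatches`.
#' @param paralog_fraction Fraction of fragments that additionally align to
#'   a random second gene (cross-gene multi-mapping).
#' @param paralog_penalty Score penalty applied to the paralogous alignment.
#' @param ct_sigma Technical standard deviation (cycles) of simulated Ct.
#' @param ct_intercept Ct of a transcript at 1 CPM (the Ct model is
#'   `Ct = ct_intercept - log2(CPM) + N(0, ct_sigma)`).
#' @param ct_max Cap applied to Ct values for zero-expression genes.
#' @param emit_sequences Whether to realize read sequences (needed for
#'   FASTA/SAM output; scores are computed either way).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 500L,
                       gene_length = 1000L,
                       spacer_length = 200L,
                       divergence_rate = 0.02,
                       introgression_genes = integer(0),
                       n_replicates = 3L,
                       library_size_mean = 2e4,
                       nb_dispersion = 0.1,
                       de_fraction = 0.1,
                       de_log2fc = 2,
                       read_length = 150L,
                       error_rate = 0.001,
                       mismatch_penalty = 2L,
                       paralog_fraction = 0,
                       paralog_penalty = 0L,
                       ct_sigma = 0.2,
                       ct_intercept = 34,
                       ct_max = 40,
                       emit_sequences = TRUE) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    spacer_length = as.integer(spacer_length),
    divergence_rate = divergence_rate,
    introgression_genes = as.integer(introgression_genes),
    n_replicates = as.integer(n_replicates),
    library_size_mean = library_size_mean,
    nb_dispersion = nb_dispersion,
    de_fraction = de_fraction, de_log2fc = de_log2fc,
    read_length = as.integer(read_length), error_rate = error_rate,
    mismatch_penalty = as.integer(mismatch_penalty),
    paralog_fraction = paralog_fraction,
    paralog_penalty = as.integer(paralog_penalty),
    ct_sigma = ct_sigma, ct_intercept = ct_intercept, ct_max = ct_max,
    emit_sequences = isTRUE(emit_sequences))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$divergence_rate >= 0 && cfg$divergence_rate <= 0.25,
              "divergence_rate must lie in [0, 0.25]")
  assert_that(cfg$error_rate >= 0 && cfg$error_rate < 0.05,
              "error_rate must lie in [0, 0.05)")
  assert_that(cfg$n_genes >= 1, "n_genes must be >= 1")
  assert_that(cfg$gene_length >= cfg$read_length,
              "gene_length must be >= read_length")
  assert_that(all(cfg$introgression_genes >= 1L &
                  cfg$introgression_genes <= cfg$n_genes),
              "introgression_genes must be gene indices in 1..n_genes")
  assert_that(cfg$nb_dispersion >= 0, "nb_dispersion must be >= 0")
  assert_that(cfg$de_fraction >= 0 && cfg$de_fraction <= 1,
              "de_fraction must lie in [0, 1]")
  assert_that(cfg$paralog_fraction >= 0 && cfg$paralog_fraction <= 1,
              "paralog_fraction must lie in [0, 1]")
  assert_that(cfg$n_replicates >= 1, "n_replicates must be >= 1")
  invisible(cfg)
}

gene_ids <- function(cfg) sprintf("g%04d", seq_len(cfg$n_genes))

## 1-based start of gene i on the simulated chromosome (spacer before each
## gene, one trailing spacer).
gene_starts <- function(cfg) {
  i <- seq_len(cfg$n_genes)
  i * cfg$spacer_length + (i - 1L) * cfg$gene_length + 1L
}

shift_base <- function(base, k) {
  ## deterministic substitution: k in 1..3 moves to one of the 3 other bases
  BASES[((match(base, BASES) - 1L + k) %% 4L) + 1L]
}

#' Simulate a diverged genome pair
#'
#' Genome A is random sequence; genome B is identical except at divergent
#' sites drawn per-bp at `divergence_rate`. Both genomes are colinear: gene
#' i occupies the same coordinates on `chrA` and `chrB`, so homologous
#' alignments share positions.
#'
#' @param config A [sim_config()].
#' @return A `genome_pair` object: per-gene sequences for both genomes,
#'   per-gene divergent-site positions (1-based within the gene), gene
#'   coordinates and the spacer sequences making up each chromosome.
#' @export
make_genome_pair <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, 11L))
  n <- config$n_genes; L <- config$gene_length
  mat <- matrix(sample(BASES, n * L, replace = TRUE), nrow = n)
  div_idx <- which(matrix(runif(n * L) < config$divergence_rate, nrow = n))
  mat_b <- mat
  if (length(div_idx)) {
    mat_b[div_idx] <- shift_base(mat[div_idx],
                                 sample.int(3L, length(div_idx), replace = TRUE))
  }
  rows <- ((div_idx - 1L) %% n) + 1L
  cols <- ((div_idx - 1L) %/% n) + 1L
  div_sites <- lapply(seq_len(n), function(i) sort(cols[rows == i]))
  spacers <- vapply(seq_len(n + 1L), function(i) {
    paste(sample(BASES, config$spacer_length, replace = TRUE), collapse = "")
  }, character(1))
  pair <- list(
    config = config,
    gene_ids = gene_ids(config),
    gene_start = gene_starts(config),
    gene_length = L,
    seq_a = do.call(paste0, lapply(seq_len(L), function(j) mat[, j])),
    seq_b = do.call(paste0, lapply(seq_len(L), function(j) mat_b[, j])),
    div_sites = div_sites,
    spacers = spacers,
    chrom = c(A = "chrA", B = "chrB"))
  class(pair) <- "genome_pair"
  pair
}

#' Assemble the chromosome sequence of one genome
#' @param pair A `genome_pair`.
#' @param genome `"A"` or `"B"`.
#' @return A single chromosome string (spacers interleaved with genes).
#' @export
build_chromosome <- function(pair, genome = c("A", "B")) {
  genome <- match.arg(genome)
  genes <- if (genome == "A") pair$seq_a else pair$seq_b
  n <- length(genes)
  pieces <- character(2L * n + 1L)
  pieces[seq(1L, 2L * n + 1L, by = 2L)] <- pair$spacers
  pieces[seq(2L, 2L * n, by = 2L)] <- genes
  paste(pieces, collapse = "")
}

#' Gene models of one genome as a coordinate table
#' @inheritParams build_chromosome
#' @return data.frame with `gene_id` (suffixed `_A`/`_B`), `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @export
gene_models <- function(pair, genome = c("A", "B")) {
  genome <- match.arg(genome)
  data.frame(
    gene_id = paste0(pair$gene_ids, "_", genome),
    chrom = unname(pair$chrom[genome]),
    start = pair$gene_start,
    end = pair$gene_start + pair$gene_length - 1L,
    stringsAsFactors = FALSE)
}

#' Experimental design for one genotype
#' @param config A [sim_config()].
#' @param genotype Genotype label used to prefix sample names.
#' @return data.frame with `sample`, `genotype`, `condition`, `replicate`.
#' @export
make_design <- function(config, genotype = "F") {
  r <- seq_len(config$n_replicates)
  data.frame(
    sample = c(paste0(genotype, "c", r), paste0(genotype, "p", r)),
    genotype = genotype,
    condition = rep(c("control", "parasitized"), each = config$n_replicates),
    replicate = c(r, r),
    stringsAsFactors = FALSE)
}

#' Simulate NB counts with planted differential expression
#'
#' Gene baseline abundances are Gamma-distributed relative weights. Genes
#' with a planted effect get symmetric half-effects `2^(+/-de_log2fc/2)` in
#' the two conditions so the condition mean ratio is exactly
#' `2^(+/-de_log2fc)`; the remaining genes are rescaled per condition so the
#' expected column sum equals `library_size_mean` in every sample (they
#' thereby acquire a very small compensating fold change, recorded in the
#' truth table, which is exactly zero when `de_fraction = 0`).
#'
#' @param config A [sim_config()].
#' @param design data.frame with at least `sample` and `condition`
#'   (`"control"`/`"parasitized"`); defaults to [make_design()].
#' @return A `sim_counts` object: integer `counts` (gene x sample), latent
#'   mean matrix `mu`, per-gene `gene_truth` (weight, DE flag, true log2FC,
#'   condition means) and the design.
#' @export
simulate_counts <- function(config, design = make_design(config)) {
  validate_sim_config(config)
  assert_that(all(c("sample", "condition") %in% names(design)),
              "design needs columns 'sample' and 'condition'")
  tab <- table(design$condition)
  assert_that(length(tab) == 2 && all(tab >= 2),
              paste("each condition needs >= 2 replicates",
                    "(dispersion is unestimable otherwise)"))
  set.seed(stage_seed(config$seed, 23L))
  n <- config$n_genes
  w <- rgamma(n, shape = 1)
  w <- w / sum(w)
  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
  direction <- integer(n)
  if (n_de > 0) direction[de_idx] <- sample(rep(c(1L, -1L), length.out = n_de))
  half <- config$de_log2fc / 2
  f_control <- 2^(-direction * half)
  f_paras <- 2^(direction * half)
  de <- direction != 0L
  ## rescale non-DE genes so each condition's expected depth is exact
  scale_cond <- function(f) {
    de_mass <- sum(w[de] * f[de])
    assert_that(de_mass < 1,
                "planted DE mass exceeds the library; reduce de_fraction/de_log2fc")
    if (any(!de)) (1 - de_mass) / sum(w[!de]) else 1
  }
  a_c <- scale_cond(f_control); a_p <- scale_cond(f_paras)
  mu_c <- ifelse(de, w * f_control, w * a_c) * config$library_size_mean
  mu_p <- ifelse(de, w * f_paras, w * a_p) * config$library_size_mean
  mu <- matrix(unlist(lapply(design$condition, function(cond) {
    if (cond == "control") mu_c else mu_p
  })), nrow = n)
  dimnames(mu) <- list(gene_ids(config), design$sample)
  counts <- matrix(
    if (config$nb_dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    } else {
      rpois(length(mu), lambda = mu)
    },
    nrow = n, dimnames = dimnames(mu))
  truth <- data.frame(
    gene_id = gene_ids(config), weight = w, de = de, direction = direction,
    true_log2fc = log2(mu_p / mu_c),
    mu_control = mu_c, mu_parasitized = mu_p,
    stringsAsFactors = FALSE)
  out <- list(counts = counts, mu = mu, gene_truth = truth,
              design = design, config = config)
  class(out) <- "sim_counts"
  out
}

## cumulative divergent-site counts: row g, column p+1 = #sites <= p
div_cumulative <- function(pair) {
  L <- pair$gene_length
  t(vapply(pair$div_sites, function(s) {
    c(0L, cumsum(tabulate(s, nbins = L)))
  }, integer(L + 1L)))
}

#' Simulate per-fragment alignment bundles against both genomes
#'
#' Each counted fragment is drawn from its origin gene's allele (genome B
#' for introgressed genes of an IL, genome A otherwise), sequencing errors
#' are applied, and candidate alignments to the homologous gene in both
#' genomes are emitted with `AS = matches - mismatch_penalty * mismatches`
#' and `NH` = bundle size. In `pure_species` mode (a sample of the recurrent
#' species aligned against its own genome only) only genome-A records are
#' emitted.
#'
#' @param config A [sim_config()].
#' @param pair A [make_genome_pair()] result.
#' @param sim A [simulate_counts()] result (its `counts` drive fragment
#'   numbers).
#' @param introgressed Integer gene indices carrying genome-B alleles;
#'   defaults to `config$introgression_genes`.
#' @param pure_species If `TRUE`, emit single-genome (A) alignments only.
#' @return An `alignment_sim` list: `records` (one row per candidate
#'   alignment: `fragment_id`, `sample`, `genome`, `chrom`, `pos`, `width`,
#'   `AS`, `NH`, `secondary`) and per-fragment `truth` (origin gene/genome,
#'   divergent sites covered, errors, read sequence).
#' @export
simulate_alignment_bundles <- function(config, pair, sim,
                                       introgressed = config$introgression_genes,
                                       pure_species = FALSE) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, 37L))
  counts <- sim$counts
  L <- config$read_length
  pen1 <- 1L + config$mismatch_penalty
  divcum <- div_cumulative(pair)
  rec_list <- vector("list", ncol(counts))
  truth_list <- vector("list", ncol(counts))
  for (s in seq_len(ncol(counts))) {
    smp <- colnames(counts)[s]
    cnt <- counts[, s]
    nf <- sum(cnt)
    if (nf == 0) next
    g <- rep.int(seq_along(cnt), cnt)
    start <- sample.int(config$gene_length - L + 1L, nf, replace = TRUE)
    from_b <- g %in% introgressed & !pure_species
    n_err <- rbinom(nf, L, config$error_rate)
    n_div <- divcum[cbind(g, start + L)] - divcum[cbind(g, start)]
    seq_origin <- ifelse(from_b, pair$seq_b[g], pair$seq_a[g])
    reads <- if (config$emit_sequences || any(n_err > 0)) {
      substring(seq_origin, start, start + L - 1L)
    } else character(nf)
    e_div <- integer(nf); e_div_match <- integer(nf)
    err_i <- which(n_err > 0)
    if (length(err_i)) {
      seq_other <- ifelse(from_b, pair$seq_a[g], pair$seq_b[g])
      other_win <- substring(seq_other[err_i], start[err_i],
                             start[err_i] + L - 1L)
      for (jj in seq_along(err_i)) {
        j <- err_i[jj]
        qs <- sample.int(L, n_err[j])
        rd <- reads[j]
        for (q in qs) {
          p <- start[j] + q - 1L
          old <- substr(rd, q, q)
          new <- shift_base(old, sample.int(3L, 1L))
          substr(rd, q, q) <- new
          if (divcum[g[j], p + 1L] - divcum[g[j], p] == 1L) {
            e_div[j] <- e_div[j] + 1L
            if (substr(other_win[jj], q, q) == new) {
              e_div_match[j] <- e_div_match[j] + 1L
            }
          }
        }
        reads[j] <- rd
      }
    }
    mm_origin <- n_err
    mm_other <- n_div + n_err - e_div - e_div_match
    as_origin <- L - pen1 * mm_origin
    as_other <- L - pen1 * mm_other
    as_a <- ifelse(from_b, as_other, as_origin)
    as_b <- ifelse(from_b, as_origin, as_other)
    pos <- pair$gene_start[g] + start - 1L
    fid <- paste0(smp, ".f", seq_len(nf))
    is_par <- if (config$paralog_fraction > 0 && length(cnt) > 1) {
      runif(nf) < config$paralog_fraction
    } else rep(FALSE, nf)
    par_g <- integer(nf)
    if (any(is_par)) {
      pg <- sample.int(length(cnt) - 1L, sum(is_par), replace = TRUE)
      og <- g[is_par]
      par_g[is_par] <- pg + (pg >= og)   # uniform over genes != origin
    }
    par_pos <- rep(NA_integer_, nf)
    par_pos[is_par] <- pair$gene_start[par_g[is_par]] + start[is_par] - 1L
    if (pure_species) {
      nh <- 1L + is_par
      rec <- data.frame(
        fragment_id = c(fid, fid[is_par]),
        sample = smp,
        genome = "A",
        chrom = "chrA",
        pos = c(pos, par_pos[is_par]),
        width = L,
        AS = c(as_a, as_a[is_par] - config$paralog_penalty),
        NH = c(nh, nh[is_par]),
        secondary = c(rep(FALSE, nf), rep(TRUE, sum(is_par))),
        stringsAsFactors = FALSE)
    } else {
      nh <- 2L + 2L * is_par
      rec <- data.frame(
        fragment_id = c(fid, fid, fid[is_par], fid[is_par]),
        sample = smp,
        genome = c(rep("A", nf), rep("B", nf),
                   rep("A", sum(is_par)), rep("B", sum(is_par))),
        chrom = c(rep("chrA", nf), rep("chrB", nf),
                  rep("chrA", sum(is_par)), rep("chrB", sum(is_par))),
        pos = c(pos, pos, par_pos[is_par], par_pos[is_par]),
        width = L,
        AS = c(as_a, as_b,
               as_a[is_par] - config$paralog_penalty,
               as_b[is_par] - config$paralog_penalty),
        NH = c(nh, nh, nh[is_par], nh[is_par]),
        secondary = c(rep(FALSE, nf), rep(TRUE, nf),
                      rep(TRUE, 2L * sum(is_par))),
        stringsAsFactors = FALSE)
    }
    rec <- rec[order(rec$fragment_id, rec$genome, rec$pos), ]
    rownames(rec) <- NULL
    rec_list[[s]] <- rec
    truth_list[[s]] <- data.frame(
      fragment_id = fid, sample = smp,
      gene = pair$gene_ids[g],
      origin = ifelse(from_b, "B", "A"),
      chrom_pos = pos, gene_start_offset = start,
      n_div_covered = n_div, n_errors = n_err,
      seq = if (config$emit_sequences) reads else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- list(records = do.call(rbind, rec_list),
              truth = do.call(rbind, truth_list),
              config = config)
  class(out) <- "alignment_sim"
  out
}

#' Simulate a qPCR Ct table from latent expression
#'
#' Ct follows `Ct = ct_intercept - log2(expression) + N(0, sigma)` per
#' technical replicate, computed from latent per-sample expression means
#' (so that at `sigma = 0` planted fold changes are recovered exactly;
#' depth differences between samples are what the reference-gene
#' normalization removes downstream). Zero-expression cells are capped at
#' `ct_max` and flagged, not dropped.
#'
#' @param config A [sim_config()].
#' @param expr Gene x sample matrix of latent expression means (e.g. the
#'   `mu` component of [simulate_counts()]), or a `sim_counts` object.
#' @param targets Character vector of target gene ids (row names of `expr`).
#' @param reference_gene Reference (actin-like) gene id; must have nonzero
#'   expression in every sample.
#' @param design data.frame mapping `sample` to `genotype`, `condition`,
#'   `replicate`; defaults to the design stored in `expr` when available.
#' @param sigma Technical SD in cycles (default `config$ct_sigma`).
#' @param n_technical Technical replicates per biological replicate.
#' @return A long `qpcr_table` data.frame: genotype, condition,
#'   biological_replicate, gene, technical_replicate, ct, capped.
#' @export
simulate_ct_table <- function(config, expr, targets, reference_gene,
                              design = NULL, sigma = config$ct_sigma,
                              n_technical = 3L) {
  if (inherits(expr, "sim_counts")) {
    design <- design %||% expr$design
    expr <- expr$mu
  }
  assert_that(!is.null(design), "design is required")
  genes <- unique(c(targets, reference_gene))
  assert_that(all(genes %in% rownames(expr)),
              "all target/reference genes must be rows of expr")
  assert_that(all(expr[reference_gene, ] > 0),
              "reference gene must have nonzero expression in all samples")
  set.seed(stage_seed(config$seed, 53L))
  grid <- expand.grid(tech = seq_len(n_technical), gene = genes,
                      sample = design$sample, stringsAsFactors = FALSE)
  e <- expr[cbind(match(grid$gene, rownames(expr)),
                  match(grid$sample, colnames(expr)))]
  capped <- e <= 0
  ct0 <- ifelse(capped, config$ct_max, config$ct_intercept - log2(e))
  ct <- ct0 + if (sigma > 0) rnorm(nrow(grid), sd = sigma) else 0
  ct <- pmin(ct, config$ct_max)
  di <- match(grid$sample, design$sample)
  out <- data.frame(
    genotype = design$genotype[di] %||% "NA",
    condition = design$condition[di],
    biological_replicate = design$replicate[di] %||% di,
    gene = grid$gene,
    technical_replicate = grid$tech,
    ct = ct, capped = capped,
    stringsAsFactors = FALSE)
  class(out) <- c("qpcr_table", "data.frame")
  out
}

#' Simulate pathway annotations for both species
#'
#' A fraction of each genome's genes is annotated to 1-3 of a shared set of
#' pathway ids (pathway names are identical across species, gene ids are
#' not: they carry the `_A`/`_B` species suffix, mirroring the disjoint id
#' namespaces of real annotation files).
#'
#' @param config A [sim_config()].
#' @param n_pathways Number of shared pathways.
#' @param annotated_fraction Fraction of genes with at least one pathway.
#' @return data.frame with `gene_id`, `pathway_id`, `pathway_name`,
#'   `species` (`"A"`/`"B"`).
#' @export
simulate_pathway_annotation <- function(config, n_pathways = 30L,
                                        annotated_fraction = 0.35) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, 71L))
  ids <- gene_ids(config)
  one_species <- function(tag) {
    ann <- sort(sample.int(config$n_genes,
                           round(annotated_fraction * config$n_genes)))
    k <- sample.int(3L, length(ann), replace = TRUE)
    gene <- rep(ids[ann], k)
    pw <- unlist(lapply(k, function(m) sample.int(n_pathways, m)))
    data.frame(gene_id = paste0(gene, "_", tag),
               pathway_id = sprintf("pw%02d", pw),
               pathway_name = sprintf("pathway %02d", pw),
               species = tag, stringsAsFactors = FALSE)
  }
  out <- rbind(one_species("A"), one_species("B"))
  out[order(out$species, out$pathway_id, out$gene_id), ]
}

#' Contiguous introgression interval
#'
#' Gene indices of a single contiguous introgressed segment, sized as a
#' fraction of the genome (at least 5 genes) and anchored at a fractional
#' position — one homozygous wild-species block per line, as in real
#' introgression-line populations.
#'
#' @param config A [sim_config()].
#' @param at_fraction Fractional position of the segment start.
#' @param size_fraction Fraction of genes in the segment.
#' @return Integer vector of gene indices.
#' @export
il_interval <- function(config, at_fraction, size_fraction = 0.08) {
  size <- max(5L, round(size_fraction * config$n_genes))
  start <- min(floor(at_fraction * config$n_genes) + 1L,
               config$n_genes - size + 1L)
  seq.int(start, start + size - 1L)
}

#' Simulate the complete introgression-line study
#'
#' Three genotypes (a pure recurrent-parent hybrid plus two introgression
#' lines, each carrying one contiguous genome-B interval) x two conditions x
#' `n_replicates`, with a shared genome pair, per-genotype NB counts and
#' alignment bundles, pathway annotations, and a qPCR panel (DE and non-DE
#' targets plus a stable reference gene playing the actin role).
#'
#' @param config A [sim_config()].
#' @param genotypes Named list of genotype definitions, each a list with
#'   `introgressed` (gene indices) and `pure` (single-genome alignment).
#' @param n_panel_de,n_panel_null Number of DE / non-DE qPCR target genes.
#' @return A `sim_study` list: `pair`, per-genotype `counts` and `bundles`,
#'   `design` (all samples), `annotation`, `ct_table`, `panel`.
#' @export
simulate_study <- function(config,
                           genotypes = list(
                             Formula = list(introgressed = integer(0), pure = TRUE),
                             IL62 = list(introgressed = il_interval(config, 0.10),
                                         pure = FALSE),
                             IL63 = list(introgressed = il_interval(config, 0.40),
                                         pure = FALSE)),
                           n_panel_de = 9L, n_panel_null = 5L) {
  validate_sim_config(config)
  pair <- make_genome_pair(config)
  counts <- list(); bundles <- list(); designs <- list()
  for (k in seq_along(genotypes)) {
    gname <- names(genotypes)[k]
    cfg_k <- config
    cfg_k$seed <- config$seed + 97L * k
    des <- make_design(config, gname)
    sim <- simulate_counts(cfg_k, des)
    counts[[gname]] <- sim
    bundles[[gname]] <- simulate_alignment_bundles(
      cfg_k, pair, sim,
      introgressed = genotypes[[gname]]$introgressed,
      pure_species = isTRUE(genotypes[[gname]]$pure))
    designs[[gname]] <- des
  }
  design <- do.call(rbind, designs)
  rownames(design) <- NULL
  annotation <- simulate_pathway_annotation(config)
  ## qPCR panel: pick targets from the last genotype's truth (the line with
  ## the strongest validated response), reference = a high-abundance gene
  ## that is non-DE in every genotype
  truths <- lapply(counts, `[[`, "gene_truth")
  de_any <- Reduce(`|`, lapply(truths, `[[`, "de"))
  last_truth <- truths[[length(truths)]]
  de_pool <- which(last_truth$de)
  null_pool <- which(!de_any)
  set.seed(stage_seed(config$seed, 89L))
  panel_genes <- c(
    sample(de_pool, min(n_panel_de, length(de_pool))),
    sample(null_pool, min(n_panel_null, max(0, length(null_pool) - 1L))))
  ref_candidates <- setdiff(null_pool, panel_genes)
  ref <- ref_candidates[which.max(last_truth$weight[ref_candidates])]
  ids <- gene_ids(config)
  ct_list <- lapply(names(genotypes), function(gname) {
    simulate_ct_table(counts[[gname]]$config, counts[[gname]],
                      targets = ids[panel_genes], reference_gene = ids[ref])
  })
  ct_table <- do.call(rbind, ct_list)
  panel <- data.frame(
    gene = ids[c(panel_genes, ref)],
    role = c(rep("target", length(panel_genes)), "reference"),
    de_planted = c(last_truth$de[panel_genes], FALSE),
    stringsAsFactors = FALSE)
  out <- list(config = config, pair = pair, genotypes = genotypes,
              design = design, counts = counts, bundles = bundles,
              annotation = annotation, ct_table = ct_table, panel = panel)
  class(out) <- "sim_study"
  out
}
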