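## End-to-end orchestration of the synthetic study: generation ->
## partitioning -> quantification -> differential expression -> enrichment
## -> qPCR -> report tables.

#' Run the full study pipeline on synthetic data
#'
#' Chains all seven stages: the study generator, per-sample partitioning of
#' alignment bundles (single-genome mode for the pure genotype, dual mode
#' for the introgression lines), EM quantification of each subset (AMBI
#' merged into PENN by the chosen policy), the five pair-wise DE contrasts
#' (pure genotype vs genome A; each IL vs both genomes), both enrichment
#' approaches with the pathway-overlap summary per IL, the qPCR panel, and
#' the figure tables.
#'
#' @param config A [sim_config()].
#' @param study Optionally a pre-built [simulate_study()] result.
#' @param ambi_policy `"sum"` (default: ambiguous fragments counted into
#'   the wild-species matrix) or `"separate"` (kept apart and ignored by
#'   DE).
#' @param fdr DEG significance threshold.
#' @return An `ilseq_run` list: `study`, `partition` (per-sample
#'   summaries), `counts` (per-contrast matrices), `de` (tables + DEG
#'   summary), `enrichment` (per IL: separate A/B, merged, overlap),
#'   `qpcr` (collapsed table + panel), `report` (volcano classes, heatmap
#'   matrices, DEG bars).
#' @export
run_study <- function(config, study = NULL, ambi_policy = c("sum", "separate"),
                      fdr = 0.05) {
  ambi_policy <- match.arg(ambi_policy)
  study <- study %||% simulate_study(config)
  models_a <- gene_models(study$pair, "A")
  models_b <- gene_models(study$pair, "B")

  ## --- partition + quantify per genotype --------------------------------
  part_summaries <- list()
  counts <- list()
  groups <- list()
  for (gname in names(study$bundles)) {
    pure <- isTRUE(study$genotypes[[gname]]$pure)
    recs <- study$bundles[[gname]]$records
    des <- study$counts[[gname]]$design
    slyc <- list(); penn <- list(); ambi <- list()
    for (smp in des$sample) {
      res <- partition_alignments(recs[recs$sample == smp, , drop = FALSE],
                                  mode = if (pure) "single" else "dual")
      part_summaries[[smp]] <- res$summary
      slyc[[smp]] <- res$subsets$slyc
      penn[[smp]] <- res$subsets$penn
      ambi[[smp]] <- res$subsets$ambi
    }
    bindr <- function(l) do.call(rbind, l)
    q_slyc <- quantify_samples(bindr(slyc), models_a, samples = des$sample)
    grp <- factor(des$condition, levels = c("control", "parasitized"))
    counts[[paste0(gname, "_lyc")]] <- q_slyc$counts
    groups[[paste0(gname, "_lyc")]] <- grp
    if (!pure) {
      q_penn <- quantify_samples(bindr(penn), models_b, samples = des$sample)
      q_ambi <- quantify_samples(bindr(ambi), models_b, samples = des$sample)
      merged <- merge_subset_counts(q_penn$counts, q_ambi$counts,
                                    policy = ambi_policy)
      counts[[paste0(gname, "_penn")]] <-
        if (ambi_policy == "sum") merged else merged$penn
      groups[[paste0(gname, "_penn")]] <- grp
    }
  }

  ## --- differential expression ------------------------------------------
  de <- run_contrasts(counts, groups, fdr = fdr)

  ## --- enrichment per introgression line --------------------------------
  il_names <- names(Filter(function(g) !isTRUE(g$pure), study$genotypes))
  enrichment <- list()
  for (il in il_names) {
    tabs <- list(A = de$tables[[paste0(il, "_lyc")]],
                 B = de$tables[[paste0(il, "_penn")]])
    sep <- enrich_separate(tabs, study$annotation, fdr = fdr)
    mrg <- enrich_merged(tabs, study$annotation, fdr = fdr)
    enrichment[[il]] <- list(
      separate = sep, merged = mrg,
      overlap = summarize_overlap(sep$A, sep$B))
  }

  ## --- qPCR panel --------------------------------------------------------
  collapsed <- technical_collapse(study$ct_table)
  ref_gene <- study$panel$gene[study$panel$role == "reference"]
  qpcr <- summarize_panel(collapsed, ref_gene,
                          targets = study$panel$gene[study$panel$role == "target"])

  ## --- report tables -----------------------------------------------------
  report <- list(
    deg_bars = deg_count_bars(de$tables, alpha = fdr),
    volcano = lapply(de$tables, volcano_classify),
    heatmaps = lapply(names(de$tables), function(nm) {
      tab <- de$tables[[nm]]
      if (!any(tab$fdr < fdr, na.rm = TRUE)) return(NULL)
      mat <- counts[[nm]]
      nf <- tmm_factors(mat[attr(tab, "keep"), , drop = FALSE])
      lcpm <- cpm(mat[attr(tab, "keep"), , drop = FALSE],
                  nf$effective_lib_size, log = TRUE)
      top50_heatmap_matrix(tab, lcpm, groups[[nm]], alpha = fdr)
    }) |> setNames(names(de$tables)))

  out <- list(study = study, partition = part_summaries, counts = counts,
              groups = groups, de = de, enrichment = enrichment,
              qpcr = list(collapsed = collapsed, panel = qpcr,
                          reference_gene = ref_gene),
              report = report, config = config)
  class(out) <- "ilseq_run"
  out
}

#' Median subset fractions across samples of a run
#' @param run An `ilseq_run`.
#' @param dual_only Restrict to dual-mode (IL) samples.
#' @return Named numeric: median SLYC/PENN/AMBI fragment fractions.
#' @export
subset_fraction_summary <- function(run, dual_only = TRUE) {
  fr <- lapply(run$partition, function(s) {
    f <- unlist(s$fractions)
    f[SUBSET_LEVELS]
  })
  fr <- do.call(rbind, fr)
  fr[is.na(fr)] <- 0
  colnames(fr) <- SUBSET_LEVELS
  if (dual_only) {
    dual <- fr[, "PENN"] + fr[, "AMBI"] > 0
    if (any(dual)) fr <- fr[dual, , drop = FALSE]
  }
  apply(fr, 2, median)
}
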