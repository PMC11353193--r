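## Deterministic figure tables (and ggplot renderings) for the study's
## standard visualizations: volcano classification, top-DEG heatmap
## matrices, DEG count bars, enrichment top-N bars. Tests assert on the
## tables; the plots are thin wrappers with no randomness.

#' Volcano classification of DE results
#'
#' `up` iff `log2FC > lfc_threshold` and `FDR < alpha`; `down` for the
#' mirrored rule; `ns` otherwise (strict inequalities). The thresholds are
#' display thresholds, not the DEG significance rule.
#'
#' @param de A `de_result` data.frame.
#' @param lfc_threshold Absolute log2 fold-change display threshold.
#' @param alpha Adjusted-p threshold.
#' @return Factor of classes `up`/`down`/`ns`, one per gene.
#' @export
volcano_classify <- function(de, lfc_threshold = 0.6, alpha = 0.05) {
  assert_that(lfc_threshold > 0 && alpha > 0, "thresholds must be > 0")
  sig <- !is.na(de$fdr) & de$fdr < alpha
  cls <- ifelse(sig & de$log2fc > lfc_threshold, "up",
         ifelse(sig & de$log2fc < -lfc_threshold, "down", "ns"))
  factor(cls, levels = c("up", "down", "ns"))
}

#' Z-scored expression matrix of the top DEGs
#'
#' Selects the top `n` genes by ascending FDR (ties: ascending raw p, then
#' gene id), z-scores each gene's log2 CPM row (constant rows become
#' zeros), and orders columns controls first.
#'
#' @param de A `de_result`.
#' @param log_cpm Normalized log2 CPM matrix (genes x samples) covering the
#'   DE genes.
#' @param group Factor per sample (`control`/`parasitized`).
#' @param n Number of genes (default 50).
#' @param alpha FDR threshold defining the DEG pool.
#' @return list with `matrix` (z-scored, genes x samples), `genes`, and
#'   `n_available` (DEGs found; fewer than `n` is recorded, not an error).
#' @export
top50_heatmap_matrix <- function(de, log_cpm, group, n = 50L, alpha = 0.05) {
  assert_that(n >= 1, "n must be >= 1")
  sig <- de[!is.na(de$fdr) & de$fdr < alpha, ]
  assert_that(nrow(sig) >= 1, "no significant genes to draw")
  ord <- order(sig$fdr, sig$p_value, sig$gene_id)
  genes <- head(sig$gene_id[ord], n)
  m <- log_cpm[genes, , drop = FALSE]
  z <- t(apply(m, 1, function(x) {
    s <- sd(x)
    if (s < 1e-12) rep(0, length(x)) else (x - mean(x)) / s
  }))
  dimnames(z) <- dimnames(m)
  col_ord <- order(group != "control")
  z <- z[, col_ord, drop = FALSE]
  list(matrix = z, genes = genes, n_available = nrow(sig))
}

#' DEG counts per contrast, split by direction
#'
#' @param de_tables Named list of `de_result` tables (one per contrast).
#' @param alpha FDR threshold.
#' @return data.frame `contrast`, `up`, `down`, `total`.
#' @export
deg_count_bars <- function(de_tables, alpha = 0.05) {
  do.call(rbind, lapply(names(de_tables), function(nm) {
    de <- de_tables[[nm]]
    sig <- !is.na(de$fdr) & de$fdr < alpha
    data.frame(contrast = nm,
               up = sum(sig & de$log2fc > 0),
               down = sum(sig & de$log2fc < 0),
               total = sum(sig),
               stringsAsFactors = FALSE)
  }))
}

#' Volcano plot
#' @inheritParams volcano_classify
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, lfc_threshold = 0.6, alpha = 0.05) {
  df <- data.frame(log2fc = de$log2fc,
                   neglog10p = -log10(pmax(de$fdr, 1e-300)),
                   class = volcano_classify(de, lfc_threshold, alpha))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neglog10p,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "steelblue", ns = "grey70")) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold),
                        linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_bw()
}

#' DEG count bar plot
#' @param bars Output of [deg_count_bars()].
#' @return A ggplot object.
#' @export
plot_deg_counts <- function(bars) {
  long <- rbind(
    data.frame(contrast = bars$contrast, direction = "up", count = bars$up),
    data.frame(contrast = bars$contrast, direction = "down", count = bars$down))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$contrast, y = .data$count,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(up = "firebrick", down = "steelblue")) +
    ggplot2::labs(x = NULL, y = "significant DEGs (FDR < 0.05)") +
    ggplot2::theme_bw()
}

#' Heatmap of a z-scored top-DEG matrix
#' @param hm Output of [top50_heatmap_matrix()].
#' @return A ggplot object (tile heatmap).
#' @export
plot_top_heatmap <- function(hm) {
  z <- hm$matrix
  df <- data.frame(gene = factor(rep(rownames(z), ncol(z)),
                                 levels = rev(rownames(z))),
                   sample = factor(rep(colnames(z), each = nrow(z)),
                                   levels = colnames(z)),
                   z = as.vector(z))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$gene,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Top enriched pathways bar plot
#' @param result An `enrichment_result`.
#' @param top_n Pathways shown.
#' @return A ggplot object.
#' @export
plot_enrichment_top <- function(result, top_n = 20L) {
  r <- head(result[order(result$adj_p, result$p_value, result$pathway_id), ],
            top_n)
  r$pathway_name <- factor(r$pathway_name, levels = rev(unique(r$pathway_name)))
  ggplot2::ggplot(r, ggplot2::aes(x = -log10(.data$adj_p),
                                  y = .data$pathway_name)) +
    ggplot2::geom_col(fill = "darkolivegreen4") +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 .data
NULL
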