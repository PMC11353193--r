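## Pathway over-representation of DE gene sets: one-sided hypergeometric
## upper-tail tests against the pathway-annotated universe, BH-adjusted,
## run either separately per species or on merged cross-species gene sets
## (duplicated homologs deliberately retained, since real annotation files
## give the two species disjoint gene-id namespaces).

#' Hypergeometric over-representation test per pathway
#'
#' For each pathway with `K >= 1` members in the universe,
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `N` is the
#' annotated-universe size, `n` the number of DE genes in the universe and
#' `k` the DE genes in the pathway. BH adjustment is applied across the
#' tested pathways.
#'
#' @param de_genes Character vector of DE gene ids.
#' @param universe Character vector of background gene ids; it is
#'   restricted to genes with at least one pathway annotation.
#' @param annotation data.frame with `gene_id`, `pathway_id` and optionally
#'   `pathway_name`.
#' @param approach Tag recorded in the result (e.g. `"separate:A"`).
#' @return An `enrichment_result` data.frame: `pathway_id`, `pathway_name`,
#'   `N`, `K`, `n`, `k`, `p_value`, `adj_p`, `approach`, ordered by
#'   `adj_p`, then `p_value`, then `pathway_id`.
#' @export
hypergeom_enrich <- function(de_genes, universe, annotation,
                             approach = "separate") {
  universe <- unique(universe)
  annotated <- universe[universe %in% annotation$gene_id]
  n_unannotated <- length(universe) - length(annotated)
  de <- unique(de_genes)
  assert_that(all(de %in% universe), "de_genes must be a subset of universe")
  de <- de[de %in% annotated]
  ann <- annotation[annotation$gene_id %in% annotated, , drop = FALSE]
  N <- length(annotated)
  n <- length(de)
  pws <- unique(ann$pathway_id)
  rows <- lapply(pws, function(pw) {
    members <- unique(ann$gene_id[ann$pathway_id == pw])
    K <- length(members)
    if (K == 0) return(NULL)
    k <- sum(de %in% members)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    nm <- if ("pathway_name" %in% names(ann)) {
      ann$pathway_name[match(pw, ann$pathway_id)]
    } else pw
    data.frame(pathway_id = pw, pathway_name = nm, N = N, K = K, n = n,
               k = k, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway_id = character(0), pathway_name = character(0),
                      N = integer(0), K = integer(0), n = integer(0),
                      k = integer(0), p_value = numeric(0))
  }
  out$adj_p <- bh_adjust(out$p_value)
  out$approach <- rep(approach, nrow(out))
  out <- out[order(out$adj_p, out$p_value, out$pathway_id), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "n_unannotated_excluded") <- n_unannotated
  out
}

de_genes_of <- function(de_table, fdr = 0.05) {
  de_table$gene_id[!is.na(de_table$fdr) & de_table$fdr < fdr]
}

#' Separate-species pathway enrichment
#'
#' Independent universes, tests and BH corrections per species; the DE set
#' of each species is taken from its own DE table at `fdr` (both
#' directions pooled).
#'
#' @param de_tables Named list of two `de_result` tables, names `"A"` and
#'   `"B"` (species tags).
#' @param annotation Annotation table with a `species` column.
#' @param fdr DE significance threshold.
#' @return Named list of `enrichment_result` tables per species.
#' @export
enrich_separate <- function(de_tables, annotation, fdr = 0.05) {
  assert_that(all(names(de_tables) %in% unique(annotation$species)),
              "de_tables names must match annotation species tags")
  out <- list()
  for (sp in names(de_tables)) {
    ann <- annotation[annotation$species == sp, , drop = FALSE]
    tab <- de_tables[[sp]]
    universe <- tab$gene_id
    de <- de_genes_of(tab, fdr)
    out[[sp]] <- hypergeom_enrich(de, universe, ann,
                                  approach = paste0("separate:", sp))
  }
  out
}

#' Merged-gene-set pathway enrichment
#'
#' Pathway membership lists of the two species are concatenated without
#' cross-species deduplication (a homologous gene DE in both species counts
#' twice); the universe is the concatenation of both annotated universes,
#' and a single test + BH pass is run. `dedup_by_stem` collapses the
#' simulator's `_A`/`_B` suffixed homologs to their shared stem, an option
#' only meaningful when homolog links are known.
#'
#' @param de_tables Named list of two `de_result` tables (`"A"`, `"B"`).
#' @param annotation Annotation table with a `species` column.
#' @param fdr DE significance threshold.
#' @param dedup_by_stem Collapse cross-species homolog duplicates.
#' @return An `enrichment_result` tagged `"merged"`.
#' @export
enrich_merged <- function(de_tables, annotation, fdr = 0.05,
                          dedup_by_stem = FALSE) {
  universe <- unlist(lapply(de_tables, function(t) t$gene_id), use.names = FALSE)
  de <- unlist(lapply(de_tables, de_genes_of, fdr = fdr), use.names = FALSE)
  ann <- annotation
  if (dedup_by_stem) {
    strip <- function(x) sub("_[AB]$", "", x)
    universe <- unique(strip(universe))
    de <- unique(strip(de))
    ann$gene_id <- strip(ann$gene_id)
    ann <- unique(ann[, c("gene_id", "pathway_id", "pathway_name")])
  }
  res <- hypergeom_enrich(de, universe, ann, approach = "merged")
  attr(res, "dedup_by_stem") <- dedup_by_stem
  res
}

#' Overlap of significant pathways and the top-ranked table
#'
#' @param result_a,result_b Two `enrichment_result` tables (e.g. the two
#'   species of one introgression line).
#' @param alpha Adjusted-p significance threshold.
#' @param top_n Rows of the top table (ranked by adjusted p, ties broken by
#'   raw p then pathway id).
#' @return list with `venn` (`unique_a`, `shared`, `unique_b`),
#'   `significant` (per input), and `top` (named list of top-`top_n`
#'   tables).
#' @export
summarize_overlap <- function(result_a, result_b, alpha = 0.05, top_n = 20L) {
  sig <- function(r) r$pathway_id[!is.na(r$adj_p) & r$adj_p < alpha]
  sa <- sig(result_a); sb <- sig(result_b)
  top <- function(r) {
    r <- r[order(r$adj_p, r$p_value, r$pathway_id), ]
    head(r, top_n)
  }
  list(venn = list(unique_a = length(setdiff(sa, sb)),
                   shared = length(intersect(sa, sb)),
                   unique_b = length(setdiff(sb, sa))),
       significant = list(a = sa, b = sb),
       top = list(a = top(result_a), b = top(result_b)))
}
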