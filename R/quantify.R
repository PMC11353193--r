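## Gene-level quantification of retained alignments: fragments are assigned
## to the genes their alignments overlap, and within-genome multi-mapping is
## resolved by a small EM over gene abundances (expected counts, the
## quantity the differential-expression stage consumes).

#' Assign fragments to candidate genes by coordinate overlap
#'
#' Each retained alignment is intersected with the gene models of its
#' genome; a fragment's candidate set is the union of genes its alignments
#' fall in. Fragments hitting no gene are tallied as unassigned.
#'
#' @param records Retained alignment records (one subset, one sample).
#' @param models Gene model table (`gene_id`, `chrom`, `start`, `end`);
#'   genes must not overlap within a chromosome.
#' @return list with `pairs` (data.frame `fragment_id`, `gene_id`, unique
#'   pairs) and `unassigned` (character vector of fragment ids).
#' @export
assign_fragments <- function(records, models) {
  ## enforce non-overlapping gene models per chromosome
  for (ch in unique(models$chrom)) {
    m <- models[models$chrom == ch, ]
    m <- m[order(m$start), ]
    if (nrow(m) > 1 && any(m$start[-1] <= m$end[-nrow(m)])) {
      stop_ilseq(sprintf("overlapping gene models on %s", ch))
    }
  }
  if (nrow(records) == 0) {
    return(list(pairs = data.frame(fragment_id = character(0),
                                   gene_id = character(0)),
                unassigned = character(0)))
  }
  gene_hit <- rep(NA_character_, nrow(records))
  for (ch in unique(records$chrom)) {
    ri <- which(records$chrom == ch)
    m <- models[models$chrom == ch, ]
    if (nrow(m) == 0) next
    q <- IRanges::IRanges(start = records$pos[ri],
                          width = records$width[ri])
    s <- IRanges::IRanges(start = m$start, end = m$end)
    ov <- IRanges::findOverlaps(q, s, select = "first")
    gene_hit[ri] <- ifelse(is.na(ov), NA_character_, m$gene_id[ov])
  }
  hit <- !is.na(gene_hit)
  pairs <- unique(data.frame(fragment_id = records$fragment_id[hit],
                             gene_id = gene_hit[hit],
                             stringsAsFactors = FALSE))
  unassigned <- setdiff(unique(records$fragment_id), pairs$fragment_id)
  list(pairs = pairs, unassigned = unassigned)
}

#' Expected counts by EM over fragment-to-gene assignments
#'
#' Gene abundances `theta` start uniform over genes with at least one
#' candidate fragment; the E-step distributes each fragment over its
#' candidates proportionally to `theta`, the M-step re-estimates `theta`
#' from the fractional weights. Iteration stops when
#' `max|delta theta| < 1e-8` or after 200 iterations. The observed-data
#' log-likelihood is asserted non-decreasing at every step. Uniquely
#' assigned fragments contribute integer counts exactly.
#'
#' @param pairs data.frame of unique (`fragment_id`, `gene_id`) candidates.
#' @param genes Gene universe for the returned vector (genes without any
#'   candidate fragment get expected count 0).
#' @param tol,max_iter Convergence controls.
#' @return Named numeric vector of expected counts over `genes`, with
#'   attributes `iterations` and `loglik` (per-iteration trace).
#' @export
em_expected_counts <- function(pairs, genes, tol = 1e-8, max_iter = 200L) {
  out <- setNames(numeric(length(genes)), genes)
  if (nrow(pairs) == 0) {
    attr(out, "iterations") <- 0L
    attr(out, "loglik") <- numeric(0)
    return(out)
  }
  assert_that(all(pairs$gene_id %in% genes),
              "pairs contain genes outside the gene universe")
  fid <- factor(pairs$fragment_id)
  gid <- factor(pairs$gene_id)
  fi <- as.integer(fid); gi <- as.integer(gid)
  ng <- nlevels(gid)
  theta <- rep(1 / ng, ng)
  ll_trace <- numeric(0)
  iters <- 0L
  repeat {
    iters <- iters + 1L
    tw <- theta[gi]
    denom <- rowsum(tw, fi)[, 1]            # per-fragment normalizer
    ll <- sum(log(denom))
    if (length(ll_trace)) {
      stopifnot(ll >= ll_trace[length(ll_trace)] - 1e-8)
    }
    ll_trace <- c(ll_trace, ll)
    w <- tw / denom[fi]
    cnt <- rowsum(w, gi)[, 1]
    theta_new <- cnt / sum(cnt)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol || iters >= max_iter) break
  }
  tw <- theta[gi]
  w <- tw / rowsum(tw, fi)[fi, 1]
  cnt <- rowsum(w, gi)[, 1]
  out[levels(gid)] <- cnt
  attr(out, "iterations") <- iters
  attr(out, "loglik") <- ll_trace
  out
}

#' Quantify one subset of one sample
#'
#' @inheritParams assign_fragments
#' @param genes Gene universe (defaults to `models$gene_id`).
#' @return list with `counts` (named expected counts), `n_fragments`
#'   (quantified), `n_unassigned`.
#' @export
quantify_subset <- function(records, models, genes = models$gene_id) {
  asg <- assign_fragments(records, models)
  counts <- em_expected_counts(asg$pairs, genes)
  list(counts = counts,
       n_fragments = length(unique(asg$pairs$fragment_id)),
       n_unassigned = length(asg$unassigned))
}

#' Quantify a multi-sample record table into a count matrix
#'
#' @param records Retained records carrying a `sample` column.
#' @param models Gene model table of the records' genome.
#' @param samples Column order (defaults to order of appearance).
#' @return list with `counts` (gene x sample matrix of expected counts) and
#'   `unassigned` (per-sample tally).
#' @export
quantify_samples <- function(records, models,
                             samples = unique(records$sample)) {
  genes <- models$gene_id
  mat <- matrix(0, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  unas <- setNames(integer(length(samples)), samples)
  for (smp in samples) {
    q <- quantify_subset(records[records$sample == smp, , drop = FALSE],
                         models, genes)
    mat[, smp] <- q$counts
    unas[smp] <- q$n_unassigned
  }
  list(counts = mat, unassigned = unas)
}

#' Combine PENN and AMBI expected counts
#'
#' Both subsets are quantified against the genome-B gene models; the
#' default policy adds the ambiguous fragments' expected counts into the
#' wild-species matrix, `"separate"` keeps the two matrices apart.
#'
#' @param counts_penn,counts_ambi Gene x sample expected-count matrices on
#'   the same gene universe and samples.
#' @param policy `"sum"` or `"separate"`.
#' @return A single matrix (`"sum"`) or a list of the two unchanged
#'   matrices (`"separate"`).
#' @export
merge_subset_counts <- function(counts_penn, counts_ambi,
                                policy = c("sum", "separate")) {
  policy <- match.arg(policy)
  assert_that(identical(dimnames(counts_penn), dimnames(counts_ambi)),
              "PENN and AMBI matrices must share genes and samples")
  if (policy == "sum") counts_penn + counts_ambi
  else list(penn = counts_penn, ambi = counts_ambi)
}
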