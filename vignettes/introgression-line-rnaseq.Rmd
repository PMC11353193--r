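---
title: "Dual-genome RNA-seq analysis for introgression lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-genome RNA-seq analysis for introgression lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilseq)
```

## The problem

An introgression line (IL) is a cultivar carrying one homozygous
chromosomal segment from a wild relative in an otherwise recurrent-parent
genome. Bulk RNA-seq of such material mixes transcripts from two genomes:
most reads come from the recurrent parent (here, the *S. lycopersicum*
role, "genome A"), while reads from the introgressed interval match the
wild donor (*S. pennellii*, "genome B") better. Quantifying expression
against a single reference mis-maps the introgressed fraction; quantifying
against both genomes jointly requires deciding, per sequenced fragment,
which genome it came from.

`ilseq` implements the competitive-alignment answer: every fragment is
aligned against a combined two-genome reference, and its bundle of
candidate alignments is assigned to one of three subsets by comparing the
best alignment score (SAM `AS` tag) reached in each genome:

* **SLYC** — alignments only in genome A, or a strictly higher best score
  in A;
* **PENN** — the symmetric rule for genome B;
* **AMBI** — alignments in both genomes with tied best scores.

Genome-B entries are the ones retained for AMBI fragments, so ambiguous
mass is carried on the wild-species side rather than discarded. The three
subsets are quantified separately and analysed as separate expression
spaces: each IL yields two differential-expression contrasts (its genes in
genome A and its genes in genome B), the pure recurrent genotype one.

## Module overview

1. **syndata** — seeded generator for every input the pipeline consumes.
2. **partition** — `classify_alignments()` / `partition_alignments()` /
   `partition_sam()`.
3. **quantify** — coordinate-overlap assignment plus a gene-level EM for
   within-genome multi-mapping (`em_expected_counts()`).
4. **diffexpr** — abundance filter, TMM factors, Cox–Reid dispersion
   estimation, quasi-likelihood F-test, BH adjustment.
5. **enrichment** — hypergeometric over-representation, separate-species
   and merged-gene-set modes.
6. **qpcr** — 2^-ΔΔCt relative expression with reference-gene
   normalization.
7. **report** — deterministic figure tables (volcano classes, top-DEG
   heatmap matrices, DEG bars, enrichment top-N) and ggplot wrappers.

`run_study()` chains all seven on a synthetic study; the exported
functions are the interface for real data (SAM/BAM in, TSV out).

## The synthetic-data generator

The generator emulates the structure of a three-genotype greenhouse study:
a pure recurrent-parent hybrid plus two ILs, each sampled under control
and parasitized conditions with three biological replicates.

* **Genome pair.** Genome A is random sequence organized as one
  chromosome of `n_genes` unspliced gene-level transcripts (default 500 ×
  1 kb) separated by 200-bp spacers; genome B is identical except at
  divergent sites drawn per-bp at `divergence_rate` (default 0.02, the
  order of divergence between a tomato cultivar and its wild relative).
  The two chromosomes are colinear, so homologous alignments share
  coordinates; real genomes of course do not have this property, but the
  partitioning logic never uses it — it sees only scores.
* **Counts.** Negative-binomial with dispersion `nb_dispersion` (default
  0.1, a typical biological-replicate value) around Gamma-distributed
  gene abundances. A fraction `de_fraction` (default 0.1) of genes gets a
  planted effect of `de_log2fc` (default 2), applied as symmetric
  half-effects `2^(±1)` in the two conditions so the condition-mean ratio
  is exactly `2^±2`; the remaining genes are rescaled per condition so
  every sample's expected depth equals `library_size_mean` exactly. The
  non-DE genes thereby absorb a small (≈1–2 %) compensating fold change —
  recorded in the truth table, exactly zero when `de_fraction = 0`. This
  is the compositional compromise that lets planted ratios and expected
  library sizes both be exact.
* **Alignment bundles.** Each counted fragment is drawn uniformly from
  its origin gene's allele (genome B for introgressed genes of an IL),
  sequencing errors are applied at `error_rate`, and candidate alignments
  to the homologous gene in both genomes are emitted with
  `AS = matches − 2·mismatches` (the penalty is configurable) and `NH` =
  bundle size. Fragments are single-end 150 nt; a paired protocol changes
  only the score bookkeeping, not the per-fragment decision, so pairing
  is not modelled. Optional cross-gene multi-mapping
  (`paralog_fraction`) adds a second candidate gene so the EM has work to
  do. Indels, splice junctions, GC/positional bias and base-quality
  modelling are out of scope.
* **Ct tables.** `Ct = ct_intercept − log2(expression) + N(0, σ)` with
  three technical replicates, computed from the *latent* expression means
  rather than the noisy counts, so that at `σ = 0` planted folds round-trip
  exactly through the ΔΔCt arithmetic (halving expression raises Ct by
  exactly one cycle). Zero-expression cells are capped at `ct_max` and
  flagged. The default σ of 0.2 cycles is a typical technical SD for
  SYBR-green reactions.

Library sizes default to 2 × 10⁴ fragments per sample — enough for every
partition and quantification property to be measured at tight tolerance
while the whole 18-sample study (≈360 k fragments, ≈720 k candidate
alignments) runs in well under a minute. Calibration simulations for the
DE machinery use 2000 genes at 10⁶ fragments (≈500 per gene), a realistic
bulk depth for a panel of that size. What passing these tests does *not*
show: robustness to splice variation, indel divergence, annotation errors
or reference bias in real alignments — the generator's reads always come
from annotated, colinear, unspliced genes.

## Partitioning rules and numerical choices

Classification compares only integer `AS` values, so there is no epsilon
logic anywhere; ties are exact. Ties *within* one genome (several
equal-best loci in A) do not affect the label — all retained records pass
to quantification, where the EM resolves them. Secondary alignments
(flag 256) participate in bundles; supplementary/chimeric records
(flag 2048) are dropped and counted. A missing `NH` tag is tolerated (the
bundle size substitutes); a missing `AS` is fatal with the fragment named,
because `AS` is the decision variable and defaulting it would silently
corrupt the partition. For pure-species libraries aligned against a single
genome, `mode = "single"` sends every fragment to SLYC.

## Quantification

Retained alignments are intersected with the gene models of their genome
(genes must be non-overlapping; the generator guarantees it, violations
are an error). The EM starts from uniform abundances over genes with at
least one candidate fragment, distributes each fragment proportionally to
current abundances, and stops at `max|Δθ| < 1e-8` or 200 iterations; the
observed-data log-likelihood is asserted non-decreasing at every step, so
a broken update cannot pass silently. Uniquely assigned fragments are
reproduced as exact integer counts at any iteration. Expected counts are
*not* rounded before DE, and no effective-length correction is applied —
the DE stage consumes counts, not TPM. Ambiguous-subset counts are summed
into the wild-species matrix by default (`ambi_policy = "sum"`), since
those fragments were retained on the B side; `"separate"` keeps them
apart for sensitivity analyses.

## Differential expression

The filter keeps a gene iff its CPM reaches `10 / (median library size in
millions)` in at least as many samples as the smallest group and its
total count is at least 15 — a deterministic, testable restatement of the
usual default expression filter.

TMM normalization follows the published formula exactly: reference sample
by 75th-percentile closest to the mean, per-gene log-ratios M and
abundances A over genes positive in both libraries, rank-based trimming
of 30 % (M) and 5 % (A) on each side, inverse asymptotic binomial
variance weights, factors rescaled to geometric mean 1. Exactly scaled
libraries give unit factors via an explicit `|M| < 1e-6` short-circuit.

Dispersion estimation maximizes the Cox–Reid adjusted NB profile
likelihood: the common value by 1-D search on log φ ∈ [log 10⁻⁴, log 10],
per-gene values by weighted likelihood — `APL_g(φ)` plus
`(prior_df / residual_df)` times the mean APL across genes — on a
61-point log-φ grid with quadratic interpolation at the maximum. The
prior weight corresponds to 10 prior degrees of freedom; at 4 residual df
this pulls individual genes strongly toward the common trend, which is
what makes 3 v 3 designs workable. If the common-dispersion search fails,
a method-of-moments fallback is used with a warning.

The QL F-test fits per-gene NB log-linear models with
log-effective-library-size offsets under the null (one mean) and full
(group means) models. Because the design is one-way, each fit reduces to
Newton iterations on scalar group log-means, vectorized across genes
(steps clamped to ±5, coefficients to ±50; a gene that fails to converge
is reported with p = 1 and flagged rather than dropped). The raw
quasi-dispersion `s² = residual deviance / residual df` is squeezed by
moment matching on `log s²` toward a scaled inverse-χ² prior; when the
observed spread does not exceed pure sampling noise the prior df estimate
is infinite, and the squeeze formula's limit — every gene at the pooled
value — is used. `F = (dev_null − dev_full) / s²_post` is referred to
`F(1, d0 + df_res)`. Deviances use the continuous NB form, valid for the
EM's non-integer expected counts. Calibration is enforced by property:
under a null simulation the raw-p rate at 0.05 and the KS distance to
uniformity are tested, rather than matching any other tool bit-for-bit.
Dispersions are estimated per contrast — in this design every contrast is
its own small experiment.

## Enrichment

One-sided hypergeometric upper-tail tests (over-representation only, no
gene weighting) against a universe restricted to pathway-annotated genes,
BH across tested pathways, significance at adjusted p < 0.05. Two modes
mirror the two defensible treatments of a two-genome gene set: *separate*
(each species its own universe and correction) and *merged*
(concatenated membership lists and universes, no cross-species
deduplication — a homolog DE in both species deliberately counts twice,
reproducing the duplicate-inflation caveat of merging annotations whose
id namespaces cannot be linked). For synthetic data, where homolog links
are known by construction, `dedup_by_stem = TRUE` collapses the `_A`/`_B`
suffixes; it is off by default. The merged universe size double-counts
duplicated members, and the result carries that choice in its metadata.

## qPCR

Technical triplicates are averaged per biological replicate (SD > 0.5
cycles flagged); `ΔCt = Ct_target − Ct_reference` per replicate;
`ΔΔCt = mean(ΔCt_parasitized) − mean(ΔCt_control)`; fold = `2^−ΔΔCt`.
Condition means are compared with a two-sided Welch test on the ΔCt sets
(robust to unequal variances at n = 3); an exact permutation alternative
is available (`test = "permutation"`), enumerating all assignments when
feasible. ΔΔCt uses condition means rather than replicate pairing — the
design has no natural pairing. No amplification-efficiency correction is
applied. At σ = 0.2 the ΔΔCt standard error is ≈ 0.13 cycles, so a
single experiment's fold estimate can stray beyond ±20 % about 5 % of the
time; recovery claims are therefore made about the fold aggregated over
repeated simulations, not about every single draw.

## Report conventions

Volcano classes use strict inequalities: `up` iff log2FC > 0.6 *and*
FDR < 0.05 (mirrored for `down`) — display thresholds, distinct from the
FDR-only DEG rule. Heatmaps take the top 50 DEGs by ascending FDR with
ties broken by raw p then gene id (a deterministic choice where "top"
would otherwise be ambiguous), z-score each gene's log2 CPM row
(constant rows become zeros, not NaN), and order columns controls-first.
All figure tables are byte-deterministic given identical inputs; no stage
after the generator draws random numbers, except the optional sampled
permutation test.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
run <- run_study(cfg)
run$de$summary                     # DEG counts for the five contrasts
subset_fraction_summary(run)       # median SLYC/PENN/AMBI fractions
run$enrichment$IL62$overlap$venn   # pathway overlap between annotations
run$qpcr$panel$fold                # 2^-ddCt fold-change panel
plot_volcano(run$de$tables$IL63_lyc)
```

## Known limitations

* Single-end, unspliced, colinear genomes; no indels or structural
  variation. The partition logic is score-based and independent of these,
  but the generator cannot probe them.
* Two-group, one-way designs only; no batch terms, no multi-factor GLMs.
* Gene-level quantification only; no isoforms, no credibility intervals.
* Enrichment is over-representation only — no ranked-list (GSEA-style)
  statistics, no live annotation-service queries.
* The qPCR module implements plain 2^-ΔΔCt; efficiency-corrected methods
  are out of scope.
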