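## Species-of-origin partitioning: every fragment's alignment bundle
## (candidate alignments against the combined two-genome reference) is
## classified into exactly one of three subsets by comparing the best
## alignment score (AS) reached in each genome:
##   SLYC - alignments only in genome A, or best score strictly higher in A;
##   PENN - the symmetric rule for genome B;
##   AMBI - alignments in both genomes with tied best scores.
## Genome-B entries are the ones retained for AMBI fragments.

SUBSET_LEVELS <- c("SLYC", "PENN", "AMBI")

validate_records <- function(records) {
  assert_that(is.data.frame(records) && nrow(records) > 0,
              "alignment records must be a nonempty data.frame")
  assert_that(all(c("fragment_id", "genome", "AS") %in% names(records)),
              "records need columns fragment_id, genome, AS")
  if (anyNA(records$AS)) {
    bad <- records$fragment_id[which(is.na(records$AS))[1]]
    stop_ilseq(sprintf(
      "missing AS tag for fragment '%s'; AS is the decision variable and cannot be defaulted",
      bad))
  }
  assert_that(all(records$genome %in% c("A", "B")),
              "record genome must be 'A' or 'B'")
  invisible(records)
}

#' Classify all alignment bundles in a record table
#'
#' Vectorized classification of every fragment in `records` by the
#' best-score rule. Secondary alignments participate; within-genome ties do
#' not affect the label.
#'
#' @param records Alignment record data.frame (`fragment_id`, `genome`,
#'   `AS`, ...), covering one or more fragments.
#' @return data.frame with `fragment_id` and `label`
#'   (factor `SLYC`/`PENN`/`AMBI`), one row per fragment, in first-appearance
#'   order.
#' @export
classify_alignments <- function(records) {
  validate_records(records)
  fid <- factor(records$fragment_id, levels = unique(records$fragment_id))
  fi <- as.integer(fid)
  nf <- nlevels(fid)
  is_b <- records$genome == "B"
  best <- function(sel) {
    out <- rep(NA_real_, nf)
    if (any(sel)) {
      m <- tapply(records$AS[sel], fi[sel], max)
      out[as.integer(names(m))] <- m
    }
    out
  }
  best_a <- best(!is_b)
  best_b <- best(is_b)
  label <- ifelse(is.na(best_b), "SLYC",
           ifelse(is.na(best_a), "PENN",
           ifelse(best_a > best_b, "SLYC",
           ifelse(best_b > best_a, "PENN", "AMBI"))))
  data.frame(fragment_id = levels(fid),
             label = factor(label, levels = SUBSET_LEVELS),
             best_a = best_a, best_b = best_b,
             stringsAsFactors = FALSE)
}

#' Classify a single alignment bundle
#'
#' @param bundle data.frame of alignment records sharing one `fragment_id`.
#' @return A single factor label (`SLYC`, `PENN` or `AMBI`).
#' @export
classify_bundle <- function(bundle) {
  assert_that(is.data.frame(bundle) && nrow(bundle) > 0,
              "empty alignment bundle")
  assert_that(length(unique(bundle$fragment_id)) == 1,
              "a bundle must contain records of exactly one fragment")
  classify_alignments(bundle)$label[1]
}

#' Records retained for downstream quantification
#'
#' SLYC keeps the genome-A records; PENN and AMBI keep the genome-B records
#' (ambiguous fragments are carried on the wild-species side).
#'
#' @param bundle data.frame of records for one fragment.
#' @param label The bundle's label from [classify_bundle()].
#' @return The retained subset of `bundle`.
#' @export
select_retained_records <- function(bundle, label) {
  label <- as.character(label)
  assert_that(label %in% SUBSET_LEVELS, "unknown subset label")
  keep_genome <- if (label == "SLYC") "A" else "B"
  bundle[bundle$genome == keep_genome, , drop = FALSE]
}

#' Partition an alignment record table into the three origin subsets
#'
#' @param records Alignment records for one sample.
#' @param mode `"dual"` (combined two-genome alignment) or `"single"` (a
#'   pure-species library aligned against genome A only: every fragment is
#'   SLYC).
#' @return A `partition_result` list: `labels` (per fragment), `subsets`
#'   (named list of retained record tables `slyc`/`penn`/`ambi`) and
#'   `summary` (fragment counts and fractions per subset).
#' @export
partition_alignments <- function(records, mode = c("dual", "single")) {
  mode <- match.arg(mode)
  validate_records(records)
  if (mode == "single") {
    assert_that(all(records$genome == "A"),
                "single mode expects alignments against genome A only")
    labels <- data.frame(
      fragment_id = unique(records$fragment_id),
      label = factor("SLYC", levels = SUBSET_LEVELS),
      stringsAsFactors = FALSE)
    subsets <- list(slyc = records,
                    penn = records[0, , drop = FALSE],
                    ambi = records[0, , drop = FALSE])
  } else {
    labels <- classify_alignments(records)
    lab_of <- labels$label[match(records$fragment_id, labels$fragment_id)]
    keep_a <- records$genome == "A" & lab_of == "SLYC"
    keep_b <- records$genome == "B" & lab_of != "SLYC"
    retained <- records[keep_a | keep_b, , drop = FALSE]
    lab_ret <- labels$label[match(retained$fragment_id, labels$fragment_id)]
    subsets <- list(slyc = retained[lab_ret == "SLYC", , drop = FALSE],
                    penn = retained[lab_ret == "PENN", , drop = FALSE],
                    ambi = retained[lab_ret == "AMBI", , drop = FALSE])
    ## every fragment must retain at least one record
    stopifnot(sum(vapply(subsets, function(x) length(unique(x$fragment_id)),
                         integer(1))) == nrow(labels))
  }
  n <- nrow(labels)
  cnt <- table(labels$label)
  summary <- list(n_fragments = n,
                  counts = as.list(as.integer(cnt)) |> setNames(names(cnt)),
                  fractions = as.list(as.numeric(cnt) / n) |> setNames(names(cnt)))
  out <- list(labels = labels[, c("fragment_id", "label")],
              subsets = subsets, summary = summary, mode = mode)
  class(out) <- "partition_result"
  out
}

#' Partition a SAM/BAM file into three subset SAM files
#'
#' Reads the alignments, classifies every fragment, and writes the retained
#' records of each subset to `<prefix>.slyc.sam`, `<prefix>.penn.sam`,
#' `<prefix>.ambi.sam` (source lines re-emitted verbatim for SAM input)
#' plus a JSON summary `<prefix>.partition.json`.
#'
#' @param path Input SAM (text) or BAM file with `NH:i`/`AS:i` tags.
#' @param mode `"dual"` or `"single"`.
#' @param out_prefix Output path prefix.
#' @param genome_map Reference-name to genome map (see [read_alignments()]).
#' @return Invisibly, the `partition_result`.
#' @export
partition_sam <- function(path, mode = c("dual", "single"), out_prefix,
                          genome_map = c(chrA = "A", chrB = "B")) {
  mode <- match.arg(mode)
  records <- read_alignments(path, genome_map, keep_lines = TRUE)
  lines <- attr(records, "lines")
  hdr <- attr(records, "header")
  res <- partition_alignments(records, mode)
  for (nm in names(res$subsets)) {
    sub <- res$subsets[[nm]]
    out <- paste0(out_prefix, ".", nm, ".sam")
    if (!is.null(lines)) {
      idx <- as.integer(rownames(sub))
      writeLines(c(hdr, lines[idx]), out)
    } else {
      write_sam(sub, header = c("@HD\tVN:1.6",
                                sprintf("@SQ\tSN:%s\tLN:1000000", unique(sub$chrom))),
                path = out)
    }
  }
  jsonlite::write_json(
    list(n_fragments = res$summary$n_fragments,
         fractions = res$summary$fractions),
    paste0(out_prefix, ".partition.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
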