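## Readers/writers for the standard formats the pipeline exchanges:
## FASTA genomes (Biostrings), GTF gene models (1-based inclusive), SAM with
## NH:i / AS:i tags, and plain TSV tables.

#' Write the genome pair as FASTA
#' @param pair A `genome_pair`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_genome_fasta <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(A = file.path(dir, "genome_a.fa"), B = file.path(dir, "genome_b.fa"))
  for (g in c("A", "B")) {
    x <- Biostrings::DNAStringSet(build_chromosome(pair, g))
    names(x) <- pair$chrom[g]
    Biostrings::writeXStringSet(x, paths[g])
  }
  invisible(paths)
}

#' Write gene models of one genome as GTF
#' @inheritParams gene_models
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(pair, genome = c("A", "B"), path) {
  genome <- match.arg(genome)
  gm <- gene_models(pair, genome)
  feats <- c("gene", "exon")
  lines <- unlist(lapply(feats, function(f) {
    sprintf('%s\tilseq\t%s\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s";',
            gm$chrom, f, gm$start, gm$end, gm$gene_id, gm$gene_id)
  }))
  ## interleave so each gene's features are adjacent
  idx <- order(rep(seq_len(nrow(gm)), length(feats)))
  writeLines(lines[idx], path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Uses `rtracklayer` to parse the file and returns the coordinate table
#' the quantifier consumes (one row per `gene` feature).
#'
#' @param path GTF file path.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  assert_that(requireNamespace("rtracklayer", quietly = TRUE),
              "reading GTF requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  gr <- gr[gr$type == "gene", ]
  data.frame(gene_id = gr$gene_id,
             chrom = as.character(gr$seqnames),
             start = gr$start,
             end = gr$end,
             stringsAsFactors = FALSE)
}

sam_header <- function(pair) {
  lens <- (length(pair$gene_ids) + 1L) * pair$config$spacer_length +
    length(pair$gene_ids) * pair$gene_length
  c("@HD\tVN:1.6\tSO:queryname",
    sprintf("@SQ\tSN:%s\tLN:%d", pair$chrom, c(lens, lens)))
}

#' Write alignment records as SAM
#'
#' Emits a combined header (both genomes' reference sequences) and one line
#' per candidate alignment with `NH:i` and `AS:i` tags. Secondary records
#' get flag 256. Read sequences are taken from the per-fragment truth table
#' when supplied, else `*`.
#'
#' @param records Alignment records (one sample) as produced by
#'   [simulate_alignment_bundles()] or [read_alignments()].
#' @param pair The `genome_pair` (for the header); alternatively a character
#'   vector of pre-built header lines via `header`.
#' @param path Output file.
#' @param truth Optional per-fragment truth table carrying `seq`.
#' @param header Optional explicit header lines (overrides `pair`).
#' @return Invisibly, `path`.
#' @export
write_sam <- function(records, pair = NULL, path, truth = NULL, header = NULL) {
  hdr <- header %||% sam_header(pair)
  seqs <- rep("*", nrow(records))
  if (!is.null(truth) && !all(is.na(truth$seq))) {
    m <- match(records$fragment_id, truth$fragment_id)
    seqs <- ifelse(is.na(m), "*", truth$seq[m])
  }
  cigar <- paste0(records$width, "M")
  flag <- ifelse(records$secondary, 256L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNH:i:%d\tAS:i:%d",
                   records$fragment_id, flag, records$chrom, records$pos,
                   cigar, seqs, records$NH, records$AS)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

cigar_ref_width <- function(cigar) {
  out <- integer(length(cigar))
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  for (i in seq_along(cigar)) {
    m <- regmatches(cigar[i], ops[i])[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", m))
    op <- sub("\\d+", "", m)
    out[i] <- sum(n[op %in% c("M", "D", "N", "=", "X")])
  }
  out
}

parse_sam_tag <- function(fields_list, tag, type = "i") {
  pre <- paste0(tag, ":", type, ":")
  vapply(fields_list, function(f) {
    hit <- f[startsWith(f, pre)]
    if (length(hit)) as.integer(substring(hit[1], nchar(pre) + 1L)) else NA_integer_
  }, integer(1))
}

#' Read alignments from SAM (text) or BAM
#'
#' Returns the flat record table the partitioner consumes. The genome of
#' each record is derived from its reference name through `genome_map`.
#' Supplementary/chimeric records (flag 0x800) are dropped and counted in
#' the `n_supplementary` attribute; unmapped records (flag 0x4) are skipped.
#'
#' @param path SAM or BAM file.
#' @param genome_map Named character vector mapping reference names to
#'   `"A"`/`"B"` (default: the simulator's `chrA`/`chrB`).
#' @param keep_lines Keep the raw source line of each record (SAM input
#'   only; used by [partition_sam()] to re-emit subsets verbatim).
#' @return data.frame of records with attributes `header` (SAM input),
#'   `n_supplementary`, and optionally `lines`.
#' @export
read_alignments <- function(path, genome_map = c(chrA = "A", chrB = "B"),
                            keep_lines = FALSE) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    assert_that(requireNamespace("Rsamtools", quietly = TRUE),
                "reading BAM requires the Rsamtools package")
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar"),
      tag = c("NH", "AS"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    df <- data.frame(fragment_id = b$qname, flag = b$flag,
                     chrom = as.character(b$rname), pos = b$pos,
                     cigar = b$cigar,
                     NH = b$tag$NH %||% NA_integer_,
                     AS = b$tag$AS %||% NA_integer_,
                     stringsAsFactors = FALSE)
    hdr <- character(0)
    lines <- NULL
  } else {
    raw <- readLines(path)
    hdr <- raw[startsWith(raw, "@")]
    body <- raw[!startsWith(raw, "@") & nzchar(raw)]
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 11L)
    if (length(bad)) {
      stop_ilseq(sprintf("unparseable SAM record at line %d of %s",
                         length(hdr) + bad[1], path))
    }
    opt <- lapply(fields, function(f) f[-seq_len(11L)])
    df <- data.frame(
      fragment_id = vapply(fields, `[`, "", 1L),
      flag = as.integer(vapply(fields, `[`, "", 2L)),
      chrom = vapply(fields, `[`, "", 3L),
      pos = as.integer(vapply(fields, `[`, "", 4L)),
      cigar = vapply(fields, `[`, "", 6L),
      NH = parse_sam_tag(opt, "NH"),
      AS = parse_sam_tag(opt, "AS"),
      stringsAsFactors = FALSE)
    lines <- body
  }
  mapped <- !bitwAnd(df$flag, 4L)
  supp <- bitwAnd(df$flag, 2048L) > 0
  keep <- mapped & !supp
  n_supp <- sum(supp)
  df <- df[keep, , drop = FALSE]
  if (!is.null(lines)) lines <- lines[keep]
  df$genome <- unname(genome_map[df$chrom])
  if (anyNA(df$genome)) {
    stop_ilseq(sprintf("reference '%s' not present in genome_map",
                       df$chrom[which(is.na(df$genome))[1]]))
  }
  df$width <- cigar_ref_width(df$cigar)
  df$secondary <- bitwAnd(df$flag, 256L) > 0
  out <- df[, c("fragment_id", "genome", "chrom", "pos", "width",
                "AS", "NH", "secondary")]
  rownames(out) <- NULL
  attr(out, "header") <- hdr
  attr(out, "n_supplementary") <- n_supp
  if (keep_lines && !is.null(lines)) attr(out, "lines") <- lines
  out
}

#' Write / read a gene x sample count matrix as TSV
#' @param mat Numeric matrix with gene row names and sample column names.
#' @param path File path.
#' @return Invisibly `path` / the matrix.
#' @export
write_counts_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write the full synthetic study to disk
#'
#' Materializes the generator's outputs in their on-disk formats: FASTA
#' genomes, per-genome GTF, one SAM per sample, count/truth/Ct/annotation
#' TSVs.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(study$pair, dir)
  write_gtf(study$pair, "A", file.path(dir, "genes_a.gtf"))
  write_gtf(study$pair, "B", file.path(dir, "genes_b.gtf"))
  for (gname in names(study$counts)) {
    write_counts_tsv(study$counts[[gname]]$counts,
                     file.path(dir, paste0("true_counts_", gname, ".tsv")))
    write.table(study$counts[[gname]]$gene_truth,
                file.path(dir, paste0("gene_truth_", gname, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    b <- study$bundles[[gname]]
    for (smp in unique(b$records$sample)) {
      write_sam(b$records[b$records$sample == smp, ], study$pair,
                file.path(dir, paste0(smp, ".sam")),
                truth = b$truth[b$truth$sample == smp, ])
    }
  }
  write.table(study$annotation, file.path(dir, "pathways.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$ct_table, file.path(dir, "ct_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$design, file.path(dir, "design.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
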