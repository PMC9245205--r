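# Readers and writers for every external format the pipeline touches.
# All coordinates are 1-based inclusive (GFF3/VCF convention); counts must be
# non-negative integers (the negative-binomial model is defined on integers,
# fractional upstream estimates are rejected rather than silently rounded).

VALID_ROLES <- c("maternal", "paternal", "hybrid")

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `accession`, `role`
#'   (maternal/paternal/hybrid), `tissue`, `replicate`.
#' @return data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read_tsv(path)
  need <- c("sample_id", "accession", "role", "tissue", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) schema_error("sample sheet missing column(s): ",
                                 paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    schema_error("duplicated sample_id in sample sheet")
  if (!all(sheet$role %in% VALID_ROLES))
    schema_error("role must be one of ", paste(VALID_ROLES, collapse = ", "))
  sheet$replicate <- as.integer(sheet$replicate)
  sheet
}

#' Read a counts matrix with its sample sheet
#'
#' The counts TSV has a `gene_id` column followed by one column per sample;
#' header names must match the sheet's `sample_id`s exactly (same set).
#' Entries must be non-negative integers.
#'
#' @param counts_path path to counts TSV.
#' @param sheet_path path to sample sheet TSV.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"` and the sheet as column data.
#' @export
read_counts <- function(counts_path, sheet_path) {
  sheet <- read_sample_sheet(sheet_path)
  tab <- read_tsv(counts_path)
  if (names(tab)[1] != "gene_id")
    schema_error("first column of counts TSV must be gene_id")
  if (anyDuplicated(tab$gene_id)) schema_error("duplicated gene_id in counts")
  samples <- names(tab)[-1]
  if (!setequal(samples, sheet$sample_id))
    schema_error("counts columns and sample sheet disagree: ",
                 paste(union(setdiff(samples, sheet$sample_id),
                             setdiff(sheet$sample_id, samples)),
                       collapse = ", "))
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) schema_error("non-numeric counts")
  if (any(is.na(mat))) schema_error("missing counts")
  if (any(mat < 0)) schema_error("negative counts")
  if (any(mat != round(mat))) schema_error("non-integer counts")
  storage.mode(mat) <- "integer"
  rownames(mat) <- tab$gene_id
  sheet <- sheet[match(samples, sheet$sample_id), ]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    colData = S4Vectors::DataFrame(sheet, row.names = sheet$sample_id))
  se
}

#' Write a counts matrix and its sample sheet
#' @param se SummarizedExperiment with assay `"counts"`.
#' @param counts_path,sheet_path output TSV paths.
#' @export
write_counts <- function(se, counts_path, sheet_path) {
  mat <- SummarizedExperiment::assay(se, "counts")
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write_tsv(df, counts_path)
  write_tsv(as.data.frame(SummarizedExperiment::colData(se)), sheet_path)
  invisible(NULL)
}

#' Read/write gene-level allelic counts
#'
#' Columns: `gene_id`, `tissue`, `replicate`, `maternal_count`,
#' `paternal_count`.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_allelic_counts <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "tissue", "replicate", "maternal_count",
            "paternal_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) schema_error("allelic counts missing column(s): ",
                                 paste(miss, collapse = ", "))
  for (cc in c("maternal_count", "paternal_count")) {
    if (any(df[[cc]] < 0) || any(df[[cc]] != round(df[[cc]])))
      schema_error(cc, " must be non-negative integers")
    df[[cc]] <- as.integer(df[[cc]])
  }
  df$replicate <- as.integer(df$replicate)
  df
}

#' @rdname read_allelic_counts
#' @param allelic data.frame of allelic counts.
#' @export
write_allelic_counts <- function(allelic, path) {
  write_tsv(allelic, path)
  invisible(NULL)
}

# ---- GFF3 ------------------------------------------------------------------

#' Read gene models from a GFF3 file
#'
#' Parses the gene/mRNA/exon/CDS subset via [rtracklayer::import] and
#' assembles a [gene_models] object. Unsorted intervals are sorted with a
#' warning; genes whose CDS length is not a codon multiple are flagged
#' invalid (see [gene_models]).
#'
#' @param path GFF3 file.
#' @return A [gene_models] object.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  typ <- as.character(df$type)
  gid <- function(rows) {
    id <- df$Parent[rows]
    id <- vapply(id, function(p) if (length(p)) as.character(p[1]) else NA_character_,
                 character(1))
    sub("\\.t1$", "", sub("^mRNA:", "", id))
  }
  gene_rows <- which(typ == "gene")
  genes <- data.frame(
    gene_id = as.character(df$ID[gene_rows]),
    chrom = as.character(df$seqnames[gene_rows]),
    strand = as.character(df$strand[gene_rows]),
    start = df$start[gene_rows], end = df$end[gene_rows],
    stringsAsFactors = FALSE)
  ex_rows <- which(typ == "exon")
  exons <- data.frame(gene_id = gid(ex_rows),
                      chrom = as.character(df$seqnames[ex_rows]),
                      start = df$start[ex_rows], end = df$end[ex_rows],
                      stringsAsFactors = FALSE)
  cds_rows <- which(typ == "CDS")
  phase <- df$phase[cds_rows]
  if (is.null(phase)) phase <- rep(0L, length(cds_rows))
  cds <- data.frame(gene_id = gid(cds_rows),
                    chrom = as.character(df$seqnames[cds_rows]),
                    start = df$start[cds_rows], end = df$end[cds_rows],
                    phase = as.integer(phase),
                    stringsAsFactors = FALSE)
  gene_models(genes, exons, cds)
}

#' Write gene models as GFF3
#'
#' Deterministic writer (stable field formatting and feature order) so that
#' identical models yield byte-identical files.
#'
#' @param models a [gene_models] object.
#' @param path output path.
#' @export
write_gff <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- models$genes
  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    ex <- models$exons[models$exons$gene_id == id, , drop = FALSE]
    cd <- models$cds[models$cds$gene_id == id, , drop = FALSE]
    lines <- c(
      sprintf("%s\theteroseq\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], id),
      sprintf("%s\theteroseq\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], id, id),
      sprintf("%s\theteroseq\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
              ex$chrom, ex$start, ex$end, g$strand[i], id),
      sprintf("%s\theteroseq\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s.t1",
              cd$chrom, cd$start, cd$end, g$strand[i], cd$phase, id))
    writeLines(lines, con)
  }
  invisible(NULL)
}

# ---- VCF -------------------------------------------------------------------

VCF_INFO_KEYS <- c("QD", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

#' Read variants from a VCF (v4.2 subset)
#'
#' Parses via [VariantAnnotation::readVcf]; multi-allelic records are split
#' into one row per ALT allele. The INFO metrics used by the hard filters
#' (QD, SOR, FS, MQ, MQRankSum, ReadPosRankSum) are carried as columns, NA
#' when absent.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `qual` and one column per INFO metric.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) schema_error("file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    id = names(rr) %||% rep(".", length(rr)),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    qual = as.numeric(rr$QUAL),
    stringsAsFactors = FALSE)
  for (k in VCF_INFO_KEYS) {
    out[[k]] <- if (k %in% names(info)) as.numeric(info[[k]])
                else rep(NA_real_, nrow(out))
  }
  rownames(out) <- NULL
  if (any(out$pos < 1)) schema_error("VCF position < 1")
  if (any(out$ref == out$alt)) schema_error("REF equal to ALT")
  if (any(!nzchar(out$ref)) || any(!nzchar(out$alt)))
    schema_error("empty REF/ALT allele")
  out
}

#' Write variants as VCF v4.2
#'
#' Deterministic writer for the subset produced by the simulator and read by
#' [read_variants].
#'
#' @param variants data.frame as returned by [read_variants].
#' @param path output path.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Float,",
                   "Description=\"%s\">"),
            VCF_INFO_KEYS,
            c("Quality by depth", "Symmetric odds ratio",
              "Fisher strand bias", "RMS mapping quality",
              "Mapping quality rank sum", "Read position rank sum")),
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))), con)
  ord <- order(variants$chrom, variants$pos)
  v <- variants[ord, , drop = FALSE]
  info <- vapply(seq_len(nrow(v)), function(i) {
    vals <- unlist(v[i, VCF_INFO_KEYS])
    keep <- !is.na(vals)
    if (!any(keep)) return(".")
    paste(sprintf("%s=%s", VCF_INFO_KEYS[keep], fmt_num(vals[keep])),
          collapse = ";")
  }, character(1))
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t%s\t.\t%s",
                     v$chrom, v$pos, v$id, v$ref, v$alt,
                     fmt_num(v$qual), info), con)
  invisible(NULL)
}

# ---- FASTA -----------------------------------------------------------------

#' Read/write a genome as FASTA
#' @param path FASTA path.
#' @return [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_genome
#' @param genome a [Biostrings::DNAStringSet].
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(NULL)
}

# ---- Truth table -----------------------------------------------------------

#' Read/write the synthetic ground-truth table
#'
#' The truth table is written by the simulator and read only by tests and
#' benchmarking code, never by the analysis pipeline itself.
#' @param path TSV path.
#' @export
read_truth <- function(path) read_tsv(path)

#' @rdname read_truth
#' @param truth data.frame.
#' @export
write_truth <- function(truth, path) {
  write_tsv(truth, path)
  invisible(NULL)
}
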