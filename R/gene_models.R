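#' Gene model container
#'
#' A light container for gene structures used by the variant annotator and
#' the allele-specific counting step. Coordinates are 1-based inclusive
#' (the GFF3/VCF convention); exon and CDS intervals are kept sorted by
#' genomic start within each gene. CDS phase follows GFF3: the number of
#' bases to skip from the 5' end (in transcript orientation) of a CDS piece
#' to reach the first complete codon.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end`.
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @param cds data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `phase`.
#'
#' @return An object of class `gene_models`: a list with elements `genes`
#'   (with an added logical `cds_valid` column), `exons` and `cds`.
#'   Genes whose total CDS length (after trimming the leading phase of the
#'   transcript-first piece) is not divisible by 3 are flagged
#'   `cds_valid = FALSE` with a warning and are excluded from coding-effect
#'   calls downstream.
#' @export
gene_models <- function(genes, exons, cds) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) schema_error(what, " missing column(s): ",
                                   paste(miss, collapse = ", "))
  }
  need(genes, c("gene_id", "chrom", "strand", "start", "end"), "genes")
  need(exons, c("gene_id", "chrom", "start", "end"), "exons")
  need(cds, c("gene_id", "chrom", "start", "end", "phase"), "cds")
  for (cc in c("start", "end")) {
    genes[[cc]] <- as.integer(genes[[cc]])
    exons[[cc]] <- as.integer(exons[[cc]])
    cds[[cc]] <- as.integer(cds[[cc]])
  }
  cds$phase <- as.integer(cds$phase)
  if (anyDuplicated(genes$gene_id))
    schema_error("duplicated gene_id in gene models")
  if (!all(genes$strand %in% c("+", "-")))
    schema_error("strand must be '+' or '-'")
  if (any(exons$start > exons$end) || any(cds$start > cds$end))
    schema_error("interval with start > end")
  if (any(exons$start < 1) || any(cds$start < 1))
    schema_error("coordinates are 1-based; start < 1")

  ord <- function(df) df[order(df$gene_id, df$start, df$end), , drop = FALSE]
  sorted_in <- function(df) {
    sp <- split(df$start, df$gene_id)
    !all(vapply(sp, function(s) !is.unsorted(s), logical(1)))
  }
  if (sorted_in(exons) || sorted_in(cds))
    warning("unsorted exon/CDS intervals; sorting on load")
  exons <- ord(exons)
  cds <- ord(cds)

  # non-overlap within gene
  chk_overlap <- function(df, what) {
    bad <- unlist(lapply(split(df, df$gene_id), function(g) {
      if (nrow(g) < 2) return(FALSE)
      any(g$start[-1] <= g$end[-nrow(g)])
    }))
    if (any(bad)) schema_error("overlapping ", what, " intervals within gene ",
                               paste(names(bad)[bad], collapse = ", "))
  }
  chk_overlap(exons, "exon")
  chk_overlap(cds, "CDS")

  # CDS contained in exons
  for (g in unique(cds$gene_id)) {
    cg <- cds[cds$gene_id == g, ]
    eg <- exons[exons$gene_id == g, ]
    inside <- vapply(seq_len(nrow(cg)), function(i) {
      any(eg$start <= cg$start[i] & eg$end >= cg$end[i])
    }, logical(1))
    if (!all(inside)) schema_error("CDS not contained in exons for gene ", g)
  }

  # CDS length divisible by 3 after phase trim of the transcript-first piece
  genes$cds_valid <- vapply(genes$gene_id, function(g) {
    cg <- cds[cds$gene_id == g, ]
    if (nrow(cg) == 0) return(FALSE)
    first_phase <- if (genes$strand[genes$gene_id == g] == "+")
      cg$phase[1] else cg$phase[nrow(cg)]
    tot <- sum(cg$end - cg$start + 1) - first_phase
    tot %% 3 == 0
  }, logical(1))
  if (!all(genes$cds_valid))
    warning("CDS length not divisible by 3 for gene(s): ",
            paste(genes$gene_id[!genes$cds_valid], collapse = ", "),
            "; excluded from coding-effect calls")

  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$cds), "CDS intervals on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

# GRanges views used internally for overlap queries
models_gene_ranges <- function(models, flank = 0L) {
  g <- models$genes
  GenomicRanges::GRanges(g$chrom,
                         IRanges::IRanges(pmax(1L, g$start - flank),
                                          g$end + flank),
                         strand = g$strand, gene_id = g$gene_id)
}

models_exon_ranges <- function(models) {
  e <- models$exons
  GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end),
                         gene_id = e$gene_id)
}
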