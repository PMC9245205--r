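# Variant hard filtering (GATK-style printed thresholds) and a minimal
# consequence/impact annotator against gene models and a genome sequence.

CONSEQUENCE_ORDER <- c("stop_gained", "stop_lost", "start_lost", "frameshift",
                       "splice_acceptor", "splice_donor", "inframe_indel",
                       "missense", "synonymous", "stop_retained", "intron",
                       "utr", "upstream", "downstream", "intergenic")

IMPACT_OF_CONSEQUENCE <- c(
  stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  frameshift = "HIGH", splice_acceptor = "HIGH", splice_donor = "HIGH",
  missense = "MODERATE", inframe_indel = "MODERATE",
  synonymous = "LOW", stop_retained = "LOW",
  intron = "MODIFIER", utr = "MODIFIER", upstream = "MODIFIER",
  downstream = "MODIFIER", intergenic = "MODIFIER")

#' Impact category of a consequence term
#' @param consequence character vector of consequence terms.
#' @return character vector of HIGH/MODERATE/LOW/MODIFIER.
#' @export
impact_of <- function(consequence) {
  out <- IMPACT_OF_CONSEQUENCE[consequence]
  if (any(is.na(out))) schema_error("unknown consequence term: ",
                                    paste(consequence[is.na(out)],
                                          collapse = ", "))
  unname(out)
}

variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snp",
  ifelse(nchar(ref) != nchar(alt), "indel", "complex"))
}

#' Hard-filter variant records
#'
#' Applies the printed thresholds per variant type. SNPs fail on
#' `QUAL < 30`, `QD < 2`, `SOR > 3`, `FS > 60`, `MQ < 40`,
#' `MQRankSum < -12.5` or `ReadPosRankSum < -8`; indels fail on
#' `QUAL < 30`, `QD < 2`, `FS > 200`, `MQ < 40` or
#' `ReadPosRankSum < -20`. The rank-sum thresholds are negative by default
#' (the convention of the variant-calling toolkit these filters come from;
#' positive thresholds would discard nearly all variants); set
#' `rank_sum_sign_fix = FALSE` to apply them as positive values instead.
#' A missing metric skips that criterion. Records whose REF and ALT are both
#' longer than one base with equal lengths are flagged `complex` and passed
#' through with a warning.
#'
#' @param records data.frame as returned by [read_variants].
#' @param rank_sum_sign_fix apply rank-sum thresholds as negative values.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `type`, `passed`
#'   and `failed_criteria` (comma-separated, empty when passed).
#' @export
filter_variants <- function(records, rank_sum_sign_fix = TRUE) {
  type <- variant_type(records$ref, records$alt)
  if (any(type == "complex"))
    warning(sum(type == "complex"),
            " complex record(s) (equal-length multi-base alleles) passed through")
  sgn <- if (rank_sum_sign_fix) -1 else 1
  crit <- function(value, bad) !is.na(value) & bad
  n <- nrow(records)
  fails <- vector("list", n)
  add <- function(which_rows, label) {
    for (i in which(which_rows)) fails[[i]] <<- c(fails[[i]], label)
  }
  snp <- type == "snp"; ind <- type == "indel"
  add(snp & crit(records$qual, records$qual < 30), "QUAL<30.0")
  add(snp & crit(records$QD, records$QD < 2), "QD<2.0")
  add(snp & crit(records$SOR, records$SOR > 3), "SOR>3.0")
  add(snp & crit(records$FS, records$FS > 60), "FS>60.0")
  add(snp & crit(records$MQ, records$MQ < 40), "MQ<40.0")
  add(snp & crit(records$MQRankSum, records$MQRankSum < sgn * 12.5),
      "MQRankSum")
  add(snp & crit(records$ReadPosRankSum, records$ReadPosRankSum < sgn * 8),
      "ReadPosRankSum")
  add(ind & crit(records$qual, records$qual < 30), "QUAL<30.0")
  add(ind & crit(records$QD, records$QD < 2), "QD<2.0")
  add(ind & crit(records$FS, records$FS > 200), "FS>200.0")
  add(ind & crit(records$MQ, records$MQ < 40), "MQ<40.0")
  add(ind & crit(records$ReadPosRankSum, records$ReadPosRankSum < sgn * 20),
      "ReadPosRankSum")
  failed <- vapply(fails, function(f) paste(f, collapse = ","), character(1))
  data.frame(chrom = records$chrom, pos = records$pos, ref = records$ref,
             alt = records$alt, type = type, passed = !nzchar(failed),
             failed_criteria = failed, stringsAsFactors = FALSE)
}

# coding-sequence view of one gene: transcript-ordered CDS string plus the
# mapping from genomic position to coding coordinate
gene_coding_view <- function(gene, models, genome) {
  g <- models$genes[models$genes$gene_id == gene, ]
  cd <- models$cds[models$cds$gene_id == gene, , drop = FALSE]
  chr <- as.character(genome[[g$chrom]])
  pieces <- substring(chr, cd$start, cd$end)
  if (g$strand == "+") {
    cds_seq <- paste(pieces, collapse = "")
    phase0 <- cd$phase[1]
  } else {
    cds_seq <- revcomp_str(paste(pieces, collapse = ""))
    phase0 <- cd$phase[nrow(cd)]
  }
  if (phase0 > 0) cds_seq <- substring(cds_seq, phase0 + 1)
  list(strand = g$strand, cds = cd, cds_seq = cds_seq, phase0 = phase0)
}

# coding coordinate (1-based within the phase-trimmed CDS) of genomic pos
coding_coord <- function(view, pos) {
  cd <- view$cds
  if (view$strand == "+") {
    before <- sum(pmax(0, pmin(cd$end, pos - 1) - cd$start + 1))
  } else {
    before <- sum(pmax(0, cd$end - pmax(cd$start, pos + 1) + 1))
  }
  before + 1L - view$phase0
}

classify_cds_snv <- function(view, pos, ref, alt) {
  cc <- coding_coord(view, pos)
  if (cc < 1) return("utr")  # inside the phase-trimmed overhang
  ref_t <- if (view$strand == "+") ref else comp_base(ref)
  alt_t <- if (view$strand == "+") alt else comp_base(alt)
  ci <- (cc - 1) %/% 3 + 1
  off <- (cc - 1) %% 3 + 1
  codon <- substr(view$cds_seq, 3 * ci - 2, 3 * ci)
  if (nchar(codon) < 3) return("utr")  # ragged terminal piece
  if (substr(codon, off, off) != ref_t)
    warning("REF does not match the coding sequence at ", pos)
  new <- codon
  substr(new, off, off) <- alt_t
  aa0 <- aa_of(codon); aa1 <- aa_of(new)
  if (ci == 1 && new != "ATG") return("start_lost")
  if (aa0 == "*" && aa1 == "*") return("stop_retained")
  if (aa0 == "*") return("stop_lost")
  if (aa1 == "*") return("stop_gained")
  if (aa0 == aa1) return("synonymous")
  "missense"
}

# consequence of one variant within one gene (or NA when outside its window)
consequence_in_gene <- function(gene, models, genome, pos, ref, alt,
                                window = 5000L) {
  g <- models$genes[models$genes$gene_id == gene, ]
  type <- variant_type(ref, alt)
  span <- c(pos, pos + max(nchar(ref) - 1L, 0L))
  overlaps <- function(s, e) span[1] <= e & span[2] >= s
  cd <- models$cds[models$cds$gene_id == gene, , drop = FALSE]
  ex <- models$exons[models$exons$gene_id == gene, , drop = FALSE]
  in_cds <- any(overlaps(cd$start, cd$end))
  if (in_cds && g$cds_valid) {
    if (type == "indel") {
      return(if (abs(nchar(ref) - nchar(alt)) %% 3 != 0) "frameshift"
             else "inframe_indel")
    }
    if (type == "snp") {
      view <- gene_coding_view(gene, models, genome)
      return(classify_cds_snv(view, pos, ref, alt))
    }
    return(NA_character_)  # complex records are not classified
  }
  # introns: gaps between consecutive exons; splice = first/last 2 bases
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1)) {
      i_start <- ex$end[i] + 1L
      i_end <- ex$start[i + 1] - 1L
      if (i_start > i_end) next
      if (overlaps(i_start, i_end)) {
        donor <- if (g$strand == "+") c(i_start, i_start + 1L)
                 else c(i_end - 1L, i_end)
        acceptor <- if (g$strand == "+") c(i_end - 1L, i_end)
                    else c(i_start, i_start + 1L)
        if (overlaps(donor[1], donor[2])) return("splice_donor")
        if (overlaps(acceptor[1], acceptor[2])) return("splice_acceptor")
        return("intron")
      }
    }
  }
  if (any(overlaps(ex$start, ex$end)))
    return(if (in_cds) NA_character_ else "utr")
  if (overlaps(g$start, g$end)) return("intron")  # between exons edge case
  five_prime_side <- if (g$strand == "+") span[2] < g$start
                     else span[1] > g$end
  near <- overlaps(g$start - window, g$end + window)
  if (!near) return(NA_character_)
  if (five_prime_side) "upstream" else "downstream"
}

#' Classify variants into consequence terms and impact categories
#'
#' For each variant the most severe consequence among all overlapping gene
#' windows is reported (severity HIGH > MODERATE > LOW > MODIFIER, ties
#' broken by a fixed consequence order). Coding SNP effects are computed by
#' codon translation on the gene's strand; a CDS indel is a frameshift when
#' the allele-length difference is not a multiple of 3; splice sites are the
#' first/last two intronic bases; upstream/downstream windows span 5 kb.
#' Genes flagged with an invalid CDS at load are skipped for coding calls.
#' Variants on chromosomes absent from the models are reported intergenic
#' with a warning.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (e.g. from [read_variants]).
#' @param models a [gene_models] object.
#' @param genome a [Biostrings::DNAStringSet] holding the chromosomes.
#' @param window upstream/downstream window size in bases.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `gene_id` (NA for
#'   intergenic), `consequence`, `impact`.
#' @export
classify_variant_effects <- function(variants, models, genome,
                                     window = 5000L) {
  if (any(!(variants$chrom %in% models$genes$chrom)))
    warning("variant(s) on chromosome(s) absent from the gene models: ",
            "reported intergenic")
  span_end <- variants$pos + pmax(nchar(variants$ref) - 1L, 0L)
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, span_end))
  gr <- models_gene_ranges(models, flank = window)
  GenomicRanges::strand(gr) <- "*"
  hits <- GenomicRanges::findOverlaps(vr, gr)
  cand <- split(gr$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
  n <- nrow(variants)
  consequence <- rep("intergenic", n)
  gene_out <- rep(NA_character_, n)
  for (qi in names(cand)) {
    i <- as.integer(qi)
    best_cons <- "intergenic"; best_gene <- NA_character_
    best_rank <- length(CONSEQUENCE_ORDER) + 1L
    for (gene in cand[[qi]]) {
      cons <- consequence_in_gene(gene, models, genome, variants$pos[i],
                                  variants$ref[i], variants$alt[i], window)
      if (is.na(cons)) next
      rank <- match(cons, CONSEQUENCE_ORDER)
      if (rank < best_rank) {
        best_rank <- rank; best_cons <- cons; best_gene <- gene
      }
    }
    consequence[i] <- best_cons
    gene_out[i] <- best_gene
  }
  data.frame(chrom = variants$chrom, pos = variants$pos,
             ref = variants$ref, alt = variants$alt, gene_id = gene_out,
             consequence = consequence, impact = impact_of(consequence),
             stringsAsFactors = FALSE)
}

#' Per-gene and genome-wide variant counts by impact category
#'
#' @param effects data.frame from [classify_variant_effects].
#' @return list with `per_gene` (data.frame gene_id x impact counts, genes
#'   with assigned variants only) and `totals` (genome-wide counts per
#'   impact, including intergenic variants).
#' @export
effects_by_gene <- function(effects) {
  totals <- data.frame(impact = IMPACT_LEVELS,
                       n = vapply(IMPACT_LEVELS,
                                  function(k) sum(effects$impact == k),
                                  integer(1)),
                       stringsAsFactors = FALSE)
  withg <- effects[!is.na(effects$gene_id), , drop = FALSE]
  if (nrow(withg) == 0) {
    per_gene <- data.frame(gene_id = character(0))
    for (k in IMPACT_LEVELS) per_gene[[k]] <- integer(0)
    return(list(per_gene = per_gene, totals = totals))
  }
  tab <- table(factor(withg$gene_id), factor(withg$impact,
                                             levels = IMPACT_LEVELS))
  per_gene <- data.frame(gene_id = rownames(tab),
                         as.data.frame.matrix(tab),
                         stringsAsFactors = FALSE, check.names = FALSE)
  rownames(per_gene) <- NULL
  list(per_gene = per_gene, totals = totals)
}
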