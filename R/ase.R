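# Gene-level allele-specific expression: aggregation of per-SNP parental
# allele counts over exons, an NB GLM allelic-imbalance test with replicate
# terms, and cross-tissue pattern classification.

#' Negative-binomial GLM by iteratively reweighted least squares
#'
#' Log-link NB regression with fixed dispersion `alpha`; used by the
#' allelic-imbalance test. Returns NA results when the fit does not
#' converge (e.g. a structural zero makes the MLE infinite).
#'
#' @param y non-negative counts.
#' @param X design matrix.
#' @param alpha NB dispersion (Var = mu + alpha mu^2).
#' @param max_iter,tol iteration controls.
#' @return list with `beta`, `cov` (inverse Fisher information) and
#'   `converged`.
#' @keywords internal
nb_glm_irls <- function(y, X, alpha, max_iter = 100L, tol = 1e-10) {
  beta <- tryCatch(qr.solve(X, log(pmax(y, 0.5))), error = function(e) NULL)
  if (is.null(beta)) return(list(converged = FALSE))
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- eta + (y - mu) / mu
    XtW <- t(X * w)
    new <- tryCatch(drop(solve(XtW %*% X, XtW %*% z)),
                    error = function(e) NULL)
    if (is.null(new) || any(!is.finite(new)))
      return(list(converged = FALSE))
    done <- max(abs(new - beta)) < tol
    beta <- new
    if (done) {
      cov <- tryCatch(solve(XtW %*% X), error = function(e) NULL)
      if (is.null(cov)) return(list(converged = FALSE))
      return(list(beta = beta, cov = cov, converged = TRUE))
    }
  }
  list(converged = FALSE)
}

#' Aggregate per-SNP parental-allele counts to gene level
#'
#' Sums, per gene and sample, the reads supporting the maternal and the
#' paternal allele over the informative SNPs (homozygous-different between
#' the parents) that overlap the gene's exons. A SNP overlapping the exons
#' of several genes contributes to each and the affected genes are flagged.
#' Count rows whose allele matches neither parent are excluded and reported
#' in the `qc` attribute.
#'
#' @param snp_counts data.frame with columns `chrom`, `pos`, `sample`,
#'   `allele`, `count`.
#' @param phased_snps data.frame with columns `chrom`, `pos`, `maternal`,
#'   `paternal` (distinct parental alleles).
#' @param models a [gene_models] object.
#' @return data.frame with `gene_id`, `sample`, `maternal_count`,
#'   `paternal_count`, `shared_snps` (TRUE when any contributing SNP is
#'   shared with another gene); attribute `qc` holds the excluded rows.
#' @export
aggregate_haplotype_counts <- function(snp_counts, phased_snps, models) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) schema_error(what, " missing column(s): ",
                                   paste(miss, collapse = ", "))
  }
  need(snp_counts, c("chrom", "pos", "sample", "allele", "count"),
       "snp_counts")
  need(phased_snps, c("chrom", "pos", "maternal", "paternal"), "phased_snps")
  if (any(phased_snps$maternal == phased_snps$paternal))
    schema_error("phased SNP with identical parental alleles is uninformative")
  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  ph <- phased_snps[match(key(snp_counts$chrom, snp_counts$pos),
                          key(phased_snps$chrom, phased_snps$pos)), ]
  origin <- ifelse(is.na(ph$maternal), NA_character_,
            ifelse(snp_counts$allele == ph$maternal, "maternal",
            ifelse(snp_counts$allele == ph$paternal, "paternal", NA)))
  qc <- snp_counts[is.na(origin), , drop = FALSE]
  rownames(qc) <- NULL
  keep <- !is.na(origin)
  sc <- snp_counts[keep, , drop = FALSE]
  sc$origin <- origin[keep]

  snp_gr <- GenomicRanges::GRanges(sc$chrom, IRanges::IRanges(sc$pos, sc$pos))
  hits <- GenomicRanges::findOverlaps(snp_gr, models_exon_ranges(models))
  if (length(hits) == 0) {
    out <- data.frame(gene_id = character(0), sample = character(0),
                      maternal_count = integer(0),
                      paternal_count = integer(0), shared_snps = logical(0))
    attr(out, "qc") <- qc
    return(out)
  }
  rows <- S4Vectors::queryHits(hits)
  gene <- models$exons$gene_id[S4Vectors::subjectHits(hits)]
  # a SNP position may hit several exons of the same gene only once
  dd <- !duplicated(data.frame(rows, gene))
  rows <- rows[dd]; gene <- gene[dd]
  snp_pos_key <- key(sc$chrom, sc$pos)[rows]
  pairs <- unique(data.frame(key = snp_pos_key, gene = gene,
                             stringsAsFactors = FALSE))
  shared_keys <- unique(pairs$key[duplicated(pairs$key)])
  shared_snp <- snp_pos_key %in% shared_keys
  df <- data.frame(gene_id = gene, sample = sc$sample[rows],
                   origin = sc$origin[rows], count = sc$count[rows],
                   shared = shared_snp, stringsAsFactors = FALSE)
  agg <- stats::aggregate(count ~ gene_id + sample + origin, df, sum)
  wide <- stats::reshape(agg, idvar = c("gene_id", "sample"),
                         timevar = "origin", direction = "wide")
  mc <- wide$count.maternal %||% rep(NA_integer_, nrow(wide))
  pc <- wide$count.paternal %||% rep(NA_integer_, nrow(wide))
  out <- data.frame(gene_id = wide$gene_id, sample = wide$sample,
                    maternal_count = ifelse(is.na(mc), 0L, mc),
                    paternal_count = ifelse(is.na(pc), 0L, pc),
                    stringsAsFactors = FALSE)
  shared_genes <- unique(df$gene_id[df$shared])
  out$shared_snps <- out$gene_id %in% shared_genes
  out <- out[order(out$gene_id, out$sample), ]
  rownames(out) <- NULL
  attr(out, "qc") <- qc
  out
}

#' Test allelic imbalance per gene in one tissue
#'
#' Fits, per gene, a negative-binomial GLM with log link on the
#' maternal/paternal counts of all replicates, with a replicate factor (so
#' replicate-level depth differences cannot masquerade as imbalance) and an
#' allele factor, and Wald-tests the allele coefficient. The per-gene
#' dispersion is a method-of-moments estimate on within-allele replicate
#' variation, floored at 1e-8. P-values are BH adjusted over the tested
#' genes of the tissue; a gene is an ASEG when `p_adj <= padj_cutoff`
#' (default 0.05).
#'
#' @param allelic data.frame with columns `gene_id`, `tissue`, `replicate`,
#'   `maternal_count`, `paternal_count`.
#' @param tissue tissue label to test.
#' @param min_depth minimum summed allelic count per gene for testing;
#'   genes below it are reported with `p = NA`.
#' @param padj_cutoff ASEG threshold on the BH-adjusted p-value.
#' @return data.frame with `gene_id`, `tissue`, `log2_ratio`
#'   (maternal over paternal), `p`, `p_adj`, `is_aseg`, `direction`
#'   (maternal/paternal/none).
#' @export
ase_test <- function(allelic, tissue, min_depth = 10L, padj_cutoff = 0.05) {
  sub <- allelic[allelic$tissue == tissue, , drop = FALSE]
  if (nrow(sub) == 0) schema_error("no allelic counts for tissue ", tissue)
  genes <- unique(sub$gene_id)
  beta <- se <- rep(NA_real_, length(genes))
  msum <- psum <- rep(0L, length(genes))
  design_cache <- new.env(parent = emptyenv())
  for (k in seq_along(genes)) {
    g <- sub[sub$gene_id == genes[k], , drop = FALSE]
    reps <- sort(unique(g$replicate))
    msum[k] <- sum(g$maternal_count)
    psum[k] <- sum(g$paternal_count)
    if (length(reps) < 2) next
    if (msum[k] + psum[k] < min_depth) next
    g <- g[match(reps, g$replicate), ]
    y <- c(g$maternal_count, g$paternal_count)
    ck <- paste(reps, collapse = ",")
    X <- design_cache[[ck]]
    if (is.null(X)) {
      rep_f <- factor(rep(reps, 2))
      X <- stats::model.matrix(~ rep_f + rep(c(1, 0), each = length(reps)))
      colnames(X)[ncol(X)] <- "allele_maternal"
      design_cache[[ck]] <- X
    }
    mom <- function(v) {
      m <- mean(v)
      if (m <= 0) return(NA_real_)
      (var(v) - m) / m^2
    }
    a2 <- c(mom(g$maternal_count), mom(g$paternal_count))
    alpha <- max(1e-8, mean(a2, na.rm = TRUE), na.rm = TRUE)
    fit <- nb_glm_irls(y, X, alpha)
    if (!fit$converged) next
    j <- ncol(X)
    beta[k] <- fit$beta[j]
    se[k] <- sqrt(fit$cov[j, j])
  }
  stat <- beta / se
  p <- 2 * pnorm(-abs(stat))
  p_adj <- bh_adjust(p)
  is_aseg <- !is.na(p_adj) & p_adj <= padj_cutoff
  direction <- ifelse(is_aseg & msum > psum, "maternal",
               ifelse(is_aseg & psum > msum, "paternal", "none"))
  out <- data.frame(gene_id = genes, tissue = tissue,
                    log2_ratio = beta / log(2), p = p, p_adj = p_adj,
                    is_aseg = is_aseg, direction = direction,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cross-tissue ASEG pattern classification
#'
#' Genes that are ASEGs in both tissues are classified as
#' `consistent_maternal` / `consistent_paternal` when biased toward the
#' same parent in both, and `shift_direction` when biased toward different
#' parents. Genes significant in only one tissue are not classified.
#'
#' @param res_tissue1,res_tissue2 results of [ase_test] for the two tissues.
#' @return list with `patterns` (data.frame `gene_id`, `pattern`) and
#'   `counts` (data.frame of per-pattern counts).
#' @export
classify_aseg_patterns <- function(res_tissue1, res_tissue2) {
  a <- res_tissue1[res_tissue1$is_aseg & res_tissue1$direction != "none", ]
  b <- res_tissue2[res_tissue2$is_aseg & res_tissue2$direction != "none", ]
  common <- intersect(a$gene_id, b$gene_id)
  d1 <- a$direction[match(common, a$gene_id)]
  d2 <- b$direction[match(common, b$gene_id)]
  pattern <- ifelse(d1 == d2, paste0("consistent_", d1), "shift_direction")
  patterns <- data.frame(gene_id = common, pattern = pattern,
                         stringsAsFactors = FALSE)
  lv <- c("consistent_maternal", "consistent_paternal", "shift_direction")
  counts <- data.frame(pattern = lv,
                       n = vapply(lv, function(k) sum(pattern == k),
                                  integer(1)),
                       stringsAsFactors = FALSE)
  list(patterns = patterns, counts = counts)
}
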