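# Counts-level differential expression: active-gene calling, median-of-ratios
# normalization, method-of-moments NB dispersion with trend shrinkage, and a
# two-group NB Wald test. The NB score equations are solved on size-factor
# normalized counts, which coincides with the offset IRLS fixed point when
# all factors are equal and makes results exactly invariant to per-sample
# depth rescaling (see the methods vignette).

as_counts <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "counts")
  if (!is.matrix(x)) schema_error("counts must be a matrix or SummarizedExperiment")
  x
}

resolve_cols <- function(mat, cols) {
  if (is.character(cols)) {
    miss <- setdiff(cols, colnames(mat))
    if (length(miss)) schema_error("unknown sample(s): ",
                                   paste(miss, collapse = ", "))
    match(cols, colnames(mat))
  } else as.integer(cols)
}

#' Call actively expressed genes in a replicate group
#'
#' A gene is active when at least `min_reps` replicate columns of the group
#' have a raw count of at least `min_reads` (default: two reads in two
#' biological replicates).
#'
#' @param counts matrix or SummarizedExperiment of raw counts.
#' @param group column names or indices of one replicate group (>= 2).
#' @param min_reads,min_reps the activity rule thresholds.
#' @return character vector of active gene ids.
#' @export
call_active_genes <- function(counts, group, min_reads = 2L, min_reps = 2L) {
  mat <- as_counts(counts)
  idx <- resolve_cols(mat, group)
  if (length(idx) < 2) schema_error("group must have at least 2 replicates")
  hits <- rowSums(mat[, idx, drop = FALSE] >= min_reads)
  rownames(mat)[hits >= min_reps]
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference genes (genes with nonzero
#' counts in every sample) of the ratio of its count to the gene's geometric
#' mean across samples.
#'
#' @param counts matrix or SummarizedExperiment of raw counts.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  mat <- as_counts(counts)
  ref <- rowSums(mat == 0) == 0
  if (!any(ref)) schema_error("no reference gene with nonzero counts in all samples")
  lg <- log(mat[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, median)
  setNames(sf, colnames(mat))
}

#' Size-factor-normalized counts
#' @param counts matrix or SummarizedExperiment of raw counts.
#' @param sf size factors; computed with [size_factors] when `NULL`.
#' @return numeric matrix of normalized counts.
#' @export
normalized_counts <- function(counts, sf = NULL) {
  mat <- as_counts(counts)
  if (is.null(sf)) sf <- size_factors(mat)
  if (!is.null(names(sf)) && !is.null(colnames(mat))) {
    if (!all(colnames(mat) %in% names(sf)))
      schema_error("size factors missing for sample(s): ",
                   paste(setdiff(colnames(mat), names(sf)), collapse = ", "))
    sf <- sf[colnames(mat)]
  }
  if (length(sf) != ncol(mat))
    schema_error("size factor length does not match sample count")
  if (any(!(sf > 0))) schema_error("size factors must be positive")
  sweep(mat, 2, sf, "/")
}

#' Per-gene NB dispersion by method of moments with trend shrinkage
#'
#' The raw per-gene estimate is `max(0, (s^2 - mu)/mu^2)` on normalized
#' counts, pooled across the supplied replicate groups with weights
#' `n_g - 1`. A mean-dispersion trend `alpha(mu) = a0/mu + a1` is fitted by
#' least squares over genes and the final estimate is the 50/50 mixture of
#' the raw value and the trend (weight configurable).
#'
#' @param counts matrix or SummarizedExperiment of raw counts.
#' @param groups list of column-name/index vectors, one per replicate group
#'   (each of size >= 2).
#' @param sf size factors (computed when `NULL`).
#' @param shrink_weight weight of the gene-wise estimate in the mixture.
#' @return data.frame with `gene_id`, pooled normalized mean `mu`,
#'   `alpha_raw`, `alpha_trend` and the shrunk `alpha` (NA for genes with
#'   no signal in any group).
#' @export
estimate_dispersion <- function(counts, groups, sf = NULL,
                                shrink_weight = 0.5) {
  mat <- as_counts(counts)
  q <- normalized_counts(mat, sf)
  idx <- lapply(groups, resolve_cols, mat = mat)
  if (any(lengths(idx) < 2))
    schema_error("every group needs >= 2 replicates for dispersion estimation")
  num <- 0; den <- 0
  have <- rep(FALSE, nrow(q))
  for (ii in idx) {
    m <- rowMeans(q[, ii, drop = FALSE])
    v <- apply(q[, ii, drop = FALSE], 1, var)
    a <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    w <- length(ii) - 1
    num <- num + ifelse(is.na(a), 0, a * w)
    den <- den + ifelse(is.na(a), 0, w)
    have <- have | !is.na(a)
  }
  alpha_raw <- ifelse(have, pmax(0, num / pmax(den, 1)), NA_real_)
  mu <- rowMeans(q[, unlist(idx), drop = FALSE])
  ok <- !is.na(alpha_raw) & mu > 0
  alpha_trend <- rep(NA_real_, nrow(q))
  if (sum(ok) >= 10) {
    fit <- lm(alpha_raw[ok] ~ I(1 / mu[ok]))
    alpha_trend[ok] <- pmax(1e-8, coef(fit)[1] + coef(fit)[2] / mu[ok])
  } else {
    alpha_trend[ok] <- pmax(1e-8, mean(alpha_raw[ok]))
  }
  alpha <- shrink_weight * alpha_raw + (1 - shrink_weight) * alpha_trend
  data.frame(gene_id = rownames(q) %||% seq_len(nrow(q)), mu = mu,
             alpha_raw = alpha_raw, alpha_trend = alpha_trend,
             alpha = alpha, stringsAsFactors = FALSE)
}

#' Two-group negative-binomial Wald test
#'
#' Fits per gene the NB log-link model with a group contrast on size-factor
#' normalized counts and tests the group coefficient with a Wald z-test.
#' For this design the score equations have the closed-form solution
#' `mu_g = mean of normalized counts in group g`, with
#' `Var(beta) = sum_g (1 + alpha mu_g) / (n_g mu_g)`. P-values are BH
#' adjusted across tested genes; a gene is flagged a DEG when
#' `fdr <= fdr_cutoff` and `|log2fc| >= lfc_cutoff` (defaults 0.01 and 1).
#'
#' `log2fc` is the log2 ratio of group B over group A. Genes with zero mean
#' in either group (no finite NB estimate) or undefined dispersion are
#' reported with `p = NA` and excluded from the BH adjustment.
#'
#' @param counts matrix or SummarizedExperiment of raw counts.
#' @param group_a,group_b column names/indices of the two replicate groups.
#' @param sf size factors (computed on the full matrix when `NULL`).
#' @param dispersion per-gene NB dispersion; estimated from the two groups
#'   via [estimate_dispersion] when `NULL`.
#' @param fdr_cutoff,lfc_cutoff DEG thresholds.
#' @param pseudocount_lfc when TRUE, adds a reporting-only
#'   `log2fc_pseudo` column computed with a +0.5 pseudocount on the group
#'   means (never used for testing or the DEG flag).
#' @return data.frame with `gene_id`, `base_mean_a`, `base_mean_b`,
#'   `log2fc`, `stat`, `p`, `fdr`, `is_deg`, `direction` (up/down/ns, group
#'   B relative to group A).
#' @export
nb_wald_test <- function(counts, group_a, group_b, sf = NULL,
                         dispersion = NULL, fdr_cutoff = 0.01,
                         lfc_cutoff = 1, pseudocount_lfc = FALSE) {
  mat <- as_counts(counts)
  ia <- resolve_cols(mat, group_a)
  ib <- resolve_cols(mat, group_b)
  if (length(ia) < 2 || length(ib) < 2)
    schema_error("both groups need >= 2 replicates")
  if (length(intersect(ia, ib)))
    schema_error("groups must not share samples")
  if (is.null(sf)) sf <- size_factors(mat)
  q <- normalized_counts(mat, sf)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(mat, list(ia, ib), sf = sf)$alpha
  mu_a <- rowMeans(q[, ia, drop = FALSE])
  mu_b <- rowMeans(q[, ib, drop = FALSE])
  na <- length(ia); nb <- length(ib)
  testable <- mu_a > 0 & mu_b > 0 & !is.na(dispersion)
  beta <- se <- rep(NA_real_, nrow(q))
  beta[testable] <- log(mu_b[testable] / mu_a[testable])
  se[testable] <- sqrt(
    (1 + dispersion[testable] * mu_a[testable]) / (na * mu_a[testable]) +
    (1 + dispersion[testable] * mu_b[testable]) / (nb * mu_b[testable]))
  stat <- ifelse(testable, beta / se, NA_real_)
  p <- ifelse(testable, 2 * pnorm(-abs(stat)), NA_real_)
  fdr <- bh_adjust(p)
  log2fc <- beta / log(2)
  is_deg <- !is.na(fdr) & fdr <= fdr_cutoff & abs(log2fc) >= lfc_cutoff
  out <- data.frame(
    gene_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    base_mean_a = mu_a, base_mean_b = mu_b, log2fc = log2fc, stat = stat,
    p = p, fdr = fdr, is_deg = is_deg,
    direction = ifelse(is_deg, ifelse(log2fc > 0, "up", "down"), "ns"),
    stringsAsFactors = FALSE)
  if (pseudocount_lfc)
    out$log2fc_pseudo <- log2((mu_b + 0.5) / (mu_a + 0.5))
  rownames(out) <- NULL
  out
}

#' Pairwise sample correlation of expression (R-squared)
#'
#' Pearson correlation of `log2(normalized count + 1)` between all sample
#' pairs, per pair over the genes detected (raw count >= `min_reads`) in at
#' least one of the two samples; reported as R^2. Samples with zero variance
#' over the compared genes give NA.
#'
#' @param counts matrix or SummarizedExperiment of raw counts.
#' @param sf size factors (computed when `NULL`).
#' @param min_reads per-sample detection threshold.
#' @return symmetric matrix of R^2 values with unit diagonal.
#' @export
sample_correlation <- function(counts, sf = NULL, min_reads = 2L) {
  mat <- as_counts(counts)
  if (ncol(mat) < 2) schema_error("need >= 2 samples")
  lq <- log2(normalized_counts(mat, sf) + 1)
  n <- ncol(mat)
  r2 <- matrix(NA_real_, n, n, dimnames = list(colnames(mat), colnames(mat)))
  diag(r2) <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      keep <- mat[, i] >= min_reads | mat[, j] >= min_reads
      if (sum(keep) < 2) next
      x <- lq[keep, i]; y <- lq[keep, j]
      if (sd(x) == 0 || sd(y) == 0) next
      r2[i, j] <- r2[j, i] <- cor(x, y)^2
    }
  }
  r2
}
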