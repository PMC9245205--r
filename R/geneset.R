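# Set-level statistics: resampling overlap enrichment between two gene
# sets, hypergeometric term over-representation, and the ASEG variant
# density comparison.

#' Resampling test for the overlap of two gene sets
#'
#' Draws, `n_sim` times, random sets of the same sizes as `set_a` and
#' `set_b` uniformly without replacement from the universe and records the
#' intersection size. Reports a one-sample Student t-test of the null
#' overlaps against the observed overlap (alternative: null mean below the
#' observed value, i.e. the overlap exceeds expectation) together with the
#' empirical permutation p-value `(1 + #[null >= observed]) / (n_sim + 1)`.
#' The empirical p is the recommended headline number; the t-test is kept
#' as the conventional companion.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @param n_sim number of null draws (>= 2).
#' @param seed optional integer seed for the draws.
#' @return list of class `overlap_test` with `observed_overlap`,
#'   `null_mean`, `null_sd`, `n_sim`, `t_stat`, `p_t`, `p_empirical`.
#' @export
overlap_resampling_test <- function(set_a, set_b, universe, n_sim = 1000L,
                                    seed = NULL) {
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    schema_error("sets must be subsets of the universe")
  if (length(set_a) > length(universe) || length(set_b) > length(universe))
    schema_error("set larger than universe")
  if (n_sim < 2) config_error("n_sim must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  observed <- length(intersect(set_a, set_b))
  n <- length(universe)
  na <- length(set_a); nb <- length(set_b)
  null <- integer(n_sim)
  for (s in seq_len(n_sim)) {
    ia <- logical(n); ia[sample.int(n, na)] <- TRUE
    null[s] <- sum(ia[sample.int(n, nb)])
  }
  null_sd <- sd(null)
  if (null_sd > 0) {
    tt <- t.test(null, mu = observed, alternative = "less")
    t_stat <- unname(tt$statistic); p_t <- tt$p.value
  } else {
    t_stat <- NA_real_; p_t <- NA_real_
  }
  structure(list(observed_overlap = observed, null_mean = mean(null),
                 null_sd = null_sd, n_sim = n_sim, t_stat = t_stat,
                 p_t = p_t,
                 p_empirical = (1 + sum(null >= observed)) / (n_sim + 1)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(paste0("overlap test: observed %d, null %.2f +/- %.2f ",
                     "(%d draws), t p = %s, empirical p = %.4g\n"),
              x$observed_overlap, x$null_mean, x$null_sd, x$n_sim,
              format(x$p_t, digits = 3), x$p_empirical))
  invisible(x)
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least the seen number of query genes annotated to the term, given the
#' term size and the universe; BH-adjusted across terms and sorted by
#' p-value. The term map is restricted to the universe first.
#'
#' @param query character vector of genes (non-empty subset of `universe`).
#' @param term_map data.frame with columns `term_id`, `gene_id`.
#' @param universe character vector of all genes considered.
#' @return data.frame with `term_id`, `k` (query hits), `K` (term size),
#'   `n` (query size), `N` (universe size), `p`, `fdr`.
#' @export
hypergeom_enrichment <- function(query, term_map, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(query) == 0) schema_error("empty query set")
  if (!all(query %in% universe))
    schema_error("query must be a subset of the universe")
  tm <- unique(term_map[term_map$gene_id %in% universe,
                        c("term_id", "gene_id")])
  N <- length(universe)
  n <- length(query)
  terms <- unique(tm$term_id)
  K <- vapply(terms, function(t) sum(tm$term_id == t), integer(1))
  k <- vapply(terms, function(t)
    sum(tm$gene_id[tm$term_id == t] %in% query), integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = terms, k = k, K = K, n = n, N = N, p = p,
                    fdr = p.adjust(p, "BH"), stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Variant density on ASEGs versus the genomic background
#'
#' Per impact category, counts the variants assigned to ASEGs and
#' genome-wide, the ASEG proportion, and a permutation significance value:
#' gene sets of the ASEG size are resampled from all genes `n_sim` times
#' and the per-category variant counts compared with the observed ones
#' (`p = (1 + #[perm >= observed]) / (n_sim + 1)`).
#'
#' @param effects data.frame from [classify_variant_effects].
#' @param aseg_set character vector of ASEG gene ids (non-empty).
#' @param all_genes character vector of all genes eligible for resampling.
#' @param n_sim number of permutations.
#' @param seed optional integer seed.
#' @return data.frame with `impact`, `variants_on_asegs`,
#'   `variants_genomewide`, `proportion`, `p`.
#' @export
variant_density_comparison <- function(effects, aseg_set, all_genes,
                                       n_sim = 1000L, seed = NULL) {
  aseg_set <- unique(aseg_set)
  all_genes <- unique(all_genes)
  if (length(aseg_set) == 0) schema_error("empty ASEG set")
  if (!all(aseg_set %in% all_genes))
    schema_error("aseg_set must be a subset of all_genes")
  if (!is.null(seed)) set.seed(seed)
  counts <- effects_by_gene(effects)
  per_gene <- counts$per_gene
  mat <- matrix(0L, length(all_genes), length(IMPACT_LEVELS),
                dimnames = list(all_genes, IMPACT_LEVELS))
  hit <- per_gene$gene_id %in% all_genes
  mat[per_gene$gene_id[hit], ] <-
    as.matrix(per_gene[hit, IMPACT_LEVELS, drop = FALSE])
  obs <- colSums(mat[rownames(mat) %in% aseg_set, , drop = FALSE])
  total <- setNames(counts$totals$n, counts$totals$impact)[IMPACT_LEVELS]
  ge <- matrix(0L, n_sim, length(IMPACT_LEVELS))
  m <- length(aseg_set)
  for (s in seq_len(n_sim)) {
    perm <- colSums(mat[sample.int(nrow(mat), m), , drop = FALSE])
    ge[s, ] <- as.integer(perm >= obs)
  }
  data.frame(impact = IMPACT_LEVELS,
             variants_on_asegs = as.integer(obs),
             variants_genomewide = as.integer(total),
             proportion = ifelse(total > 0, obs / total, NA_real_),
             p = (1 + colSums(ge)) / (n_sim + 1),
             stringsAsFactors = FALSE)
}
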