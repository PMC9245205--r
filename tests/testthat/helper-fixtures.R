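# Shared fixtures and small oracles built in code at test time.

# small trio simulation reused across tests
tiny_sim <- function(seed = 3, n_genes = 120, ...) {
  cfg <- sim_config(seed = seed, n_genes = n_genes, ...)
  list(config = cfg, trio = simulate_trio_counts(cfg))
}

# NB count matrix for two groups with given means
nb_matrix <- function(n_genes, mu_a, mu_b, alpha, reps = 3) {
  mat <- cbind(
    matrix(rnbinom(n_genes * reps, mu = mu_a, size = 1 / alpha), n_genes),
    matrix(rnbinom(n_genes * reps, mu = mu_b, size = 1 / alpha), n_genes))
  rownames(mat) <- sprintf("g%05d", seq_len(n_genes))
  colnames(mat) <- sprintf("s%d", seq_len(2 * reps))
  mat
}

# allelic counts frame for one tissue with constant maternal fraction
allelic_frame <- function(n_genes, pi, depth = 100, reps = 3,
                          tissue = "leaf") {
  tot <- rpois(n_genes * reps, depth)
  m <- rbinom(n_genes * reps, tot, pi)
  data.frame(gene_id = rep(sprintf("g%05d", seq_len(n_genes)), each = reps),
             tissue = tissue, replicate = rep(seq_len(reps), n_genes),
             maternal_count = m, paternal_count = tot - m,
             stringsAsFactors = FALSE)
}

# brute-force upper-tail hypergeometric p by enumerating all query draws
hyper_p_enum <- function(N, K, n, k_obs) {
  genes <- seq_len(N)
  in_term <- genes <= K
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(in_term[draws], nrow = n))
  mean(hits >= k_obs)
}

# brute-force NB fit for one gene, two groups: profile the log-likelihood
# over the two group means on a grid, then Wald from expected information
nb_wald_oracle <- function(ya, yb, alpha) {
  loglik <- function(y, mu) sum(dnbinom(y, mu = mu, size = 1 / alpha,
                                        log = TRUE))
  grid_opt <- function(y) {
    lo <- max(mean(y) / 10, 1e-3); hi <- max(mean(y) * 10, 1)
    g <- exp(seq(log(lo), log(hi), length.out = 20000))
    g[which.max(vapply(g, function(m) loglik(y, m), numeric(1)))]
  }
  ma <- grid_opt(ya); mb <- grid_opt(yb)
  beta <- log(mb / ma)
  va <- (1 + alpha * ma) / (length(ya) * ma)
  vb <- (1 + alpha * mb) / (length(yb) * mb)
  z <- beta / sqrt(va + vb)
  list(beta = beta, z = z, p = 2 * pnorm(-abs(z)))
}

# reverse-complement a genome + gene model and remap SNV coordinates,
# for the strand-symmetry property of the variant annotator
revcomp_world <- function(models, genome, variants) {
  L <- Biostrings::width(genome)
  names(L) <- names(genome)
  flip <- function(chrom, s, e) {
    n <- L[chrom]
    data.frame(start = n - e + 1L, end = n - s + 1L)
  }
  g <- models$genes
  fg <- flip(g$chrom, g$start, g$end)
  g$start <- fg$start; g$end <- fg$end
  g$strand <- ifelse(g$strand == "+", "-", "+")
  ex <- models$exons
  fe <- flip(ex$chrom, ex$start, ex$end)
  ex$start <- fe$start; ex$end <- fe$end
  cd <- models$cds
  fc <- flip(cd$chrom, cd$start, cd$end)
  cd$start <- fc$start; cd$end <- fc$end
  ord <- function(df) df[order(df$gene_id, df$start), , drop = FALSE]
  m2 <- gene_models(g, ord(ex), ord(cd))
  genome2 <- Biostrings::reverseComplement(genome)
  names(genome2) <- names(genome)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  v2 <- variants
  v2$pos <- L[variants$chrom] - variants$pos + 1L
  v2$ref <- rc(variants$ref)
  v2$alt <- rc(variants$alt)
  list(models = m2, genome = genome2, variants = v2)
}
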