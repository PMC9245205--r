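test_that("identical config and seed give bit-identical simulations", {
  a <- tiny_sim(seed = 11)$trio
  b <- tiny_sim(seed = 11)$trio
  expect_identical(SummarizedExperiment::assay(a$counts),
                   SummarizedExperiment::assay(b$counts))
  expect_identical(a$truth, b$truth)
  cfg <- sim_config(seed = 11, n_genes = 120)
  expect_identical(simulate_allelic_counts(cfg, a$truth),
                   simulate_allelic_counts(cfg, b$truth))
})

test_that("frac_de = 0 builds a null dataset with equal means", {
  s <- tiny_sim(seed = 5, frac_de = 0)$trio
  expect_false(any(s$truth$de_status))
  expect_equal(s$truth$mu_maternal, s$truth$mu_paternal)
  expect_equal(s$truth$mu_maternal, s$truth$mu_hybrid)
  # empirical hybrid/parent mean ratios concentrate near 1
  q <- normalized_counts(s$counts)
  cd <- SummarizedExperiment::colData(s$counts)
  h <- rowMeans(q[, cd$role == "hybrid" & cd$tissue == "leaf"])
  m <- rowMeans(q[, cd$role == "maternal" & cd$tissue == "leaf"])
  keep <- m > 0 & h > 0
  expect_lt(abs(median(log(h[keep] / m[keep]))), 0.1)
})

test_that("planted DE fraction matches frac_de by direct truth count", {
  cfg <- sim_config(seed = 1, n_genes = 2000, frac_de = 0.3)
  s <- simulate_trio_counts(cfg)
  frac <- mean(s$truth$de_status[s$truth$tissue == "leaf"])
  expect_lt(abs(frac - 0.30), 0.02)
})

test_that("planted truth is realizable: noiseless means reproduce the category", {
  for (seed in c(2, 7)) {
    s <- tiny_sim(seed = seed, n_genes = 400)$trio
    tr <- s$truth[s$truth$de_status, ]
    st <- hp_statistic(tr$mu_maternal, tr$mu_paternal, tr$mu_hybrid)
    expect_equal(st$hp, tr$hp_planted, tolerance = 1e-12)
    expect_true(all(classify_dominance(st$hp) == tr$hp_category))
    # margin of at least 0.1 from every finite interval endpoint
    ends <- c(-1.2, -0.8, -0.2, 0.2, 0.8, 1.2)
    expect_true(all(vapply(tr$hp_planted,
                           function(h) min(abs(h - ends)) >= 0.1 - 1e-9,
                           logical(1))))
    # hybrid at least 2^lfc-fold from one parent
    fold <- pmax(tr$mu_hybrid / pmax(tr$mu_maternal, 1e-12),
                 pmax(tr$mu_maternal, 1e-12) / pmax(tr$mu_hybrid, 1e-12),
                 tr$mu_hybrid / pmax(tr$mu_paternal, 1e-12),
                 pmax(tr$mu_paternal, 1e-12) / pmax(tr$mu_hybrid, 1e-12))
    expect_true(all(fold >= 2^2 - 1e-9))
  }
})

test_that("truth table lists every gene exactly once per tissue", {
  s <- tiny_sim(seed = 9)$trio
  tab <- table(s$truth$gene_id, s$truth$tissue)
  expect_true(all(tab == 1))
  expect_setequal(unique(s$truth$gene_id),
                  rownames(SummarizedExperiment::assay(s$counts)))
})

test_that("allelic counts follow the planted binomial model", {
  cfg <- sim_config(seed = 4, n_genes = 300, frac_ase = 0.4, ase_fold = 4,
                    allelic_depth_mean = 200)
  s <- simulate_trio_counts(cfg)
  al <- simulate_allelic_counts(cfg, s$truth)
  tr <- s$truth[s$truth$tissue == "leaf", ]
  al1 <- al[al$tissue == "leaf", ]
  agg <- aggregate(cbind(maternal_count, paternal_count) ~ gene_id, al1, sum)
  m <- match(agg$gene_id, tr$gene_id)
  frac <- agg$maternal_count / (agg$maternal_count + agg$paternal_count)
  bal <- tr$ase_direction[m] == "none"
  # balanced genes: summed maternal fraction within 3 SE of 0.5
  ntot <- sum(agg$maternal_count[bal] + agg$paternal_count[bal])
  pooled <- sum(agg$maternal_count[bal]) / ntot
  expect_lt(abs(pooled - 0.5), 3 * sqrt(0.25 / ntot))
  # biased genes: fraction near ase_fold/(1+ase_fold) = 0.8
  expect_equal(mean(frac[tr$ase_direction[m] == "maternal"]), 0.8,
               tolerance = 0.02)
  expect_equal(mean(frac[tr$ase_direction[m] == "paternal"]), 0.2,
               tolerance = 0.02)
})

test_that("zero allelic depth is flagged uninformative", {
  cfg <- sim_config(seed = 4, n_genes = 20, allelic_depth_mean = 0)
  s <- simulate_trio_counts(cfg)
  expect_warning(al <- simulate_allelic_counts(cfg, s$truth),
                 "uninformative")
  expect_true(all(al$maternal_count == 0 & al$paternal_count == 0))
  expect_true(attr(al, "uninformative"))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(hp_category_fractions = c(over_dominance = 0.8,
                                                    additive = 0.4)),
               class = "heteroseq_config_error")
  expect_error(sim_config(ase_fold = 1), class = "heteroseq_config_error")
  expect_error(sim_config(impact_category_probs = c(HIGH = 0.5,
                                                    MODERATE = 0.2,
                                                    LOW = 0.2,
                                                    MODIFIER = 0.2)),
               class = "heteroseq_config_error")
  expect_error(sim_config(dispersion = 0), class = "heteroseq_config_error")
  expect_error(sim_config(frac_de = 1.2), class = "heteroseq_config_error")
})

test_that("genome annotation is deterministic to the byte and well formed", {
  cfg <- sim_config(seed = 6, n_genes = 60)
  s <- simulate_trio_counts(cfg)
  a1 <- simulate_genome_annotation(cfg, s$truth)
  a2 <- simulate_genome_annotation(cfg, s$truth)
  d <- withr::local_tempdir()
  write_gff(a1$models, file.path(d, "a.gff3"))
  write_gff(a2$models, file.path(d, "b.gff3"))
  write_vcf(a1$variants, file.path(d, "a.vcf"))
  write_vcf(a2$variants, file.path(d, "b.vcf"))
  expect_identical(readLines(file.path(d, "a.gff3")),
                   readLines(file.path(d, "b.gff3")))
  expect_identical(readLines(file.path(d, "a.vcf")),
                   readLines(file.path(d, "b.vcf")))
  # REF alleles match the genome; planted frameshifts are 1-2 bp indels
  chr <- as.character(a1$genome)
  ref_seen <- unname(substr(chr[a1$variants$chrom], a1$variants$pos,
                            a1$variants$pos + nchar(a1$variants$ref) - 1))
  expect_identical(ref_seen, a1$variants$ref)
  fs <- a1$variant_truth$consequence == "frameshift"
  dl <- abs(nchar(a1$variants$ref) - nchar(a1$variants$alt))
  expect_true(all(dl[fs] %in% c(1, 2)))
  expect_true(all(dl[!fs] == 0))
  # gene spacing leaves intergenic space unambiguous
  g <- a1$models$genes
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1)
      expect_true(all(gc$start[-1] - gc$end[-nrow(gc)] > 10000))
  }
})

test_that("ASE genes receive a higher planted variant rate when configured", {
  cfg <- sim_config(seed = 8, n_genes = 400, frac_ase = 0.3,
                    aseg_variant_multiplier = 3)
  s <- simulate_trio_counts(cfg)
  ann <- simulate_genome_annotation(cfg, s$truth)
  ase_genes <- unique(s$truth$gene_id[s$truth$ase_direction != "none"])
  per_gene <- table(factor(ann$variant_truth$gene_id,
                           levels = unique(s$truth$gene_id)))
  r_ase <- mean(per_gene[names(per_gene) %in% ase_genes])
  r_bg <- mean(per_gene[!names(per_gene) %in% ase_genes])
  expect_gt(r_ase / r_bg, 2)
})
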