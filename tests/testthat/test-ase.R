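ase_models <- function() {
  # two adjacent genes sharing an exon interval, one distant gene
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      strand = "+", start = c(100L, 180L, 5000L),
                      end = c(220L, 321L, 5120L))
  exons <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      start = c(100L, 180L, 5000L),
                      end = c(220L, 321L, 5120L))
  cds <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                    start = c(101L, 181L, 5001L),
                    end = c(220L, 321L, 5120L), phase = 0L)
  suppressWarnings(gene_models(genes, exons, cds))
}

test_that("SNP counts aggregate to gene-level haplotypic counts", {
  models <- ase_models()
  phased <- data.frame(chrom = "chr1", pos = c(120L, 150L, 200L, 9000L),
                       maternal = c("A", "C", "G", "T"),
                       paternal = c("G", "T", "A", "C"))
  snp_counts <- data.frame(
    chrom = "chr1",
    pos = c(120, 120, 150, 150, 200, 200, 120, 9000),
    sample = c(rep("s1", 6), "s2", "s1"),
    allele = c("A", "G", "C", "T", "G", "A", "A", "T"),
    count = c(5, 1, 7, 3, 4, 2, 9, 11))
  out <- aggregate_haplotype_counts(snp_counts, phased, models)
  gA_s1 <- out[out$gene_id == "gA" & out$sample == "s1", ]
  # SNPs 120 and 150 fall only in gA: maternal 5+7, paternal 1+3
  expect_equal(gA_s1$maternal_count + 0, 5 + 7 + 4)  # 200 is shared
  expect_equal(gA_s1$paternal_count + 0, 1 + 3 + 2)
  # the shared SNP at 200 contributes to both genes and flags them
  gB_s1 <- out[out$gene_id == "gB" & out$sample == "s1", ]
  expect_equal(gB_s1$maternal_count + 0, 4)
  expect_true(gA_s1$shared_snps)
  expect_true(gB_s1$shared_snps)
  # the SNP at 9000 overlaps no gene: absent from the output
  expect_false("9000" %in% out$gene_id)
  expect_false(any(out$gene_id == "gC"))
  # per-sample accounting
  gA_s2 <- out[out$gene_id == "gA" & out$sample == "s2", ]
  expect_equal(gA_s2$maternal_count + 0, 9)
})

test_that("alleles matching neither parent are excluded into the QC report", {
  models <- ase_models()
  phased <- data.frame(chrom = "chr1", pos = 120L, maternal = "A",
                       paternal = "G")
  snp_counts <- data.frame(chrom = "chr1", pos = c(120, 120, 120),
                           sample = "s1", allele = c("A", "G", "T"),
                           count = c(5, 3, 2))
  out <- aggregate_haplotype_counts(snp_counts, phased, models)
  expect_equal(out$maternal_count, 5L)
  expect_equal(out$paternal_count, 3L)
  qc <- attr(out, "qc")
  expect_equal(nrow(qc), 1L)
  expect_equal(qc$allele, "T")
  expect_error(
    aggregate_haplotype_counts(snp_counts,
                               data.frame(chrom = "chr1", pos = 120L,
                                          maternal = "A", paternal = "A"),
                               models),
    class = "heteroseq_schema_error")
})

test_that("aggregation conserves the contributing SNP-level counts", {
  models <- ase_models()
  set.seed(51)
  pos <- c(110L, 130L, 205L, 240L, 5050L)
  phased <- data.frame(chrom = "chr1", pos = pos, maternal = "A",
                       paternal = "G")
  snp_counts <- expand.grid(pos = pos, sample = c("s1", "s2"),
                            allele = c("A", "G"),
                            stringsAsFactors = FALSE)
  snp_counts$chrom <- "chr1"
  snp_counts$count <- rpois(nrow(snp_counts), 20)
  out <- aggregate_haplotype_counts(snp_counts, phased, models)
  # gC holds only the SNP at 5050, no sharing: totals conserved exactly
  gc_tot <- sum(out$maternal_count[out$gene_id == "gC"] +
                out$paternal_count[out$gene_id == "gC"])
  expect_equal(gc_tot, sum(snp_counts$count[snp_counts$pos == 5050]))
  expect_false(any(out$shared_snps[out$gene_id == "gC"]))
})

test_that("equal allelic counts give a unit p-value and no direction", {
  al <- data.frame(gene_id = "g1", tissue = "leaf", replicate = 1:3,
                   maternal_count = c(10L, 20L, 30L),
                   paternal_count = c(10L, 20L, 30L))
  r <- ase_test(al, "leaf")
  expect_equal(r$log2_ratio, 0)
  expect_equal(r$p, 1)
  expect_equal(r$direction, "none")
  expect_false(r$is_aseg)
})

test_that("genes below the depth floor are untested", {
  al <- rbind(
    data.frame(gene_id = "lo", tissue = "leaf", replicate = 1:3,
               maternal_count = c(1L, 1L, 0L), paternal_count = c(1L, 0L, 1L)),
    data.frame(gene_id = "hi", tissue = "leaf", replicate = 1:3,
               maternal_count = c(30L, 28L, 35L),
               paternal_count = c(5L, 8L, 6L)))
  r <- ase_test(al, "leaf", min_depth = 10)
  expect_true(is.na(r$p[r$gene_id == "lo"]))
  expect_false(is.na(r$p[r$gene_id == "hi"]))
})

test_that("swapping allele labels flips directions and keeps p-values", {
  set.seed(52)
  al <- allelic_frame(150, 0.75, depth = 120)
  sw <- al
  sw$maternal_count <- al$paternal_count
  sw$paternal_count <- al$maternal_count
  a <- ase_test(al, "leaf")
  b <- ase_test(sw, "leaf")
  expect_equal(a$p, b$p, tolerance = 1e-6)
  expect_equal(a$log2_ratio, -b$log2_ratio, tolerance = 1e-6)
  flip <- c(maternal = "paternal", paternal = "maternal", none = "none")
  expect_equal(unname(flip[a$direction]), b$direction)
})

test_that("planted imbalance is detected with the right direction", {
  set.seed(53)
  al <- rbind(allelic_frame(300, 0.8), allelic_frame(300, 0.5))
  al$gene_id <- rep(sprintf("g%05d", 1:600), each = 3)
  r <- ase_test(al, "leaf")
  biased <- r$gene_id %in% sprintf("g%05d", 1:300)
  expect_gt(mean(r$is_aseg[biased]), 0.8)
  expect_true(all(r$direction[biased & r$is_aseg] == "maternal"))
})

test_that("cross-tissue patterns follow the two-tissue intersection rule", {
  res1 <- data.frame(gene_id = c("a", "b", "c", "d"), tissue = "leaf",
                     is_aseg = c(TRUE, TRUE, TRUE, FALSE),
                     direction = c("maternal", "paternal", "maternal",
                                   "none"))
  res2 <- data.frame(gene_id = c("a", "b", "c", "d"), tissue = "panicle",
                     is_aseg = c(TRUE, TRUE, FALSE, TRUE),
                     direction = c("maternal", "maternal", "none",
                                   "paternal"))
  out <- classify_aseg_patterns(res1, res2)
  expect_equal(out$patterns$pattern[out$patterns$gene_id == "a"],
               "consistent_maternal")
  expect_equal(out$patterns$pattern[out$patterns$gene_id == "b"],
               "shift_direction")
  # ASEG in one tissue only: excluded
  expect_false("c" %in% out$patterns$gene_id)
  expect_false("d" %in% out$patterns$gene_id)
  expect_equal(out$counts$n[out$counts$pattern == "consistent_maternal"], 1L)
  expect_equal(out$counts$n[out$counts$pattern == "shift_direction"], 1L)
})
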