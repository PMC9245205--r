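test_that("the activity rule counts replicates with at least two reads", {
  mat <- rbind(gA = c(2, 2, 0), gB = c(1, 1, 1), gC = c(5, 0, 0),
               gD = c(2, 2, 2))
  colnames(mat) <- c("r1", "r2", "r3")
  act <- call_active_genes(mat, c("r1", "r2", "r3"))
  expect_setequal(act, c("gA", "gD"))
  expect_error(call_active_genes(mat, "r1"),
               class = "heteroseq_schema_error")
})

test_that("median-of-ratios size factors behave on the printed cases", {
  m <- matrix(rpois(40, 50), 10, 4,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4)))
  m_same <- m[, c(1, 1, 1)]
  colnames(m_same) <- c("a", "b", "c")
  expect_equal(unname(size_factors(m_same)), c(1, 1, 1))
  one <- matrix(c(10, 20), 1, 2, dimnames = list("g", c("a", "b")))
  expect_equal(unname(size_factors(one)), c(10, 20) / sqrt(200),
               tolerance = 1e-6)
  # rescaling one column rescales its factor relative to the others
  # (factors are defined up to a common scale: the geometric-mean
  # reference moves with the data, so only factor ratios are meaningful)
  two <- rbind(g1 = c(10, 20), g2 = c(30, 15))
  colnames(two) <- c("a", "b")
  sf0 <- size_factors(two)
  two2 <- two
  two2[, "b"] <- two2[, "b"] * 3L
  sf1 <- size_factors(two2)
  expect_equal(sf1[["b"]] / sf1[["a"]], 3 * sf0[["b"]] / sf0[["a"]])
  expect_error(size_factors(rbind(c(0, 1), c(1, 0))),
               class = "heteroseq_schema_error")
})

test_that("dispersion estimates recover the truth and clamp at zero", {
  set.seed(21)
  pois <- matrix(rpois(2000 * 6, 200), 2000,
                 dimnames = list(sprintf("g%d", 1:2000), sprintf("s%d", 1:6)))
  dp <- estimate_dispersion(pois, list(1:3, 4:6))
  expect_lt(mean(dp$alpha, na.rm = TRUE), 0.02)
  nb <- matrix(rnbinom(2000 * 6, mu = 500, size = 1 / 0.2), 2000,
               dimnames = list(sprintf("g%d", 1:2000), sprintf("s%d", 1:6)))
  dn <- estimate_dispersion(nb, list(1:6))
  expect_gt(median(dn$alpha, na.rm = TRUE), 0.1)
  expect_lt(median(dn$alpha, na.rm = TRUE), 0.3)
  # underdispersed gene clamps the raw estimate to 0
  under <- matrix(rep(c(9L, 10L, 11L), 40), nrow = 1)
  under <- rbind(under, under + 5L)
  colnames(under) <- sprintf("s%d", 1:120)
  rownames(under) <- c("g1", "g2")
  du <- estimate_dispersion(under, list(1:120), sf = rep(1, 120))
  expect_equal(du$alpha_raw, c(0, 0))
  # an all-zero gene is excluded with NA
  z <- rbind(g0 = rep(0L, 6), g1 = rep(10L, 6))
  colnames(z) <- sprintf("s%d", 1:6)
  dz <- estimate_dispersion(z, list(1:3, 4:6), sf = rep(1, 6))
  expect_true(is.na(dz$alpha[1]))
})

test_that("literally equal groups give log2fc 0, stat 0, p 1", {
  mat <- rbind(gA = c(5L, 9L, 13L, 5L, 9L, 13L),
               gB = c(100L, 80L, 90L, 100L, 80L, 90L))
  colnames(mat) <- sprintf("s%d", 1:6)
  de <- nb_wald_test(mat, 1:3, 4:6, sf = rep(1, 6))
  expect_equal(de$log2fc, c(0, 0))
  expect_equal(de$stat, c(0, 0))
  expect_equal(de$p, c(1, 1))
  expect_false(any(de$is_deg))
})

test_that("swapping the group labels negates log2fc and keeps p", {
  set.seed(31)
  mat <- nb_matrix(300, 150, 300, alpha = 0.05)
  a <- nb_wald_test(mat, 1:3, 4:6)
  b <- nb_wald_test(mat, 4:6, 1:3)
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p, b$p)
})

test_that("rescaling one sample's counts is absorbed by the size factors", {
  # rescaling one column rescales every normalized count by a common
  # constant (7^(1/6) here, because the geometric-mean reference moves);
  # fold changes are exactly invariant, while the Wald statistic moves
  # only through the O(1/depth) Poisson part of the variance
  set.seed(32)
  mat <- nb_matrix(400, 200, 200, alpha = 0.05)
  de0 <- nb_wald_test(mat, 1:3, 4:6)
  mat2 <- mat
  mat2[, 2] <- mat2[, 2] * 7L
  de1 <- nb_wald_test(mat2, 1:3, 4:6)
  expect_equal(de0$log2fc, de1$log2fc, tolerance = 1e-12)
  expect_equal(de0$stat, de1$stat, tolerance = 1e-3)
  expect_equal(de0$p, de1$p, tolerance = 1e-3)
  expect_identical(de0$is_deg, de1$is_deg)
  # with frozen dispersions and factors spanning the rescale, results are
  # exactly invariant
  sf <- size_factors(mat)
  sf2 <- sf
  sf2[2] <- sf2[2] * 7
  alpha <- estimate_dispersion(mat, list(1:3, 4:6), sf = sf)$alpha
  a <- nb_wald_test(mat, 1:3, 4:6, sf = sf, dispersion = alpha)
  b <- nb_wald_test(mat2, 1:3, 4:6, sf = sf2, dispersion = alpha)
  expect_equal(a$stat, b$stat, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("BH-adjusted values are monotone and never below p", {
  set.seed(33)
  mat <- nb_matrix(500, 100, 100, alpha = 0.1)
  de <- nb_wald_test(mat, 1:3, 4:6)
  ok <- !is.na(de$p)
  expect_true(all(de$fdr[ok] >= de$p[ok] - 1e-12))
  o <- order(de$p[ok])
  expect_true(all(diff(de$fdr[ok][o]) >= -1e-12))
})

test_that("the Wald p matches a brute-force profile-likelihood oracle", {
  set.seed(34)
  for (i in 1:5) {
    alpha <- c(0.02, 0.1, 0.2, 0.05, 0.15)[i]
    ya <- rnbinom(3, mu = 120, size = 1 / alpha)
    yb <- rnbinom(3, mu = 120 * c(1, 2, 4, 1, 3)[i], size = 1 / alpha)
    mat <- matrix(c(ya, yb), 1, dimnames = list("g", sprintf("s%d", 1:6)))
    de <- nb_wald_test(mat, 1:3, 4:6, sf = rep(1, 6), dispersion = alpha)
    orc <- nb_wald_oracle(ya, yb, alpha)
    expect_equal(de$p, orc$p, tolerance = 0.01)
  }
})

test_that("the NB test broadly agrees with an established DE package", {
  set.seed(35)
  ng <- 200
  mu2 <- rep(c(200, 800), c(150, 50))
  mat <- cbind(matrix(rnbinom(ng * 3, mu = 200, size = 20), ng),
               matrix(rnbinom(ng * 3, mu = mu2, size = 20), ng))
  rownames(mat) <- sprintf("g%03d", 1:ng)
  colnames(mat) <- sprintf("s%d", 1:6)
  ours <- nb_wald_test(mat, 1:3, 4:6)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      mat, data.frame(group = factor(rep(c("A", "B"), each = 3))), ~group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds)
  })
  keep <- !is.na(res$pvalue) & !is.na(ours$p)
  expect_gt(cor(ours$log2fc[keep], res$log2FoldChange[keep]), 0.95)
  strong <- which(res$padj < 1e-6 & !is.na(res$padj))
  expect_gt(mean(ours$fdr[strong] < 0.01), 0.9)
})

test_that("sample correlation removes depth and separates shared signal", {
  set.seed(36)
  mu <- rlnorm(800, log(100), 1)
  mk <- function() rnbinom(800, mu = mu, size = 10)
  mat <- cbind(a = mk(), b = mk(), c = rnbinom(800, mu = rev(mu), size = 10))
  mat <- cbind(mat, a2x = mat[, "a"] * 2L)
  rownames(mat) <- sprintf("g%d", 1:800)
  r2 <- sample_correlation(mat)
  expect_equal(unname(diag(r2)), rep(1, 4))
  # a scaled copy of a sample is perfectly correlated after normalization
  expect_equal(r2["a", "a2x"], 1, tolerance = 1e-12)
  # replicates sharing planted means beat samples with scrambled means
  expect_gt(r2["a", "b"], r2["a", "c"])
})
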