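null_counts <- function(nf = 300, n = c(3, 3), mu = 100, alpha = 0.1,
                        seed = 61) {
  simulate_counts(sprintf("f%04d", seq_len(nf)), n, lfc = 0,
                  baseline_mean = mu, nb_dispersion = alpha,
                  seed = seed)$counts
}

test_that("size factors equal the literal median-of-ratios double loop", {
  cm <- null_counts(nf = 200, seed = 62)
  sf <- size_factors(cm)
  expect_equal(unname(sf), size_factors_brute_force(cm$counts),
               tolerance = 1e-12)

  # identical columns -> equal factors; doubling one column doubles its
  # factor
  m <- matrix(rep(c(5, 10, 20, 40), 3), ncol = 3)
  expect_equal(unname(size_factors(m)), rep(1, 3))
  m2 <- cbind(m, m[, 1] * 2)
  sf2 <- size_factors(m2)
  expect_equal(sf2[4] / sf2[1], 2, tolerance = 1e-12)

  # no feature positive everywhere -> informative error
  z <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(size_factors(z), "nonzero counts in all samples")
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  # Poisson data, 25 + 25 samples: estimates concentrate near zero
  cmp <- null_counts(nf = 400, n = c(25, 25), alpha = 0, seed = 63)
  dp <- estimate_dispersion(cmp)
  expect_lt(median(dp), 0.05)

  # NB alpha = 0.5 recovered at 25 + 25
  cmn <- null_counts(nf = 400, n = c(25, 25), alpha = 0.5, seed = 64)
  dn <- estimate_dispersion(cmn)
  expect_gt(median(dn), 0.3)
  expect_lt(median(dn), 0.8)

  # under-dispersed feature floored at 0 in the raw estimate
  m <- matrix(rep(c(100, 100, 100, 100, 100, 100), 50), ncol = 6,
              byrow = TRUE)
  cm0 <- count_matrix(m, rep(c("low", "high"), each = 3))
  expect_true(all(attr(estimate_dispersion(cm0), "raw") == 0))
})

test_that("NB Wald test is calibrated, powered and symmetric", {
  # reduced-scale null calibration (full scale in the acceptance suite)
  cm <- null_counts(nf = 1000, seed = 65)
  res <- diff_test(cm, "rna")
  t1 <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gt(t1, 0.02)
  expect_lt(t1, 0.08)

  # identical counts in all samples: log2FC 0, p ~ 1
  set.seed(70)
  m <- rbind(rep(7, 6), matrix(rpois(30 * 6, 50), ncol = 6))
  rownames(m) <- paste0("g", 0:30)
  cmi <- count_matrix(m, rep(c("low", "high"), each = 3))
  sf1 <- rep(1, 6)
  r1 <- nb_wald_test(cmi, sf1, rep(0.1, 31))
  expect_equal(r1$log2fc[1], 0, tolerance = 1e-6)
  expect_equal(r1$p[1], 1, tolerance = 1e-6)

  # planted lfc = 2 at mean 200 embedded in a null background: detected
  # with the correct sign in >= 90% of replicate features
  lfc <- rep(0, 800)
  lfc[1:80] <- 2 * rep(c(1, -1), 40)
  sp <- simulate_counts(sprintf("g%04d", 1:800), c(3, 3), lfc = lfc,
                        baseline_mean = 200, nb_dispersion = 0.05,
                        seed = 66)
  rp <- diff_test(sp$counts, "rna")
  det <- rp$p < 0.05 & sign(rp$log2fc) == sign(lfc)
  expect_gte(mean(det[1:80], na.rm = TRUE), 0.9)

  # group-swap antisymmetry: negated log2FC, unchanged p
  cm2 <- null_counts(nf = 100, seed = 67)
  swapped <- count_matrix(cm2$counts,
                          factor(cm2$groups, levels = rev(levels(cm2$groups))))
  a <- diff_test(cm2, "rna")
  b <- diff_test(swapped, "rna")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-8)
  expect_equal(a$p, b$p, tolerance = 1e-8)

  # size-factor equivariance: tripling one sample's counts is absorbed by
  # its re-estimated factor up to the genuinely changed Poisson
  # information of that sample (a 3x-deeper sample carries more weight in
  # the GLM and a smaller shot-noise term in the dispersion moment), so
  # estimates agree closely but not bitwise
  cm3 <- null_counts(nf = 150, seed = 68)
  m3 <- cm3$counts
  m3[, 2] <- m3[, 2] * 3
  cm3s <- count_matrix(m3, cm3$groups)
  a3 <- diff_test(cm3, "rna")
  b3 <- diff_test(cm3s, "rna")
  # the *relative* factor of the scaled sample rises by exactly c (the
  # absolute factors shift by c^(1/n) through the geometric means)
  sf3 <- size_factors(cm3s)
  sf0 <- size_factors(cm3)
  expect_equal(unname((sf3[2] / sf3[1]) / (sf0[2] / sf0[1])), 3,
               tolerance = 1e-12)
  expect_lt(max(abs(a3$log2fc - b3$log2fc)), 0.05)
  expect_lt(max(abs(a3$p - b3$p)), 0.05)
  expect_gte(mean(a3$status == b3$status), 0.99)
})

test_that("classification presets apply the documented thresholds", {
  res <- data.frame(
    feature = c("a", "b", "c", "d"),
    log2fc = c(1.2, 0.9, -1.0, 0.58),
    p = c(0.01, 0.001, 0.05, 0.049)
  )
  rna <- classify_features(res, "rna")
  expect_identical(rna$status, c("up", "ns", "ns", "ns"))
  atac <- classify_features(res, "atac")
  # 0.9 >= 0.58 -> up under the accessibility preset; p = 0.05 stays ns
  # (strictly below required); lfc exactly 0.58 with p < 0.05 -> up
  expect_identical(atac$status, c("up", "up", "ns", "up"))
  expect_error(classify_features(res, "chip"))
})

test_that("descriptive pseudo-count fold change stays finite for all-zero
           groups", {
  m <- rbind(c(0, 0, 0, 40, 50, 60), c(10, 12, 9, 11, 10, 12))
  rownames(m) <- c("gz", "gn")
  cm <- count_matrix(m, factor(rep(c("low", "high"), each = 3),
                               levels = c("low", "high")))
  res <- nb_wald_test(cm, rep(1, 6), rep(0.1, 2))
  expect_true(is.finite(res$log2fc_pseudo[1]))
  expect_gt(res$log2fc_pseudo[1], 5)
})

test_that("NB pipeline agrees in direction with an independent DESeq2 run
           on strong planted signal", {
  skip_if_not_installed("DESeq2")
  lfc <- rep(0, 120)
  lfc[1:12] <- c(rep(3, 6), rep(-3, 6))
  sim <- simulate_counts(sprintf("g%03d", 1:120), c(4, 4), lfc = lfc,
                         baseline_mean = 300, nb_dispersion = 0.05,
                         seed = 69)
  ours <- diff_test(sim$counts, "rna")
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$counts$counts,
      data.frame(group = sim$counts$groups),
      ~group
    )
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    dr <- DESeq2::results(dds, contrast = c("group", "high", "low"))
  })
  ours_up <- ours$feature[ours$status == "up"]
  deseq_up <- rownames(dr)[!is.na(dr$pvalue) & dr$pvalue < 0.05 &
                             dr$log2FoldChange >= 1]
  # both routes must recover the strong planted truth
  expect_true(all(sprintf("g%03d", 1:6) %in% ours_up))
  expect_true(all(sprintf("g%03d", 1:6) %in% deseq_up))
  # and the planted log2FCs agree between routes
  i <- match(sprintf("g%03d", 1:12), ours$feature)
  j <- match(sprintf("g%03d", 1:12), rownames(dr))
  expect_lt(max(abs(ours$log2fc[i] - dr$log2FoldChange[j])), 0.6)
})
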