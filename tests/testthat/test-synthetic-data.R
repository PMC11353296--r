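test_that("genotype simulation respects allele-draw moments and determinism", {
  # degenerate frequency: every allele draw fixed -> all dosages 2
  cfg <- sim_config(n_samples = 10, n_variants = 5, n_chromosomes = 1,
                    seed = 1)
  cfg$maf_range <- c(1, 1)   # degenerate, tolerated by the generator only
  G <- simulate_genotypes(cfg)
  expect_true(all(G$dosages == 2))

  # determinism: identical config + seed -> bit-identical matrices
  cfg2 <- sim_config(n_samples = 30, n_variants = 50, seed = 7)
  expect_identical(simulate_genotypes(cfg2)$dosages,
                   simulate_genotypes(cfg2)$dosages)

  # binomial moment oracle: mean dosage ~ 2f with SE sqrt(2f(1-f)/n);
  # many variants so the empirical coverage estimate is tight around its
  # nominal 95.45%
  cfg3 <- sim_config(n_samples = 2000, n_variants = 10000,
                     maf_range = c(0.3, 0.3), seed = 3)
  G3 <- simulate_genotypes(cfg3)
  tol <- 2 * sqrt(2 * 0.3 * 0.7 / 2000)
  frac <- mean(abs(colMeans(G3$dosages) - 0.6) <= tol)
  expect_gte(frac, 0.95)

  # positions strictly increasing per chromosome, contiguous chromosomes
  v <- G3$variants
  for (ch in unique(v$chrom)) {
    expect_true(all(diff(v$pos[v$chrom == ch]) > 0))
  }
  expect_true(all(diff(as.integer(v$chrom)) >= 0))
})

test_that("invalid maf_range is rejected naming the violated bound", {
  expect_error(simulate_genotypes(sim_config(maf_range = c(0, 0.5))),
               "lower bound")
  expect_error(sim_config(maf_range = c(0.05, 0.7)), "upper bound")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "exceeds")
})

test_that("phenotype simulation composes variance as configured", {
  # h2 = 0, no causal effects: y independent of every genotype column
  cfg <- sim_config(n_samples = 400, n_variants = 300, h2 = 0, seed = 5)
  G <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(G, cfg)
  r <- abs(cor(ph$phenotype$fcr, G$dosages))
  expect_gte(mean(r < 4 / sqrt(400)), 0.99)

  # single causal variant, h2 = 0: OLS slope recovers beta within 3 SE
  cfg2 <- sim_config(n_samples = 600, n_variants = 100, h2 = 0,
                     causal_spec = data.frame(index = 10, effect = 1),
                     seed = 6)
  G2 <- simulate_genotypes(cfg2)
  ph2 <- simulate_phenotype(G2, cfg2)
  fit <- summary(lm(ph2$phenotype$fcr ~ G2$dosages[, 10]))
  est <- coef(fit)[2, ]
  expect_lt(abs(est["Estimate"] - ph2$truth$causal_variants$effect),
            3 * est["Std. Error"])

  # variance composition: sample var of y within 15% of sigma2_total
  cfg3 <- sim_config(n_samples = 1000, n_variants = 500, h2 = 0.4,
                     causal_spec = data.frame(index = 3, var_explained = 0.05),
                     seed = 8)
  G3 <- simulate_genotypes(cfg3)
  ph3 <- simulate_phenotype(G3, cfg3)
  expect_lt(abs(var(ph3$phenotype$fcr) - 1), 0.15)

  # causal index out of range rejected
  bad <- cfg3
  bad$causal_spec <- data.frame(index = 501, effect = 1)
  expect_error(simulate_phenotype(G3, bad), "out of range")
})

test_that("growth records honor noise, outlier fraction and seed", {
  g0 <- simulate_growth_records(20, noise_sd = 0, outlier_fraction = 0,
                                seed = 2)
  # noiseless records are perfectly collinear per animal
  fits <- fit_growth_lines(g0$records)
  expect_true(all(fits$resid_sd < 1e-10))
  expect_identical(g0$truth$outliers, character(0))

  g1 <- simulate_growth_records(500, noise_sd = 1, outlier_fraction = 0.05,
                                seed = 3)
  expect_equal(length(g1$truth$outliers), 25)

  g2 <- simulate_growth_records(500, noise_sd = 1, outlier_fraction = 0.05,
                                seed = 3)
  expect_identical(g1$records, g2$records)

  expect_error(simulate_growth_records(10, noise_sd = -1), "noise_sd")
  expect_error(simulate_growth_records(10, days = 100), "at least 2")
})

test_that("regulatory landscape plants containment-valid links", {
  cfg <- sim_config(n_samples = 50, n_variants = 200, n_chromosomes = 3,
                    n_tads = 9, n_peaks = 40, n_genes = 30,
                    causal_spec = data.frame(index = c(30, 150), effect = 0.5),
                    planted_links = data.frame(variant = c(30, 150),
                                               lfc = c(2, -2)),
                    seed = 11)
  G <- simulate_genotypes(cfg)
  land <- simulate_regulatory_landscape(cfg, G)
  links <- land$truth$expected_links
  expect_equal(nrow(links), 2)
  for (i in 1:2) {
    v <- G$variants[links$variant[i], ]
    pk <- land$peaks[land$peaks$id == links$peak_id[i], ]
    gn <- land$genes[land$genes$id == links$gene_id[i], ]
    td <- land$tads[land$tads$id == links$tad_id[i], ]
    # SNP in peak (1-based pos vs half-open interval)
    expect_true(pk$start < v$pos && v$pos <= pk$end)
    # peak and gene inside the same TAD
    expect_true(td$start <= pk$start && pk$end <= td$end)
    expect_true(td$start <= gn$start && gn$end <= td$end)
    expect_identical(pk$chrom, v$chrom)
  }

  # O(n^2) overlap oracle: TADs non-overlapping per chromosome
  tads <- land$tads
  for (i in seq_len(nrow(tads))) {
    for (j in seq_len(nrow(tads))) {
      if (i == j || tads$chrom[i] != tads$chrom[j]) next
      expect_true(tads$end[i] <= tads$start[j] ||
                    tads$end[j] <= tads$start[i])
    }
  }

  # zero planted links: landscape still emitted, no expected links
  cfg0 <- sim_config(n_samples = 50, n_variants = 200, n_chromosomes = 3,
                     n_tads = 6, n_peaks = 10, n_genes = 10, seed = 12)
  land0 <- simulate_regulatory_landscape(cfg0, simulate_genotypes(cfg0))
  expect_null(land0$truth$expected_links)
  expect_equal(nrow(land0$peaks), 10)
})

test_that("count simulation matches Poisson and NB moment oracles", {
  # planted null layer: truth lists no DE features
  s0 <- simulate_counts(paste0("f", 1:10), c(3, 3), lfc = 0, seed = 1)
  expect_equal(nrow(s0$truth$de_features), 0)

  # alpha = 0 degenerates to Poisson: variance ~ mean
  sp <- simulate_counts(paste0("f", 1:2000), c(3, 2), lfc = 0,
                        baseline_mean = 100, nb_dispersion = 0, seed = 2)
  draws <- as.vector(sp$counts$counts)
  expect_lt(abs(var(draws) - 100) / 100, 0.10)

  # NB: variance ~ mu + alpha mu^2
  sn <- simulate_counts(paste0("f", 1:2000), c(3, 2), lfc = 0,
                        baseline_mean = 100, nb_dispersion = 0.5, seed = 3)
  vexp <- 100 + 0.5 * 100^2
  expect_lt(abs(var(as.vector(sn$counts$counts)) - vexp) / vexp, 0.15)

  # fold change applied to the high group through size-factor-scaled means
  s2 <- simulate_counts("f1", c(200, 200), lfc = 1, baseline_mean = 1000,
                        seed = 4)
  cm <- s2$counts
  ratio <- mean(cm$counts[1, cm$groups == "high"]) /
    mean(cm$counts[1, cm$groups == "low"])
  expect_lt(abs(ratio - 2), 0.15)

  expect_error(simulate_counts("f1", c(3, 3), baseline_mean = -1),
               "baseline_mean")
})

test_that("mask/perturb produces the configured discordance", {
  G <- small_genotypes(100, 100, seed = 21)
  # error_rate 0: pseudo-imputed identical to truth
  mp0 <- mask_and_perturb_genotypes(G, missing_rate = 0.1, error_rate = 0,
                                    seed = 1)
  expect_identical(mp0$imputed$dosages, G$dosages)
  # binomial count oracle on 10,000 entries at 2%
  mp <- mask_and_perturb_genotypes(G, missing_rate = 0, error_rate = 0.02,
                                   seed = 2)
  n_disc <- sum(mp$imputed$dosages != G$dosages)
  expect_lt(abs(n_disc - 200), 4 * sqrt(10000 * 0.02 * 0.98))
  expect_true(all(mp$imputed$dosages %in% 0:2))
  # missing_rate 1: chip matrix entirely missing
  mp1 <- mask_and_perturb_genotypes(G, missing_rate = 1, error_rate = 0,
                                    seed = 3)
  expect_true(all(is.na(mp1$chip$dosages)))
})
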