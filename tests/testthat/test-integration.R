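test_that("SNP-in-region overlap honors half-open boundary semantics and
           the brute-force oracle", {
  reg <- interval_set(data.frame(chrom = "1", start = 100, end = 200,
                                 id = "r1"))
  v <- data.frame(id = paste0("s", 1:4), chrom = "1",
                  pos = c(100, 101, 200, 201))
  ov <- snps_in_regions(v, reg)
  expect_identical(sort(ov$variant_id), c("s2", "s3"))

  # random instances match the O(nm) double loop exactly
  set.seed(71)
  for (rep in 1:3) {
    vr <- data.frame(
      id = sprintf("v%04d", 1:1000),
      chrom = as.character(sample(1:3, 1000, TRUE)),
      pos = sample(1:5000, 1000, TRUE)
    )
    st <- sample(0:4900, 200, TRUE)
    rr <- interval_set(data.frame(
      chrom = as.character(sample(1:3, 200, TRUE)),
      start = st, end = st + sample(1:300, 200, TRUE),
      id = sprintf("r%04d", 1:200)
    ))
    expect_identical(pair_key(snps_in_regions(vr, rr)),
                     pair_key(overlap_brute_force(vr, rr)))
  }

  # empty region set -> empty result; malformed intervals rejected at load
  expect_equal(nrow(snps_in_regions(v, reg[0, ])), 0)
  expect_error(interval_set(data.frame(chrom = "1", start = 5, end = 5)),
               "malformed")
})

test_that("TAD assignment requires full containment", {
  tads <- interval_set(data.frame(chrom = "1", start = c(0, 1000),
                                  end = c(1000, 2000),
                                  id = c("t1", "t2")))
  # 0-based position 1000 is 1-based 1001 -> second TAD
  expect_identical(assign_tad(data.frame(chrom = "1", pos = 1001), tads),
                   "t2")
  expect_identical(assign_tad(data.frame(chrom = "1", pos = 1000), tads),
                   "t1")
  # gap position unassigned
  tads2 <- interval_set(data.frame(chrom = "1", start = c(0, 1500),
                                   end = c(1000, 2000),
                                   id = c("t1", "t2")))
  expect_true(is.na(assign_tad(data.frame(chrom = "1", pos = 1200), tads2)))
  # straddling gene unassigned; contained gene assigned
  genes <- data.frame(chrom = "1", start = c(900, 100), end = c(1100, 300))
  expect_identical(assign_tad(genes, tads), c(NA_character_, "t1"))
  # overlapping TADs rejected with offenders listed
  bad <- interval_set(data.frame(chrom = "1", start = c(0, 500),
                                 end = c(1000, 1500), id = c("a", "b")))
  expect_error(validate_tads(bad), "overlapping TADs.*a/b")
})

test_that("genotype-class comparison behaves at the degenerate and planted
           extremes", {
  pheno <- data.frame(animal = sprintf("a%02d", 1:90),
                      fcr = rep(2.5, 90))
  dos <- setNames(rep(0:2, each = 30), pheno$animal)
  flat <- genotype_phenotype_compare(dos, pheno)
  expect_equal(flat$p, 1)
  expect_identical(flat$note, "zero_variance")

  # class 2 shifted by +3 SD, n = 30 per class -> tiny p
  set.seed(72)
  pheno2 <- pheno
  pheno2$fcr <- rnorm(90) + ifelse(dos == 2, 3, 0)
  shifted <- genotype_phenotype_compare(dos, pheno2)
  expect_lt(shifted$p, 1e-3)
  expect_equal(sum(shifted$summary$n), 90)

  # permuted trait: p approximately uniform over seeds
  set.seed(73)
  pnull <- replicate(200, {
    genotype_phenotype_compare(dos, transform(pheno2, fcr = sample(fcr)))$p
  })
  expect_lt(suppressWarnings(ks.test(pnull, "punif")$statistic), 0.1)

  # a single class present: summaries only, p NA with a reason
  one <- genotype_phenotype_compare(setNames(rep(1, 90), pheno$animal),
                                    pheno2)
  expect_true(is.na(one$p))
  expect_identical(one$note, "insufficient_classes")

  # kruskal option agrees qualitatively
  kr <- genotype_phenotype_compare(dos, pheno2, method = "kruskal")
  expect_lt(kr$p, 1e-3)
})

test_that("the hand-enumerated toy instance yields exactly two links", {
  assoc <- data.frame(id = c("vSig", "vNull"), chrom = "1",
                      pos = c(150L, 900L), p = c(1e-9, 0.5))
  attr(assoc, "threshold") <- 1e-5
  peaks <- interval_set(data.frame(chrom = "1", start = 100, end = 300,
                                   id = "pkUp"))
  peaks$status <- "up"; peaks$log2fc <- 2; peaks$tissue <- "duodenum"
  tads <- interval_set(data.frame(chrom = "1", start = 0, end = 1000,
                                  id = "tad1"))
  genes <- interval_set(data.frame(chrom = "1", start = c(400, 600),
                                   end = c(500, 700), id = c("gA", "gB")))
  de <- data.frame(feature = c("gA", "gB"), log2fc = c(2.5, 0.1),
                   p = c(0.001, 0.9))
  de <- classify_features(de, "rna")
  links <- link_variants_to_genes(assoc, peaks, tads, genes,
                                  list(duodenum = de))
  expect_equal(nrow(links), 2)
  expect_setequal(links$gene_id, c("gA", "gB"))
  expect_true(all(links$variant_id == "vSig"))
  expect_identical(links$gene_status_duodenum[links$gene_id == "gA"], "up")

  ranked <- prioritize(links)
  expect_identical(ranked$gene_id[1], "gA")   # DE evidence ranks first
  expect_identical(ranked$rank, 1:2)

  # no significant variants -> empty list
  a0 <- transform(assoc, p = c(0.5, 0.5))
  attr(a0, "threshold") <- 1e-5
  expect_equal(nrow(link_variants_to_genes(a0, peaks, tads, genes,
                                           list(duodenum = de))), 0)

  # significant variant inside an ns peak only -> zero links
  pk_ns <- peaks
  pk_ns$status <- "ns"
  expect_equal(nrow(link_variants_to_genes(assoc, pk_ns, tads, genes,
                                           list(duodenum = de))), 0)
})

test_that("ranking is deterministic and permutation-invariant", {
  links <- data.frame(
    variant_id = "v1", chrom = "1", pos = 10L, gwas_p = 1e-8,
    peak_id = "p1", peak_status = "up", peak_tissue = "duodenum",
    tad_id = "t1", gene_id = c("g1", "g2", "g3"),
    gene_status_duodenum = c("ns", "up", "ns"),
    gene_log2fc_duodenum = c(0, 2, 0.1),
    gene_status_muscle = c("up", "ns", "ns"),
    gene_log2fc_muscle = c(1.5, 0, 0),
    gp_p = c(0.5, 0.5, 0.5),
    stringsAsFactors = FALSE
  )
  r1 <- prioritize(links)
  # DE in the peak's own tissue > DE elsewhere > ns
  expect_identical(r1$gene_id, c("g2", "g1", "g3"))
  expect_identical(r1$evidence_rank, c(0L, 1L, 2L))
  set.seed(74)
  r2 <- prioritize(links[sample(3), ])
  expect_identical(r2$gene_id, r1$gene_id)

  # significance stars follow the reporting convention
  links$gp_p <- c(5e-5, 5e-4, 0.2)
  stars <- prioritize(links)
  expect_identical(sort(stars$gp_stars), sort(c("****", "***", "")))
})

test_that("a planted link is recovered end to end at a recoverable effect
           size", {
  # mechanics check at a deliberately strong effect; the study-scale
  # stochastic recovery rate lives in the acceptance suite
  cfg <- sim_config(
    n_samples = 400, n_variants = 1000, n_chromosomes = 5,
    h2 = 0.2, causal_spec = data.frame(index = 300, var_explained = 0.15),
    planted_links = data.frame(variant = 300, lfc = 2.5),
    n_genes = 80, n_peaks = 120, n_tads = 15, seed = 75
  )
  d <- simulate_dataset(cfg)
  r <- run_analysis(d, list(covariates = c("pen", "birth_month")))
  tl <- d$truth$expected_links
  pair <- paste(r$report$variant_id, r$report$gene_id)
  expect_true(paste(tl$variant_id, tl$gene_id) %in% pair)
  expect_identical(pair[1], paste(tl$variant_id, tl$gene_id))
})
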