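#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort: genotypes, phenotype
#' architecture, regulatory landscape and count layers. Defaults describe a
#' small five-chromosome genome so that leave-one-chromosome-out analyses
#' run in seconds while still exercising every code path.
#'
#' @param n_samples number of animals.
#' @param n_variants number of biallelic variants, assigned to chromosomes
#'   contiguously.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param maf_range allele-frequency range `(lo, hi]` from which per-variant
#'   frequencies are drawn uniformly; must lie in (0, 0.5].
#' @param h2 narrow-sense heritability of the polygenic background, in [0, 1).
#' @param sigma2_total total phenotypic variance of the genetic + residual
#'   part of the trait (fixed-effect variance comes on top).
#' @param causal_spec data.frame with columns `index` (variant column index)
#'   and either `effect` (per-allele effect in phenotype-SD units) or
#'   `var_explained` (fraction of `sigma2_total`; the effect is then derived
#'   from the realized allele frequency).
#' @param n_genes,n_peaks,n_tads sizes of the regulatory landscape.
#' @param planted_links data.frame with columns `variant` (causal variant
#'   index, must appear in `causal_spec`) and `lfc` (planted log2 fold
#'   change for the linked peak and gene).
#' @param nb_dispersion negative-binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`); 0 gives Poisson counts.
#' @param group_sizes list with elements `rna` and `atac`: animals per
#'   phenotype-extreme group for each count layer.
#' @param seed integer master seed; every generator derives a named
#'   substream from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500, n_variants = 5000, n_chromosomes = 5,
                       chrom_length = 2e6, maf_range = c(0.05, 0.5),
                       h2 = 0.3, sigma2_total = 1,
                       causal_spec = NULL,
                       n_genes = 200, n_peaks = 300, n_tads = 25,
                       planted_links = NULL,
                       nb_dispersion = 0.05,
                       group_sizes = list(rna = 3, atac = 2),
                       seed = 1) {
  check_range(n_samples, "n_samples", lo = 2)
  check_range(n_variants, "n_variants", lo = 1)
  check_range(n_chromosomes, "n_chromosomes", lo = 1)
  check_maf_range(maf_range)
  check_range(h2, "h2", lo = 0, hi = 1, hi_open = TRUE)
  check_range(sigma2_total, "sigma2_total", lo = 0, lo_open = TRUE)
  check_range(nb_dispersion, "nb_dispersion", lo = 0)
  if (!is.null(causal_spec)) {
    causal_spec <- as.data.frame(causal_spec)
    stopifnot("index" %in% names(causal_spec))
    if (any(causal_spec$index < 1 | causal_spec$index > n_variants)) {
      stop("causal variant index out of range 1..", n_variants)
    }
  }
  if (!is.null(planted_links)) {
    planted_links <- as.data.frame(planted_links)
    stopifnot(all(c("variant", "lfc") %in% names(planted_links)))
    if (is.null(causal_spec) ||
        !all(planted_links$variant %in% causal_spec$index)) {
      stop("every planted link's variant must appear in causal_spec")
    }
  }
  structure(list(
    n_samples = n_samples, n_variants = n_variants,
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    maf_range = maf_range, h2 = h2, sigma2_total = sigma2_total,
    causal_spec = causal_spec, n_genes = n_genes, n_peaks = n_peaks,
    n_tads = n_tads, planted_links = planted_links,
    nb_dispersion = nb_dispersion, group_sizes = group_sizes,
    seed = as.integer(seed)
  ), class = "sim_config")
}

check_maf_range <- function(maf_range, hi_max = 0.5) {
  if (length(maf_range) != 2 || !all(is.finite(maf_range))) {
    stop("maf_range must be two finite allele frequencies")
  }
  if (maf_range[1] <= 0) stop("maf_range lower bound must be > 0")
  if (maf_range[2] > hi_max) {
    stop("maf_range upper bound must be <= ", hi_max)
  }
  if (maf_range[1] > maf_range[2]) stop("maf_range lower bound exceeds upper")
  invisible(maf_range)
}

#' Default study-scale configuration with one planted causal link
#'
#' Five chromosomes of 2 Mb, 500 animals, 5,000 variants, polygenic
#' heritability 0.3, and a single causal variant on chromosome 2 explaining
#' 5\% of the trait variance, planted inside a differential ATAC peak whose
#' TAD contains a differentially expressed gene (log2FC = 2 for both).
#'
#' @param seed master seed.
#' @return a `sim_config`.
#' @export
default_sim_config <- function(seed = 1) {
  sim_config(
    n_samples = 500, n_variants = 5000, n_chromosomes = 5,
    chrom_length = 2e6, maf_range = c(0.05, 0.5), h2 = 0.3,
    causal_spec = data.frame(index = 1500, var_explained = 0.05),
    n_genes = 200, n_peaks = 300, n_tads = 25,
    planted_links = data.frame(variant = 1500, lfc = 2),
    nb_dispersion = 0.05,
    group_sizes = list(rna = 3, atac = 2),
    seed = seed
  )
}

#' Simulate diploid genotypes
#'
#' Each variant gets an allele frequency drawn uniformly from
#' `config$maf_range`; each dosage is the sum of two independent allele
#' draws at that frequency. Variants are assigned to chromosomes
#' contiguously with sorted, strictly increasing positions.
#'
#' @param config a [sim_config()]. For tests, `maf_range` up to `(1, 1)`
#'   is tolerated here (fixed alternate allele, all dosages 2).
#' @return a [genotype_matrix()]. The realized allele frequencies are
#'   attached as attribute `"freq"`.
#' @export
simulate_genotypes <- function(config) {
  check_maf_range(config$maf_range, hi_max = 1)
  n <- config$n_samples
  m <- config$n_variants
  stopifnot(n >= 2, m >= 1)
  set.seed(substream_seed(config$seed, "genotypes"))
  f <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dos <- matrix(stats::rbinom(n * m, size = 2, prob = rep(f, each = n)),
                nrow = n, ncol = m)
  # contiguous chromosome assignment, near-equal block sizes
  chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- integer(m)
  for (ch in seq_len(config$n_chromosomes)) {
    idx <- which(chrom_of == ch)
    if (!length(idx)) next
    if (length(idx) > config$chrom_length) {
      stop("more variants than base pairs on chromosome ", ch)
    }
    pos[idx] <- sort(sample.int(config$chrom_length, length(idx)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  variants <- data.frame(
    id = sprintf("v%05d", seq_len(m)),
    chrom = as.character(chrom_of), pos = pos,
    ref = ref, alt = unname(alt), stringsAsFactors = FALSE
  )
  rownames(dos) <- sprintf("A%04d", seq_len(n))
  G <- genotype_matrix(dos, variants)
  attr(G, "freq") <- f
  G
}

#' Simulate a quantitative trait with polygenic background and planted
#' causal variants
#'
#' The trait is `y = X b + sum_j g_j beta_j + u + e`: fixed effects for the
#' declared categorical covariates, per-allele causal effects, a polygenic
#' term built from standardized non-causal dosages (so its covariance is
#' `h2 * sigma2_total` times the realized relationship matrix), and Gaussian
#' noise filling the variance remainder.
#'
#' @param G a [genotype_matrix()].
#' @param config a [sim_config()]; `h2`, `sigma2_total` and `causal_spec`
#'   are used.
#' @param covariates optional data.frame skeleton with column `animal`
#'   (matching `G$samples`) plus categorical covariate columns; per-level
#'   effects are drawn with SD `covariate_effect_sd`.
#' @param covariate_effect_sd SD (in trait units) of the drawn fixed
#'   effects; 0 declares the covariates without effect.
#' @param intercept baseline trait value (a feed-conversion-ratio-like
#'   trait sits around 2.5).
#' @return list with `phenotype` (data.frame: `animal`, `fcr`, covariates)
#'   and `truth` (causal variant ids, effects in trait units, variance
#'   explained).
#' @export
simulate_phenotype <- function(G, config, covariates = NULL,
                               covariate_effect_sd = 0.2, intercept = 2.5) {
  n <- nrow(G$dosages)
  m <- ncol(G$dosages)
  set.seed(substream_seed(config$seed, "phenotype"))
  sigma2 <- config$sigma2_total
  sd_tot <- sqrt(sigma2)

  cs <- config$causal_spec
  causal_idx <- integer(0)
  beta <- numeric(0)
  if (!is.null(cs) && nrow(cs)) {
    if (any(cs$index < 1 | cs$index > m)) {
      stop("causal variant index out of range 1..", m)
    }
    causal_idx <- as.integer(cs$index)
    f <- colMeans(G$dosages[, causal_idx, drop = FALSE], na.rm = TRUE) / 2
    if ("effect" %in% names(cs) && any(!is.na(cs$effect))) {
      beta <- cs$effect * sd_tot
    }
    if ("var_explained" %in% names(cs)) {
      need <- if (length(beta)) is.na(cs$effect) else rep(TRUE, nrow(cs))
      if (!length(beta)) beta <- numeric(nrow(cs))
      v <- 2 * f * (1 - f)
      if (any(v[need] <= 0)) stop("causal variant is monomorphic")
      beta[need] <- sqrt(cs$var_explained[need] * sigma2 / v[need])
    }
    explained <- sum(2 * f * (1 - f) * beta^2)
  } else {
    explained <- 0
  }
  if (config$h2 + explained / sigma2 > 1) {
    stop("h2 plus causal variance explained exceeds 1")
  }

  # fixed effects
  Xb <- rep(intercept, n)
  cov_out <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot("animal" %in% names(covariates))
    covariates <- covariates[match(G$samples, covariates$animal), , drop = FALSE]
    cov_cols <- setdiff(names(covariates), "animal")
    for (cc in cov_cols) {
      lv <- factor(covariates[[cc]])
      eff <- stats::rnorm(nlevels(lv), 0, covariate_effect_sd)
      eff[1] <- 0  # first level is the reference
      Xb <- Xb + eff[as.integer(lv)]
    }
    cov_out <- covariates[cov_cols]
  }

  # polygenic term from standardized non-causal dosages (VanRaden scaling)
  u <- 0
  if (config$h2 > 0) {
    nc <- setdiff(seq_len(m), causal_idx)
    W <- standardize_dosages(G$dosages[, nc, drop = FALSE])
    mw <- ncol(W)
    if (!mw) stop("no polymorphic non-causal variants for the polygenic term")
    u <- drop(W %*% stats::rnorm(mw, 0, sqrt(config$h2 * sigma2 / mw)))
  }

  e_var <- sigma2 * (1 - config$h2) - explained
  e <- stats::rnorm(n, 0, sqrt(max(e_var, 0)))
  g_part <- if (length(causal_idx)) {
    drop(G$dosages[, causal_idx, drop = FALSE] %*% beta)
  } else 0
  y <- Xb + g_part + u + e

  phenotype <- data.frame(animal = G$samples, fcr = y,
                          stringsAsFactors = FALSE)
  if (!is.null(cov_out)) phenotype <- cbind(phenotype, cov_out)
  truth <- list(
    causal_variants = data.frame(
      id = G$variants$id[causal_idx],
      index = causal_idx,
      effect = beta,
      var_explained = if (length(causal_idx)) {
        f <- colMeans(G$dosages[, causal_idx, drop = FALSE], na.rm = TRUE) / 2
        2 * f * (1 - f) * beta^2 / sigma2
      } else numeric(0),
      stringsAsFactors = FALSE
    ),
    h2 = config$h2, sigma2_total = sigma2
  )
  list(phenotype = phenotype, truth = truth)
}

# Column-standardize dosages with 2f(1-f) variance; missing entries are
# mean-imputed first; monomorphic columns are dropped.
standardize_dosages <- function(dos) {
  f <- colMeans(dos, na.rm = TRUE) / 2
  keep <- is.finite(f) & f > 0 & f < 1
  dos <- dos[, keep, drop = FALSE]
  f <- f[keep]
  if (anyNA(dos)) {
    for (j in which(colSums(is.na(dos)) > 0)) {
      dos[is.na(dos[, j]), j] <- 2 * f[j]
    }
  }
  sweep(sweep(dos, 2, 2 * f, "-"), 2, sqrt(2 * f * (1 - f)), "/")
}

#' Simulate per-animal growth records
#'
#' Weights follow `weight = a + b * age + noise` per animal; a configurable
#' fraction of animals get records with inflated noise and are listed in
#' the returned truth as planted outliers.
#'
#' @param n_animals number of animals.
#' @param days vector of measurement ages in days (>= 2 values).
#' @param slope_range range (kg/day) from which each animal's growth slope
#'   is drawn uniformly.
#' @param noise_sd record-level noise SD in kg (>= 0).
#' @param outlier_fraction fraction of animals with corrupted records.
#' @param outlier_inflation noise multiplier for corrupted animals.
#' @param seed integer seed.
#' @param animal_ids optional character ids (defaults to `A0001`...).
#' @return list with `records` (data.frame `animal`, `age_days`, `weight`)
#'   and `truth` (`outliers`, per-animal `coef`).
#' @export
simulate_growth_records <- function(n_animals, days = seq(60, 180, by = 15),
                                    slope_range = c(0.6, 1.0),
                                    noise_sd = 1, outlier_fraction = 0,
                                    outlier_inflation = 10, seed = 1,
                                    animal_ids = NULL) {
  if (length(days) < 2) stop("need at least 2 measurement days per animal")
  check_range(noise_sd, "noise_sd", lo = 0)
  check_range(outlier_fraction, "outlier_fraction", lo = 0, hi = 1)
  set.seed(substream_seed(seed, "growth"))
  if (is.null(animal_ids)) animal_ids <- sprintf("A%04d", seq_len(n_animals))
  a <- stats::rnorm(n_animals, 5, 2)
  b <- stats::runif(n_animals, slope_range[1], slope_range[2])
  n_out <- round(outlier_fraction * n_animals)
  outliers <- if (n_out > 0) sample(animal_ids, n_out) else character(0)
  sds <- ifelse(animal_ids %in% outliers, noise_sd * outlier_inflation,
                noise_sd)
  records <- data.frame(
    animal = rep(animal_ids, each = length(days)),
    age_days = rep(days, times = n_animals),
    weight = rep(a, each = length(days)) +
      rep(b, each = length(days)) * rep(days, times = n_animals) +
      stats::rnorm(n_animals * length(days), 0, rep(sds, each = length(days))),
    stringsAsFactors = FALSE
  )
  list(records = records,
       truth = list(outliers = sort(outliers),
                    coef = data.frame(animal = animal_ids, a = a, b = b)))
}

#' Mask and perturb genotypes to emulate chip data and imputation output
#'
#' Produces a chip-like matrix with entries set missing at `missing_rate`,
#' and a pseudo-imputed matrix equal to the truth except that a fraction
#' `error_rate` of entries is moved to a different valid dosage. Supplies
#' input pairs for [genotype_concordance()] without running an imputation
#' tool.
#'
#' @param G a [genotype_matrix()] holding the true dosages.
#' @param missing_rate,error_rate rates in [0, 1].
#' @param seed integer seed.
#' @return list with `chip` and `imputed` genotype matrices.
#' @export
mask_and_perturb_genotypes <- function(G, missing_rate = 0.05,
                                       error_rate = 0.02, seed = 1) {
  check_range(missing_rate, "missing_rate", lo = 0, hi = 1)
  check_range(error_rate, "error_rate", lo = 0, hi = 1)
  set.seed(substream_seed(seed, "mask_perturb"))
  dos <- G$dosages
  chip <- dos
  if (missing_rate > 0) {
    drop_mask <- stats::runif(length(dos)) < missing_rate
    chip[drop_mask] <- NA
  }
  imputed <- dos
  if (error_rate > 0) {
    err <- which(stats::runif(length(dos)) < error_rate & !is.na(dos))
    if (length(err)) {
      shift <- sample(1:2, length(err), replace = TRUE)
      imputed[err] <- (dos[err] + shift) %% 3
    }
  }
  list(chip = genotype_matrix(chip, G$variants),
       imputed = genotype_matrix(imputed, G$variants))
}
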