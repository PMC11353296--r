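# Independent brute-force oracles, deliberately written in the most naive
# form so they cannot share bugs with the package implementations.

# O(n^2 m) GRM: standardize columns, then explicit double loop.
grm_brute_force <- function(dosages) {
  f <- colMeans(dosages, na.rm = TRUE) / 2
  keep <- f > 0 & f < 1
  dosages <- dosages[, keep, drop = FALSE]
  f <- f[keep]
  n <- nrow(dosages)
  m <- ncol(dosages)
  W <- matrix(0, n, m)
  for (j in seq_len(m)) {
    col <- dosages[, j]
    col[is.na(col)] <- 2 * f[j]
    W[, j] <- (col - 2 * f[j]) / sqrt(2 * f[j] * (1 - f[j]))
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      K[i, k] <- sum(W[i, ] * W[k, ]) / m
    }
  }
  K
}

# O(nm) overlap: every (variant, region) pair, 1-based pos vs half-open.
overlap_brute_force <- function(variants, regions) {
  out <- list()
  for (i in seq_len(nrow(variants))) {
    for (j in seq_len(nrow(regions))) {
      if (variants$chrom[i] == regions$chrom[j] &&
          regions$start[j] < variants$pos[i] &&
          variants$pos[i] <= regions$end[j]) {
        out[[length(out) + 1]] <- data.frame(
          variant_id = variants$id[i], region_id = regions$id[j],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(variant_id = character(0), region_id = character(0)))
  }
  do.call(rbind, out)
}

# per-variant OLS with the large-n normal approximation on the t statistic
ols_normal_p <- function(y, g) {
  fit <- stats::lm(y ~ g)
  tv <- stats::coef(summary(fit))[2, 3]
  2 * stats::pnorm(-abs(tv))
}

# closed-form OLS through the normal equations
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)
}

# literal median-of-ratios double loop
size_factors_brute_force <- function(counts) {
  use <- which(apply(counts, 1, function(r) all(r > 0)))
  geo <- numeric(length(use))
  for (k in seq_along(use)) geo[k] <- exp(mean(log(counts[use[k], ])))
  sf <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    ratios <- numeric(length(use))
    for (k in seq_along(use)) ratios[k] <- counts[use[k], s] / geo[k]
    sf[s] <- stats::median(ratios)
  }
  sf
}

pair_key <- function(d) sort(paste(d$variant_id, d$region_id))

small_genotypes <- function(n = 40, m = 60, seed = 1, maf = c(0.1, 0.5)) {
  simulate_genotypes(sim_config(n_samples = n, n_variants = m,
                                n_chromosomes = 3, maf_range = maf,
                                seed = seed))
}
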