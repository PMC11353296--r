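#' Fit a per-animal growth line
#'
#' Ordinary least squares of weight (kg) on age (days): `weight = a + b *
#' age`. Used to screen animals whose growth records are unreliable before
#' any trait is analyzed.
#'
#' @param records data.frame with columns `age_days` and `weight` for one
#'   animal (an `animal` column, if present, must hold a single id).
#' @return an object of class `growth_fit`: list with `animal`, `a`
#'   (intercept, kg), `b` (slope, kg/day), `residuals`, `resid_sd` (sample
#'   SD, kg), `n_records`.
#' @export
fit_growth_line <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("age_days", "weight") %in% names(records)))
  animal <- if ("animal" %in% names(records)) {
    ids <- unique(records$animal)
    if (length(ids) > 1) stop("records contain more than one animal")
    ids
  } else NA_character_
  x <- records$age_days
  y <- records$weight
  if (length(unique(x)) < 2) {
    stop("degenerate design: all ages identical for animal ",
         animal %||% "<unnamed>")
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, age = x), y)
  r <- fit$residuals
  structure(list(
    animal = animal, a = unname(fit$coefficients[1]),
    b = unname(fit$coefficients[2]), residuals = r,
    resid_sd = if (length(r) > 1) stats::sd(r) else 0,
    n_records = length(y)
  ), class = "growth_fit")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a[1])) b else a

#' Fit growth lines for all animals
#'
#' @param records data.frame with columns `animal`, `age_days`, `weight`.
#' @return data.frame with one row per animal: `animal`, `a`, `b`,
#'   `resid_sd`, `n_records`.
#' @export
fit_growth_lines <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("animal", "age_days", "weight") %in% names(records)))
  fits <- lapply(split(records, records$animal), fit_growth_line)
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(animal = f$animal, a = f$a, b = f$b, resid_sd = f$resid_sd,
               n_records = f$n_records, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$animal), , drop = FALSE]
}

#' Flag animals with outlying growth residuals
#'
#' An animal is excluded when its residual SD exceeds
#' `median + k * MAD` of the per-animal residual SDs (MAD with the usual
#' 1.4826 consistency constant). Robust and scale-free, so a handful of
#' grossly non-linear growers cannot drag the cutoff with them.
#'
#' @param fits output of [fit_growth_lines()] (or a list of `growth_fit`s).
#' @param k cutoff multiplier (default 3).
#' @return list with `excluded` (sorted animal ids), `cutoff`, and `stats`
#'   (per-animal residual SD and exclusion flag).
#' @export
flag_outlier_animals <- function(fits, k = 3) {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- do.call(rbind, lapply(fits, function(f) {
      data.frame(animal = f$animal, resid_sd = f$resid_sd,
                 stringsAsFactors = FALSE)
    }))
  }
  stopifnot(nrow(fits) >= 3)
  s <- fits$resid_sd
  cutoff <- stats::median(s) + k * stats::mad(s)
  excl <- s > cutoff
  list(
    excluded = sort(fits$animal[excl]),
    cutoff = cutoff,
    stats = data.frame(animal = fits$animal, resid_sd = s,
                       excluded = excl, stringsAsFactors = FALSE)
  )
}

#' Descriptive statistics and normality check for a trait
#'
#' Mean, sample SD, min, max and n over non-missing values, plus an
#' omnibus normality test: D'Agostino-Pearson K2 (default; robust across
#' sample sizes, no upper n limit) or Shapiro-Wilk.
#'
#' @param pheno phenotype data.frame (one row per animal).
#' @param trait column name of the trait.
#' @param normality `"dagostino"` or `"shapiro"`.
#' @return list with `n`, `mean`, `sd`, `min`, `max`, `normality_stat`,
#'   `normality_p`, `normality_method`. The normality fields are `NA` when
#'   fewer than 8 values are available.
#' @export
describe_trait <- function(pheno, trait = "fcr",
                           normality = c("dagostino", "shapiro")) {
  normality <- match.arg(normality)
  x <- pheno[[trait]]
  if (is.null(x)) stop("trait column `", trait, "` not found")
  x <- x[is.finite(x)]
  if (length(x) < 3) {
    stop("describe_trait needs at least 3 non-missing values; got ",
         length(x))
  }
  out <- list(n = length(x), mean = mean(x), sd = stats::sd(x),
              min = min(x), max = max(x),
              normality_stat = NA_real_, normality_p = NA_real_,
              normality_method = normality)
  if (length(x) >= 8) {
    nt <- if (normality == "dagostino") {
      dagostino_pearson_test(x)
    } else {
      st <- stats::shapiro.test(x)
      list(statistic = unname(st$statistic), p.value = st$p.value)
    }
    out$normality_stat <- nt$statistic
    out$normality_p <- nt$p.value
  }
  out
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness and kurtosis Z scores into
#' `K2 = Zg1^2 + Zg2^2`, referred to a chi-square with 2 df.
#'
#' @param x numeric vector, n >= 8.
#' @return list with `statistic` (K2), `p.value`, `z_skewness`,
#'   `z_kurtosis`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test needs n >= 8; got ", n)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: D'Agostino (1970) transformation
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zg1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983) transformation
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  Zg2 <- ((1 - 2 / (9 * A)) -
            ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- Zg1^2 + Zg2^2
  list(statistic = K2,
       p.value = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       z_skewness = Zg1, z_kurtosis = Zg2)
}

#' Select phenotype-extreme groups
#'
#' The `k` animals with the largest trait values form the high group, the
#' `k` smallest the low group. Ties are broken by animal id
#' (lexicographic) so the selection is reproducible and
#' permutation-invariant.
#'
#' @param pheno phenotype data.frame with column `animal` and the trait.
#' @param trait trait column name.
#' @param k animals per group.
#' @return list with `high` and `low` (character ids, each of length `k`,
#'   disjoint).
#' @export
select_extremes <- function(pheno, trait = "fcr", k = 3) {
  stopifnot("animal" %in% names(pheno))
  x <- pheno[[trait]]
  if (is.null(x)) stop("trait column `", trait, "` not found")
  ok <- is.finite(x)
  ids <- pheno$animal[ok]
  x <- x[ok]
  if (2 * k > length(x)) {
    stop("need at least ", 2 * k, " non-missing animals; got ", length(x))
  }
  ord_hi <- order(-x, ids)
  ord_lo <- order(x, ids)
  list(high = ids[ord_hi[seq_len(k)]], low = ids[ord_lo[seq_len(k)]])
}
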