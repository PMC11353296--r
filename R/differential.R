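#' Count matrix with two-group labels
#'
#' Feature-by-sample non-negative integer counts plus a per-sample group
#' factor. Log2 fold changes reported downstream compare the second factor
#' level to the first, so order the levels `c("low", "high")` for a
#' high-vs-low contrast.
#'
#' @param counts numeric matrix, features in rows, samples in columns;
#'   entries must be non-negative integers.
#' @param groups factor (or vector) of length `ncol(counts)` with exactly
#'   two levels and at least 2 samples per group. Groups of size 2 are
#'   allowed with a warning: dispersion estimates are unstable there.
#' @return object of class `count_matrix`: list with `counts`, `groups`.
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("f%05d", seq_len(nrow(counts)))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) {
    stop("groups must label every sample column")
  }
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  sizes <- table(groups)
  if (any(sizes < 2)) stop("need at least 2 samples per group")
  if (any(sizes == 2)) {
    warning("a group has only 2 samples: dispersion estimates are unstable",
            call. = FALSE)
  }
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over features (positive in all samples) of
#' the ratio of its count to the feature's geometric mean. Factors are
#' reported unnormalized.
#'
#' @param x a [count_matrix()] or a counts matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) {
    stop("no feature has nonzero counts in all samples; size factors ",
         "cannot be estimated by median-of-ratios (consider pooling ",
         "samples or using library-size ratios)")
  }
  geo <- exp(rowMeans(log(counts[use, , drop = FALSE])))
  apply(counts[use, , drop = FALSE], 2, function(cnt) {
    stats::median(cnt / geo)
  })
}

#' Per-feature NB dispersion by method of moments with trend shrinkage
#'
#' The raw estimate comes from the within-group variance of normalized
#' counts: with `q = count / size_factor`, `Var(q) ~ mu * mean(1/sf) +
#' alpha * mu^2` per group, solved for `alpha`, combined across groups
#' with df weights and floored at 0. Raw estimates are then shrunk toward
#' a fitted mean-dispersion trend `alpha ~ a0 + a1 / mu` with weight
#' `shrink_weight`.
#'
#' @param x a [count_matrix()].
#' @param sf size factors (default [size_factors()]).
#' @param shrink_weight weight of the trend in the final estimate, in
#'   [0, 1] (default 0.5).
#' @return non-negative numeric vector per feature with attributes `raw`
#'   and `trend`.
#' @export
estimate_dispersion <- function(x, sf = NULL, shrink_weight = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  check_range(shrink_weight, "shrink_weight", lo = 0, hi = 1)
  if (is.null(sf)) sf <- size_factors(x)
  q <- sweep(x$counts, 2, sf, "/")
  lev <- levels(x$groups)
  num <- 0; den <- 0; mu_all <- 0
  for (g in lev) {
    cols <- x$groups == g
    ng <- sum(cols)
    qg <- q[, cols, drop = FALSE]
    mu <- rowMeans(qg)
    v <- apply(qg, 1, stats::var)
    xi <- mean(1 / sf[cols])
    a_g <- ifelse(mu > 0, (v - mu * xi) / mu^2, NA_real_)
    w <- ng - 1
    num <- num + ifelse(is.na(a_g), 0, w * a_g)
    den <- den + ifelse(is.na(a_g), 0, w)
    mu_all <- mu_all + mu / length(lev)
  }
  raw <- pmax(ifelse(den > 0, num / den, 0), 0)
  # mean-dispersion trend: alpha ~ a0 + a1/mu, fitted on informative features
  use <- mu_all > 0 & is.finite(raw)
  trend <- rep(mean(raw[use]), length(raw))
  if (sum(use) >= 10 && stats::sd(1 / mu_all[use]) > 0) {
    fit <- stats::lm(raw[use] ~ I(1 / mu_all[use]))
    tr <- stats::coef(fit)[1] + stats::coef(fit)[2] / mu_all
    trend <- pmax(tr, 0)
  }
  out <- pmax((1 - shrink_weight) * raw + shrink_weight * trend, 0)
  names(out) <- rownames(x$counts)
  attr(out, "raw") <- raw
  attr(out, "trend") <- trend
  # effective df of the shrunk estimator for the downstream Wald reference:
  # the raw moment estimate carries sum(n_g - 1) df; averaging with the
  # trend (fitted across all features, df treated as infinite) scales its
  # sampling variance by (1 - w)^2, hence df_eff = df_raw / (1 - w)^2
  df_raw <- sum(table(x$groups) - 1)
  attr(out, "df_eff") <- if (shrink_weight < 1) {
    df_raw / (1 - shrink_weight)^2
  } else {
    Inf
  }
  out
}

#' Per-feature NB Wald test for a two-group design
#'
#' Fits, per feature, a negative-binomial GLM with log link, design
#' intercept + group indicator and size factors as offsets, by iteratively
#' reweighted least squares with the dispersion held fixed. The Wald
#' statistic on the group coefficient is referred two-sided to a t
#' distribution whose df reflect the precision of the plug-in dispersion
#' (the `df_eff` attribute of [estimate_dispersion()]; standard normal
#' when the dispersion is supplied as a plain vector, e.g. known exactly).
#' `log2FC = coefficient / ln(2)` compares the second group level to the
#' first.
#'
#' @param x a [count_matrix()].
#' @param sf size factors (default [size_factors()]).
#' @param dispersion per-feature NB dispersion (default
#'   [estimate_dispersion()]).
#' @param maxit IRLS iteration cap; non-converged features are flagged and
#'   get `p = NA`.
#' @return data.frame of class `diff_result`: `feature`, `baseMean`,
#'   `log2fc`, `lfc_se`, `stat`, `p`, `padj` (Benjamini-Hochberg, reported
#'   but not used for status), `log2fc_pseudo` (descriptive, pseudo-count
#'   0.5, finite even for all-zero groups), `converged`.
#' @export
nb_wald_test <- function(x, sf = NULL, dispersion = NULL, maxit = 50) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(sf)) sf <- size_factors(x)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(x, sf)
  counts <- x$counts
  nf <- nrow(counts)
  ind <- as.numeric(x$groups == levels(x$groups)[2])
  Xd <- cbind(1, ind)
  off <- log(sf)
  q <- sweep(counts, 2, sf, "/")
  mu1 <- rowMeans(q[, ind == 0, drop = FALSE])
  mu2 <- rowMeans(q[, ind == 1, drop = FALSE])

  beta <- se <- rep(NA_real_, nf)
  conv <- rep(FALSE, nf)
  for (i in seq_len(nf)) {
    y <- counts[i, ]
    al <- dispersion[i]
    b <- c(log(max(mu1[i], 0.1)), log(max(mu2[i], 0.1) / max(mu1[i], 0.1)))
    for (it in seq_len(maxit)) {
      eta <- pmin(pmax(off + drop(Xd %*% b), -30), 30)
      mu <- exp(eta)
      w <- mu / (1 + al * mu)
      z <- (eta - off) + (y - mu) / mu
      A <- crossprod(Xd, w * Xd)
      b_new <- tryCatch(drop(solve(A, crossprod(Xd, w * z))),
                        error = function(e) NULL)
      if (is.null(b_new) || !all(is.finite(b_new))) break
      if (max(abs(b_new - b)) < 1e-8) {
        b <- b_new
        conv[i] <- TRUE
        break
      }
      b <- b_new
    }
    if (conv[i]) {
      eta <- pmin(pmax(off + drop(Xd %*% b), -30), 30)
      mu <- exp(eta)
      w <- mu / (1 + al * mu)
      Vi <- tryCatch(solve(crossprod(Xd, w * Xd)), error = function(e) NULL)
      if (!is.null(Vi) && Vi[2, 2] > 0) {
        beta[i] <- b[2]
        se[i] <- sqrt(Vi[2, 2])
      } else {
        conv[i] <- FALSE
      }
    }
  }
  stat <- beta / se
  df_eff <- attr(dispersion, "df_eff") %||na% Inf
  pval <- 2 * stats::pt(-abs(stat), df = df_eff)
  res <- data.frame(
    feature = rownames(counts),
    baseMean = rowMeans(q),
    log2fc = beta / log(2),
    lfc_se = se / log(2),
    stat = stat,
    p = pval,
    padj = stats::p.adjust(pval, "BH"),
    log2fc_pseudo = log2((mu2 + 0.5) / (mu1 + 0.5)),
    converged = conv,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("diff_result", "data.frame")
  res
}

#' Classify features as up / down / not significant
#'
#' Presets carry the two standard threshold pairs: `rna` flags
#' `|log2FC| >= 1 & p < 0.05`, `atac` flags `|log2FC| >= 0.58 & p < 0.05`.
#' The p cutoff is strict (`<`); the fold-change cutoff is inclusive
#' (`>=`). Raw p is used, not the adjusted p.
#'
#' @param result a `diff_result`.
#' @param preset `"rna"` or `"atac"`.
#' @param lfc_threshold,p_threshold overrides for the preset values.
#' @return the result with a `status` column (`up`, `down`, `ns`);
#'   attributes `preset`, `lfc_threshold`, `p_threshold`.
#' @export
classify_features <- function(result, preset = c("rna", "atac"),
                              lfc_threshold = NULL, p_threshold = 0.05) {
  preset <- match.arg(preset)
  if (is.null(lfc_threshold)) {
    lfc_threshold <- c(rna = 1, atac = 0.58)[[preset]]
  }
  stopifnot(all(c("log2fc", "p") %in% names(result)))
  sig <- !is.na(result$p) & result$p < p_threshold
  status <- rep("ns", nrow(result))
  status[sig & result$log2fc >= lfc_threshold] <- "up"
  status[sig & result$log2fc <= -lfc_threshold] <- "down"
  result$status <- status
  attr(result, "preset") <- preset
  attr(result, "lfc_threshold") <- lfc_threshold
  attr(result, "p_threshold") <- p_threshold
  result
}

#' One-call differential test with a threshold preset
#'
#' Size factors, dispersion, NB Wald test and classification in one step.
#'
#' @inheritParams classify_features
#' @param x a [count_matrix()].
#' @param shrink_weight passed to [estimate_dispersion()].
#' @return classified `diff_result`.
#' @export
diff_test <- function(x, preset = c("rna", "atac"), lfc_threshold = NULL,
                      p_threshold = 0.05, shrink_weight = 0.5) {
  preset <- match.arg(preset)
  sf <- size_factors(x)
  disp <- estimate_dispersion(x, sf, shrink_weight = shrink_weight)
  res <- nb_wald_test(x, sf, disp)
  classify_features(res, preset, lfc_threshold, p_threshold)
}
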