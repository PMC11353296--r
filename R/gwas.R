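#' Bonferroni genome-wide significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m_tests number of tests (>= 1).
#' @return `alpha / m_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_tests) {
  stopifnot(m_tests >= 1)
  alpha / m_tests
}

#' Mixed-linear-model association scan with leave-one-chromosome-out GRMs
#'
#' For each variant on chromosome `c`, tests `H0: beta = 0` in
#' `y = X b + g beta + u + e` with `u ~ N(0, sigma2_g * GRM(-c))`, the GRM
#' built from all other chromosomes so the tested variant cannot be
#' absorbed by the polygenic term (proximal contamination). Variance
#' components are estimated once per LOCO GRM by [reml_fit()] on the null
#' model; each variant is then tested with a GLS Wald statistic in the
#' whitened space, with the residual scale re-estimated per variant
#' (a t-like statistic referred to the standard normal). With
#' `sigma2_g = 0` this reduces exactly to the per-variant OLS t statistic.
#'
#' Missing dosages are mean-imputed per variant (count reported in the
#' attributes). Variants with zero variance after whitening get `p = 1`
#' and a reason code.
#'
#' @param y numeric trait vector, one value per sample of `G`.
#' @param X fixed-effect design including intercept (and typically PCs and
#'   covariate dummies); `NULL` for intercept only.
#' @param G a [genotype_matrix()] of post-QC variants.
#' @param grms optional [compute_grm_set()] result (built from `G` when
#'   missing).
#' @param h2 optional fixed heritability; `NULL` (default) estimates it
#'   per LOCO GRM by REML. `h2 = 0` gives the pure OLS limit.
#' @param alpha family-wise error rate for the Bonferroni threshold
#'   attached to the result.
#' @return data.frame of class `mlma_scan`: `id`, `chrom`, `pos`, `beta`
#'   (trait units per alternate allele), `se`, `stat`, `p`, `note`, with
#'   attributes `threshold`, `alpha`, `vc` (per-chromosome variance
#'   components), `n_imputed`.
#' @export
mlma_loco_scan <- function(y, X = NULL, G, grms = NULL, h2 = NULL,
                           alpha = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(n == nrow(G$dosages))
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(grms)) grms <- compute_grm_set(G)
  chroms <- unique(G$variants$chrom)
  n_imputed <- 0L
  vc <- list()
  res <- vector("list", length(chroms))

  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    K <- grms$loco[[ch]]
    if (is.null(K)) stop("grm_set lacks a LOCO matrix for chromosome ", ch)
    eig <- eigen(K, symmetric = TRUE)
    if (is.null(h2)) {
      fit <- reml_fit(y, X, K, eig = eig)
      h2_c <- if (fit$flat) 0 else fit$h2
      vc[[ch]] <- fit
    } else {
      h2_c <- h2
      vc[[ch]] <- list(h2 = h2, sigma2_g = NA_real_, sigma2_e = NA_real_)
    }
    lam <- pmax(h2_c * pmax(eig$values, 0) + (1 - h2_c), 1e-12)
    Ut <- t(eig$vectors)
    sc <- 1 / sqrt(lam)
    yt <- sc * drop(Ut %*% y)
    Xt <- sc * (Ut %*% X)

    on_c <- which(G$variants$chrom == ch)
    dos <- G$dosages[, on_c, drop = FALSE]
    if (anyNA(dos)) {
      nmiss <- colSums(is.na(dos))
      n_imputed <- n_imputed + sum(nmiss)
      fm <- colMeans(dos, na.rm = TRUE)
      for (j in which(nmiss > 0)) dos[is.na(dos[, j]), j] <- fm[j]
    }
    Gt <- sc * (Ut %*% dos)

    qx <- qr(Xt)
    yr <- qr.resid(qx, yt)
    Gr <- qr.resid(qx, Gt)
    den <- colSums(Gr^2)
    num <- colSums(Gr * yr)
    yy <- sum(yr^2)
    df <- n - p - 1
    ok <- den > 1e-10 * n
    beta <- ifelse(ok, num / den, 0)
    rss <- pmax(yy - beta * num, 0)
    s2 <- rss / df
    se <- ifelse(ok, sqrt(s2 / den), NA_real_)
    stat <- ifelse(ok, beta / se, 0)
    pval <- ifelse(ok, 2 * stats::pnorm(-abs(stat)), 1)
    res[[ci]] <- data.frame(
      id = G$variants$id[on_c], chrom = ch, pos = G$variants$pos[on_c],
      beta = beta, se = se, stat = stat, p = pval,
      note = ifelse(ok, "", "zero_variance"),
      stringsAsFactors = FALSE
    )
  }

  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "threshold") <- bonferroni_threshold(alpha, nrow(out))
  attr(out, "alpha") <- alpha
  attr(out, "vc") <- vc
  attr(out, "n_imputed") <- n_imputed
  class(out) <- c("mlma_scan", "data.frame")
  out
}

#' @export
print.mlma_scan <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("MLMA-LOCO scan: %d variants on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  cat(sprintf("Bonferroni threshold: %.3g (alpha = %.3g); %d significant\n",
              thr, attr(x, "alpha"), sum(x$p < thr)))
  print.data.frame(utils::head(x[order(x$p), ], 5))
  invisible(x)
}

#' @export
summary.mlma_scan <- function(object, ...) {
  thr <- attr(object, "threshold")
  vc <- attr(object, "vc")
  h2s <- vapply(vc, function(f) f$h2, 0)
  structure(list(
    n_variants = nrow(object),
    n_significant = sum(object$p < thr),
    threshold = thr,
    h2_per_chromosome = h2s,
    min_p = min(object$p),
    top = utils::head(as.data.frame(object)[order(object$p), ], 10)
  ), class = "summary.mlma_scan")
}

#' @export
print.summary.mlma_scan <- function(x, ...) {
  cat(sprintf("Variants tested: %d; significant at %.3g: %d; min p = %.3g\n",
              x$n_variants, x$threshold, x$n_significant, x$min_p))
  cat("h2 per LOCO fit:", paste(sprintf("%s=%.2f", names(x$h2_per_chromosome),
                                        x$h2_per_chromosome), collapse = " "), "\n")
  print(x$top)
  invisible(x)
}

#' Manhattan-style plot of a scan (base graphics)
#'
#' Untested decoration; [export_manhattan_data()] is the supported data
#' route.
#'
#' @param x an `mlma_scan`.
#' @param ... passed to [plot()].
#' @export
plot.mlma_scan <- function(x, ...) {
  d <- manhattan_table(x)
  cols <- (as.integer(factor(d$chrom, levels = unique(d$chrom))) %% 2) + 1
  plot(d$cum_pos, d$neglog10p, pch = 16, cex = 0.5,
       col = c("grey30", "steelblue")[cols],
       xlab = "cumulative position", ylab = expression(-log[10](p)), ...)
  graphics::abline(h = -log10(attr(x, "threshold")), col = "red", lty = 2)
  invisible(x)
}

manhattan_table <- function(assoc) {
  chroms <- unique(assoc$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch) {
    max(assoc$pos[assoc$chrom == ch])
  }, 0)))
  names(offs) <- c(chroms, "_end")
  data.frame(
    chrom = assoc$chrom, pos = assoc$pos, p = assoc$p,
    neglog10p = -log10(assoc$p),
    cum_pos = assoc$pos + offs[assoc$chrom],
    stringsAsFactors = FALSE
  )
}

#' Export Manhattan-plot data
#'
#' Writes a TSV with chromosome, position, p, -log10(p) and a cumulative
#' genome coordinate; the significance threshold is recorded in a header
#' metadata line. [read_manhattan_data()] round-trips it.
#'
#' @param assoc an `mlma_scan` (or data.frame with `chrom`, `pos`, `p`).
#' @param path output file.
#' @return invisibly, the written table.
#' @export
export_manhattan_data <- function(assoc, path) {
  stopifnot(nrow(assoc) >= 1)
  d <- manhattan_table(assoc)
  con <- file(path, "w")
  on.exit(close(con))
  thr <- attr(assoc, "threshold")
  writeLines(sprintf("# bonferroni_threshold=%.17g",
                     if (is.null(thr)) NA_real_ else thr), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}

#' Read Manhattan-plot data written by [export_manhattan_data()]
#'
#' @param path file path.
#' @return data.frame with attribute `threshold`.
#' @export
read_manhattan_data <- function(path) {
  first <- readLines(path, n = 1)
  thr <- as.numeric(sub("# bonferroni_threshold=", "", first, fixed = TRUE))
  d <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                         colClasses = c(chrom = "character"))
  attr(d, "threshold") <- thr
  d
}
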