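#' REML variance components for a GRM-structured mixed model
#'
#' Fits `y ~ N(X b, sigma2_g * K + sigma2_e * I)` by restricted maximum
#' likelihood. One eigendecomposition of the GRM reduces the problem to a
#' one-dimensional profile likelihood in `h2 = sigma2_g / (sigma2_g +
#' sigma2_e)`, maximized by Brent's method on `[1e-6, 1 - 1e-6]`.
#'
#' @param y numeric response (trait values).
#' @param X fixed-effect design matrix including the intercept; `NULL` for
#'   intercept only. Must have full column rank.
#' @param grm symmetric GRM.
#' @param eig optional precomputed `eigen(grm, symmetric = TRUE)`; pass it
#'   when fitting several models against the same GRM.
#' @param h2_bounds search interval for `h2`.
#' @param tol convergence tolerance on `h2`.
#' @return object of class `reml_fit`: list with `sigma2_g`, `sigma2_e`,
#'   `h2`, `loglik` (restricted log-likelihood at the optimum), `n`, `p`,
#'   `flat` (TRUE when the likelihood does not separate the components, as
#'   for an identity GRM), `note`.
#' @export
reml_fit <- function(y, X = NULL, grm, eig = NULL,
                     h2_bounds = c(1e-6, 1 - 1e-6), tol = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(grm) == n)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design X is rank deficient")
  if (n <= p + 1) stop("need n > rank(X) + 1 observations")
  if (is.null(eig)) eig <- eigen(grm, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  yt <- drop(crossprod(eig$vectors, y))
  Xt <- crossprod(eig$vectors, X)
  ldXX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)

  restricted_ll <- function(h2) {
    lam <- h2 * d + (1 - h2)
    w <- 1 / lam
    XtW <- Xt * w
    A <- crossprod(Xt, XtW)
    b <- solve(A, crossprod(XtW, yt))
    r <- yt - drop(Xt %*% b)
    rss <- sum(w * r^2)
    if (!is.finite(rss)) stop("non-finite restricted likelihood at h2 = ", h2)
    if (rss < .Machine$double.xmin) return(.Machine$double.xmax)  # perfect fit
    s2 <- rss / (n - p)
    ldA <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(lam)) + ldA - ldXX)
  }

  opt <- stats::optimize(restricted_ll, interval = h2_bounds,
                         maximum = TRUE, tol = tol)
  h2 <- opt$maximum
  ll <- opt$objective

  # flat-likelihood diagnostic (e.g. GRM = I: only sigma2_g + sigma2_e is
  # identifiable)
  grid <- vapply(seq(0.05, 0.95, length.out = 10), restricted_ll, 0)
  flat <- diff(range(grid)) < 1e-6 * max(1, abs(mean(grid)))

  lam <- h2 * d + (1 - h2)
  w <- 1 / lam
  XtW <- Xt * w
  b <- solve(crossprod(Xt, XtW), crossprod(XtW, yt))
  rss <- sum(w * (yt - drop(Xt %*% b))^2)
  s2 <- rss / (n - p)
  note <- ""
  if (s2 < 1e-8 * max(stats::var(y), .Machine$double.eps)) {
    note <- "zero_residual"
  }
  if (flat) note <- paste(note, "flat_likelihood", sep = if (nzchar(note)) "," else "")
  structure(list(
    sigma2_g = h2 * s2, sigma2_e = (1 - h2) * s2, h2 = h2,
    loglik = ll, n = n, p = p, flat = flat, note = note,
    fixed_effects = drop(b)
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "REML fit (n = %d, p = %d): sigma2_g = %.4g, sigma2_e = %.4g, h2 = %.3f, logLik = %.2f%s\n",
    x$n, x$p, x$sigma2_g, x$sigma2_e, x$h2, x$loglik,
    if (x$flat) " [flat likelihood: components not separately identifiable]" else ""
  ))
  invisible(x)
}
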