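#' Genetic relationship matrix (VanRaden method 1)
#'
#' Dosages are column-standardized with `2f(1-f)` variance (missing entries
#' mean-imputed first), and `GRM = W W' / m` over the `m` usable variants.
#' Monomorphic variants are skipped; their count is attached as an
#' attribute.
#'
#' @param G a [genotype_matrix()].
#' @param exclude_chromosome optional chromosome name(s) whose variants are
#'   left out (the leave-one-chromosome-out building block).
#' @return symmetric n-by-n matrix with attributes `m_variants` (variants
#'   used), `n_monomorphic_skipped`, `excluded_chromosome`.
#' @export
compute_grm <- function(G, exclude_chromosome = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  keep <- rep(TRUE, ncol(G$dosages))
  if (!is.null(exclude_chromosome)) {
    keep <- !(G$variants$chrom %in% normalize_chrom(exclude_chromosome))
  }
  if (!any(keep)) stop("no variants remain after chromosome exclusion")
  dos <- G$dosages[, keep, drop = FALSE]
  W <- standardize_dosages(dos)
  n_mono <- ncol(dos) - ncol(W)
  if (ncol(W) == 0) stop("no polymorphic variants usable for the GRM")
  K <- tcrossprod(W) / ncol(W)
  dimnames(K) <- list(G$samples, G$samples)
  attr(K, "m_variants") <- ncol(W)
  attr(K, "n_monomorphic_skipped") <- n_mono
  attr(K, "excluded_chromosome") <- exclude_chromosome
  K
}

#' Full and leave-one-chromosome-out GRMs
#'
#' Builds the genome-wide GRM plus, for every chromosome, the GRM from all
#' other chromosomes. The LOCO matrices are identical to calling
#' [compute_grm()] with that chromosome excluded; they are assembled from
#' per-chromosome cross-products so the standardized matrix is formed only
#' once.
#'
#' @param G a [genotype_matrix()].
#' @return list of class `grm_set` with `full` (matrix), `loco` (named list
#'   of matrices), `m` (named variant counts, `full` first).
#' @export
compute_grm_set <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  chroms <- unique(G$variants$chrom)
  dos <- G$dosages
  f <- colMeans(dos, na.rm = TRUE) / 2
  poly <- is.finite(f) & f > 0 & f < 1
  W <- standardize_dosages(dos)          # drops monomorphic columns
  chrom_w <- G$variants$chrom[poly]
  C_full <- tcrossprod(W)
  m_full <- ncol(W)
  loco <- list()
  m <- c(full = m_full)
  for (ch in chroms) {
    on_c <- chrom_w == ch
    m_c <- sum(on_c)
    if (m_full - m_c == 0) stop("no variants left when excluding chromosome ", ch)
    C_c <- if (m_c) tcrossprod(W[, on_c, drop = FALSE]) else 0
    K <- (C_full - C_c) / (m_full - m_c)
    dimnames(K) <- list(G$samples, G$samples)
    attr(K, "m_variants") <- m_full - m_c
    attr(K, "excluded_chromosome") <- ch
    loco[[ch]] <- K
    m[ch] <- m_full - m_c
  }
  full <- C_full / m_full
  dimnames(full) <- list(G$samples, G$samples)
  attr(full, "m_variants") <- m_full
  attr(full, "n_monomorphic_skipped") <- sum(!poly)
  structure(list(full = full, loco = loco, m = m), class = "grm_set")
}

#' @export
print.grm_set <- function(x, ...) {
  cat(sprintf("<grm_set> n = %d samples; full GRM from %d variants; LOCO: %s\n",
              nrow(x$full), x$m[["full"]],
              paste(names(x$loco), collapse = ", ")))
  invisible(x)
}

#' Principal components of a GRM
#'
#' Eigenvectors for the `k` largest eigenvalues, scaled by
#' `sqrt(eigenvalue)` so the scores carry variance. Deterministic sign
#' convention: in each eigenvector the largest-magnitude loading is made
#' positive.
#'
#' @param grm symmetric GRM matrix.
#' @param k number of components (`k < n`).
#' @return n-by-k score matrix with eigenvalues as attribute `"values"`.
#' @export
compute_pcs <- function(grm, k = 5) {
  n <- nrow(grm)
  if (k >= n) stop("k must be smaller than the number of samples (", n, ")")
  e <- eigen(grm, symmetric = TRUE)
  vals <- pmax(e$values[seq_len(k)], 0)
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- sweep(vecs, 2, sqrt(vals), "*")
  dimnames(scores) <- list(rownames(grm), paste0("PC", seq_len(k)))
  attr(scores, "values") <- vals
  scores
}
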