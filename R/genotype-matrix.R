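#' Genotype matrix container
#'
#' Samples-by-variants diploid dosage matrix (counts of the alternate
#' allele, values 0/1/2, `NA` for missing) plus variant metadata. This is
#' the substrate for QC, the GWAS and the integration stage.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`. Row names are sample ids; column names,
#'   if present, must match `variants$id`.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; one row per column of `dosages`, positions strictly
#'   increasing within each chromosome.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants`, `samples`.
#' @export
genotype_matrix <- function(dosages, variants) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("S%04d", seq_len(nrow(dosages)))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) {
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("variant table has ", nrow(variants), " rows but dosage matrix has ",
         ncol(dosages), " columns")
  }
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  if (anyDuplicated(rownames(dosages))) stop("duplicate sample ids")
  variants$chrom <- normalize_chrom(variants$chrom)
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  colnames(dosages) <- variants$id
  structure(
    list(dosages = dosages, variants = variants, samples = rownames(dosages)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d variants on %d chromosome(s); %.2f%% missing\n",
    length(x$samples), nrow(x$variants),
    length(unique(x$variants$chrom)),
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Subset variants by a logical/integer index, keeping metadata in step.
subset_variants <- function(G, keep) {
  genotype_matrix(G$dosages[, keep, drop = FALSE],
                  G$variants[keep, , drop = FALSE])
}

# Per-variant alternate-allele frequency on non-missing calls.
allele_freq <- function(G) {
  colMeans(G$dosages, na.rm = TRUE) / 2
}
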