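#' Variant-level genotype quality control
#'
#' Keeps a variant iff its call rate is at least `min_call_rate` and its
#' minor allele frequency (computed on non-missing dosages as
#' `min(f, 1 - f)`) is at least `min_maf`. "Below" is strict: boundary
#' values are kept. Variants with no calls at all are dropped with reason
#' `no_calls`.
#'
#' @param G a [genotype_matrix()].
#' @param min_call_rate minimum non-missing fraction (default 0.90).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @return list with `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (data.frame: `id`, `chrom`, `pos`, `call_rate`, `maf`,
#'   `kept`, `reason`).
#' @export
filter_variants <- function(G, min_call_rate = 0.90, min_maf = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"), ncol(G$dosages) >= 1)
  check_range(min_call_rate, "min_call_rate", lo = 0, hi = 1)
  check_range(min_maf, "min_maf", lo = 0, hi = 0.5)
  cr <- colMeans(!is.na(G$dosages))
  f <- colMeans(G$dosages, na.rm = TRUE) / 2   # NaN when no calls
  maf <- pmin(f, 1 - f)
  no_calls <- cr == 0
  low_cr <- !no_calls & cr < min_call_rate
  low_maf <- !no_calls & maf < min_maf
  kept <- !no_calls & !low_cr & !low_maf
  reason <- character(length(cr))
  reason[no_calls] <- "no_calls"
  reason[low_cr & !low_maf] <- "low_call_rate"
  reason[!low_cr & low_maf] <- "low_maf"
  reason[low_cr & low_maf] <- "low_call_rate,low_maf"
  report <- data.frame(
    id = G$variants$id, chrom = G$variants$chrom, pos = G$variants$pos,
    call_rate = cr, maf = ifelse(no_calls, NA_real_, maf),
    kept = kept, reason = reason, stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  list(genotypes = subset_variants(G, kept), report = report)
}

#' Concordance between two genotype call sets
#'
#' Compares an imputed call set against a gold standard over the shared
#' samples and variants (matched by chromosome, position, ref and alt;
#' swapped ref/alt pairs are reported, not flipped). Concordance is the
#' fraction of entries with identical dosage among entries non-missing in
#' both.
#'
#' @param imputed,truth [genotype_matrix()] objects.
#' @return list with `overall` (rate in [0, 1]), `per_variant`
#'   (data.frame: variant id, n compared, rate), `n_entries`,
#'   `n_samples`, `n_variants`, `n_allele_swapped`.
#' @export
genotype_concordance <- function(imputed, truth) {
  stopifnot(inherits(imputed, "genotype_matrix"),
            inherits(truth, "genotype_matrix"))
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  swap_key <- function(v) paste(v$chrom, v$pos, v$alt, v$ref, sep = ":")
  ki <- key(imputed$variants)
  kt <- key(truth$variants)
  shared <- intersect(ki, kt)
  n_swapped <- length(intersect(setdiff(ki, kt), swap_key(truth$variants)))
  samples <- intersect(imputed$samples, truth$samples)
  if (!length(shared) || !length(samples)) {
    stop("no shared (sample, variant) entries between the two call sets")
  }
  A <- imputed$dosages[samples, match(shared, ki), drop = FALSE]
  B <- truth$dosages[samples, match(shared, kt), drop = FALSE]
  comp <- !is.na(A) & !is.na(B)
  agree <- comp & (A == B)
  per_variant <- data.frame(
    id = imputed$variants$id[match(shared, ki)],
    n = colSums(comp),
    rate = ifelse(colSums(comp) > 0, colSums(agree) / colSums(comp), NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(per_variant) <- NULL
  list(
    overall = sum(agree) / sum(comp),
    per_variant = per_variant,
    n_entries = sum(comp),
    n_samples = length(samples),
    n_variants = length(shared),
    n_allele_swapped = n_swapped
  )
}
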