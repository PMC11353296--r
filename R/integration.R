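#' Genotype-class phenotype comparison for one variant
#'
#' Splits animals by dosage class (0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate), summarizes the trait per
#' class, and tests class 2 against classes 0 and 1 pooled with a
#' two-sided Welch t test (Kruskal-Wallis across the three classes as an
#' option).
#'
#' @param dosages named numeric vector of dosages (names = animal ids), or
#'   unnamed in the order of `pheno$animal`.
#' @param pheno phenotype data.frame with `animal` and the trait column.
#' @param trait trait column name.
#' @param method `"welch"` (class 2 vs rest) or `"kruskal"` (across
#'   classes).
#' @return object of class `genotype_class_summary`: list with `summary`
#'   (per class: n, mean, sd), `statistic`, `p`, `method`, `note`
#'   (`"zero_variance"` when all trait values are identical, in which case
#'   `p = 1`; an insufficient-class reason when the test is impossible,
#'   with `p = NA`).
#' @export
genotype_phenotype_compare <- function(dosages, pheno, trait = "fcr",
                                       method = c("welch", "kruskal")) {
  method <- match.arg(method)
  y <- pheno[[trait]]
  if (is.null(y)) stop("trait column `", trait, "` not found")
  if (!is.null(names(dosages))) {
    d <- dosages[match(pheno$animal, names(dosages))]
  } else {
    stopifnot(length(dosages) == nrow(pheno))
    d <- dosages
  }
  ok <- !is.na(d) & is.finite(y)
  d <- d[ok]; y <- y[ok]
  cls <- factor(d, levels = c(0, 1, 2))
  smry <- data.frame(
    class = c(0L, 1L, 2L),
    n = as.integer(table(cls)),
    mean = as.numeric(tapply(y, cls, mean)),
    sd = as.numeric(tapply(y, cls, stats::sd))
  )
  present <- smry$n >= 2
  out <- list(summary = smry, statistic = NA_real_, p = NA_real_,
              method = method, note = "")
  if (sum(smry$n > 0) < 2 || sum(present) < 2) {
    out$note <- "insufficient_classes"
    class(out) <- "genotype_class_summary"
    return(out)
  }
  if (stats::var(y) == 0) {
    out$p <- 1
    out$statistic <- 0
    out$note <- "zero_variance"
    class(out) <- "genotype_class_summary"
    return(out)
  }
  if (method == "welch") {
    in2 <- d == 2
    if (sum(in2) < 2 || sum(!in2) < 2) {
      out$note <- "homozygous_alt_class_too_small"
    } else if (stats::var(y[in2]) == 0 && stats::var(y[!in2]) == 0) {
      out$p <- if (mean(y[in2]) == mean(y[!in2])) 1 else 0
      out$note <- "zero_within_class_variance"
    } else {
      tt <- stats::t.test(y[in2], y[!in2])
      out$statistic <- unname(tt$statistic)
      out$p <- tt$p.value
    }
  } else {
    kt <- stats::kruskal.test(y, droplevels(cls))
    out$statistic <- unname(kt$statistic)
    out$p <- kt$p.value
  }
  class(out) <- "genotype_class_summary"
  out
}

#' @export
print.genotype_class_summary <- function(x, ...) {
  print(x$summary)
  cat(sprintf("%s test (class 2 vs rest): stat = %.3g, p = %.3g %s\n",
              x$method, x$statistic, x$p,
              if (nzchar(x$note)) paste0("[", x$note, "]") else ""))
  invisible(x)
}

#' Attach differential status to peak intervals
#'
#' Joins a classified ATAC `diff_result` onto a peak [interval_set()] by
#' feature id and records the tissue label.
#'
#' @param peaks peak [interval_set()].
#' @param diff classified `diff_result` whose `feature` ids match peak ids.
#' @param tissue tissue label carried into the annotation.
#' @return the peaks with `status`, `log2fc`, `tissue` columns.
#' @export
annotate_peaks <- function(peaks, diff, tissue) {
  peaks <- if (inherits(peaks, "interval_set")) peaks else interval_set(peaks)
  i <- match(peaks$id, diff$feature)
  peaks$status <- ifelse(is.na(i), "ns", diff$status[i])
  peaks$log2fc <- diff$log2fc[i]
  peaks$tissue <- tissue
  peaks
}

#' Link genome-wide-significant variants to candidate genes via
#' differential peaks and TADs
#'
#' The integration strategy: (1) keep variants with GWAS `p` below the
#' threshold; (2) keep those lying inside peaks whose differential status
#' is not `ns`; (3) assign each kept variant to its TAD; (4) emit one link
#' per gene fully contained in that TAD, annotated with the gene's DE
#' status and log2FC in every supplied tissue; (5) attach the
#' genotype-class phenotype comparison for the variant.
#'
#' @param assoc an `mlma_scan` (columns `id`, `chrom`, `pos`, `p`).
#' @param peaks annotated peaks (see [annotate_peaks()]); may be the
#'   rbind of several tissues' annotations. Peaks with `status == "ns"`
#'   are ignored.
#' @param tads TAD [interval_set()] (non-overlapping per chromosome).
#' @param genes gene [interval_set()].
#' @param diff_expr named list (by tissue) of classified RNA `diff_result`s.
#' @param threshold GWAS significance threshold (default: the scan's
#'   Bonferroni attribute).
#' @param genotypes optional [genotype_matrix()] for the genotype-class
#'   comparison.
#' @param pheno optional phenotype table (required with `genotypes`).
#' @param trait trait column name.
#' @return data.frame of class `variant_gene_links`, ordered by ascending
#'   GWAS p then chromosome, position, gene id. Zero rows when nothing
#'   passes.
#' @export
link_variants_to_genes <- function(assoc, peaks, tads, genes, diff_expr,
                                   threshold = NULL, genotypes = NULL,
                                   pheno = NULL, trait = "fcr") {
  if (is.null(threshold)) threshold <- attr(assoc, "threshold")
  if (is.null(threshold)) stop("no GWAS threshold given or attached to assoc")
  tads <- validate_tads(tads)
  genes <- if (inherits(genes, "interval_set")) genes else interval_set(genes)
  if (is.null(peaks$status)) stop("peaks must carry a `status` column; see annotate_peaks()")

  empty <- data.frame(
    variant_id = character(0), chrom = character(0), pos = integer(0),
    gwas_p = numeric(0), peak_id = character(0), peak_status = character(0),
    peak_tissue = character(0), tad_id = character(0), gene_id = character(0),
    stringsAsFactors = FALSE
  )
  sig <- assoc[is.finite(assoc$p) & assoc$p < threshold, , drop = FALSE]
  if (!nrow(sig)) return(structure(empty, class = c("variant_gene_links", "data.frame")))

  dpeaks <- peaks[peaks$status != "ns", , drop = FALSE]
  if (!nrow(dpeaks)) return(structure(empty, class = c("variant_gene_links", "data.frame")))
  # a peak id may appear once per tissue; ids must be unique per tissue slice
  dpeaks$row_id <- paste0(dpeaks$id, "@", dpeaks$tissue %||na% "NA")
  ov <- snps_in_regions(sig, interval_set(transform(dpeaks, id = row_id)))
  if (!nrow(ov)) return(structure(empty, class = c("variant_gene_links", "data.frame")))

  gene_tad <- assign_tad(genes, tads)
  tissues <- names(diff_expr)
  rows <- list()
  gp_cache <- list()
  for (r in seq_len(nrow(ov))) {
    v <- sig[match(ov$variant_id[r], sig$id), ]
    pk <- dpeaks[match(ov$region_id[r], dpeaks$row_id), ]
    tad <- assign_tad(data.frame(chrom = v$chrom, pos = v$pos), tads)
    if (is.na(tad)) next   # variant in an inter-TAD gap: no links
    gidx <- which(!is.na(gene_tad) & gene_tad == tad)
    if (!length(gidx)) next
    gp <- NULL
    if (!is.null(genotypes) && !is.null(pheno)) {
      if (is.null(gp_cache[[v$id]])) {
        dos <- genotypes$dosages[, match(v$id, genotypes$variants$id)]
        names(dos) <- genotypes$samples
        gp_cache[[v$id]] <- genotype_phenotype_compare(dos, pheno, trait)
      }
      gp <- gp_cache[[v$id]]
    }
    for (gi in gidx) {
      row <- data.frame(
        variant_id = v$id, chrom = v$chrom, pos = v$pos, gwas_p = v$p,
        peak_id = pk$id, peak_status = pk$status,
        peak_tissue = pk$tissue %||na% NA_character_,
        tad_id = tad, gene_id = genes$id[gi],
        stringsAsFactors = FALSE
      )
      for (tis in tissues) {
        de <- diff_expr[[tis]]
        j <- match(genes$id[gi], de$feature)
        row[[paste0("gene_status_", tis)]] <-
          if (is.na(j)) "ns" else de$status[j]
        row[[paste0("gene_log2fc_", tis)]] <-
          if (is.na(j)) NA_real_ else de$log2fc[j]
      }
      if (!is.null(gp)) {
        row$gp_p <- gp$p
        row$gp_class2_mean <- gp$summary$mean[gp$summary$class == 2]
        row$gp_rest_mean <- with(gp$summary[gp$summary$class != 2, ],
                                 stats::weighted.mean(mean, n))
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  if (!length(rows)) return(structure(empty, class = c("variant_gene_links", "data.frame")))
  out <- do.call(rbind, rows)
  out <- out[order(out$gwas_p, out$chrom, out$pos, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_gene_links", "data.frame")
  out
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Rank variant-gene links into a report
#'
#' Composite order: GWAS p ascending, then gene DE evidence (DE in the
#' peak's own tissue beats DE elsewhere beats ns), then genotype-phenotype
#' p ascending, with a final (chromosome, position, gene) tie-break for a
#' deterministic total order. Significance stars on the genotype-class
#' test follow `***` for p < 0.001 and `****` for p < 0.0001.
#'
#' @param links output of [link_variants_to_genes()] (non-empty).
#' @return the links with `evidence_rank`, `rank` and `gp_stars` columns,
#'   sorted.
#' @export
prioritize <- function(links) {
  stopifnot(nrow(links) >= 1)
  status_cols <- grep("^gene_status_", names(links), value = TRUE)
  evid <- vapply(seq_len(nrow(links)), function(i) {
    own <- paste0("gene_status_", links$peak_tissue[i])
    if (own %in% status_cols && links[[own]][i] != "ns") return(0L)
    other <- setdiff(status_cols, own)
    if (length(other) &&
        any(vapply(other, function(cc) links[[cc]][i] != "ns", TRUE))) {
      return(1L)
    }
    2L
  }, 0L)
  links$evidence_rank <- evid
  gp <- if ("gp_p" %in% names(links)) ifelse(is.na(links$gp_p), 2, links$gp_p) else rep(2, nrow(links))
  o <- order(links$gwas_p, evid, gp, links$chrom, links$pos, links$gene_id)
  links <- links[o, , drop = FALSE]
  links$rank <- seq_len(nrow(links))
  if ("gp_p" %in% names(links)) {
    links$gp_stars <- ifelse(is.na(links$gp_p), "",
                             ifelse(links$gp_p < 1e-4, "****",
                                    ifelse(links$gp_p < 1e-3, "***", "")))
  }
  rownames(links) <- NULL
  links
}
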