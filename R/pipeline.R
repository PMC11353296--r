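#' Pipeline configuration
#'
#' Validated bag of file paths, thresholds and toggles for
#' [run_pipeline()]. Unknown keys are rejected; thresholds are checked
#' against their domains.
#'
#' @param genotypes path to a VCF (or dosage TSV ending in `.tsv`).
#' @param phenotypes path to the phenotype/covariate TSV.
#' @param growth optional path to growth records TSV (enables the
#'   growth-line outlier screen).
#' @param peaks,tads,genes BED paths for ATAC peaks, TADs and gene models.
#' @param rna_counts,atac_counts named character vectors (tissue = path)
#'   of count TSVs; the samples must be the phenotype-extreme animals.
#' @param trait trait column name in the phenotype table.
#' @param covariates character vector of categorical covariate columns in
#'   the phenotype table used as fixed effects.
#' @param min_call_rate,min_maf genotype QC thresholds.
#' @param gwas_alpha family-wise error rate for the Bonferroni threshold.
#' @param gwas_threshold optional fixed significance threshold overriding
#'   the realized Bonferroni value.
#' @param n_pcs number of GRM principal components used as fixed effects.
#' @param rna_lfc,atac_lfc,p_threshold differential-test thresholds.
#' @param k_extremes animals per phenotype-extreme group.
#' @param outlier_k growth-residual exclusion multiplier.
#' @param seed integer master seed.
#' @param outdir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, phenotypes, growth = NULL,
                            peaks, tads, genes,
                            rna_counts, atac_counts,
                            trait = "fcr", covariates = character(0),
                            min_call_rate = 0.90, min_maf = 0.05,
                            gwas_alpha = 0.05, gwas_threshold = NULL,
                            n_pcs = 5, rna_lfc = 1, atac_lfc = 0.58,
                            p_threshold = 0.05, k_extremes = 3,
                            outlier_k = 3, seed = 1, outdir = tempfile("run")) {
  check_range(min_call_rate, "min_call_rate", lo = 0, hi = 1)
  check_range(min_maf, "min_maf", lo = 0, hi = 0.5)
  check_range(gwas_alpha, "gwas_alpha", lo = 0, hi = 1, lo_open = TRUE)
  if (!is.null(gwas_threshold)) {
    check_range(gwas_threshold, "gwas_threshold", lo = 0, hi = 1,
                lo_open = TRUE)
  }
  check_range(p_threshold, "p_threshold", lo = 0, hi = 1, lo_open = TRUE)
  check_range(rna_lfc, "rna_lfc", lo = 0)
  check_range(atac_lfc, "atac_lfc", lo = 0)
  check_range(n_pcs, "n_pcs", lo = 0)
  check_range(k_extremes, "k_extremes", lo = 1)
  rna_counts <- unlist(rna_counts)     # tolerate JSON-style named lists
  atac_counts <- unlist(atac_counts)
  covariates <- unlist(covariates)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Build a pipeline_config from a named list (e.g. parsed JSON)
#'
#' Unknown keys are rejected with their names.
#'
#' @param x named list.
#' @return a [pipeline_config()].
#' @export
as_pipeline_config <- function(x) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, x)
}

#' Run the full analysis pipeline from files
#'
#' Stages: phenotype QC (growth-line outlier screen, trait description,
#' extreme-group bookkeeping) -> genotype QC -> MLMA-LOCO GWAS ->
#' differential testing of RNA and ATAC layers -> integration (SNP in
#' differential peak, TAD gene assignment, genotype-class comparison,
#' ranked report). Per-stage TSV/JSON outputs and a run manifest (config
#' hash, seed, versions, per-stage row counts) are written to
#' `config$outdir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the in-memory report bundle (see [run_analysis()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- c(genotypes = config$genotypes, phenotypes = config$phenotypes,
             growth = config$growth, peaks = config$peaks,
             tads = config$tads, genes = config$genes,
             config$rna_counts, config$atac_counts)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  G <- if (grepl("\\.tsv$", config$genotypes)) {
    read_dosage_tsv(config$genotypes)
  } else {
    read_vcf(config$genotypes)
  }
  data <- list(
    genotypes = G,
    phenotype = read_phenotypes(config$phenotypes),
    growth = if (!is.null(config$growth)) read_growth(config$growth),
    peaks = read_bed(config$peaks),
    tads = read_bed(config$tads),
    genes = read_bed(config$genes),
    counts = list(
      rna = lapply(config$rna_counts, read_counts),
      atac = lapply(config$atac_counts, read_counts)
    )
  )
  bundle <- run_analysis(data, config)
  write_report_bundle(bundle, config)
  invisible(bundle)
}

# Assign high/low group labels to count-matrix samples from the
# phenotype-extreme selection.
label_counts <- function(m, extremes) {
  ids <- colnames(m)
  grp <- ifelse(ids %in% extremes$high, "high",
                ifelse(ids %in% extremes$low, "low", NA))
  if (anyNA(grp)) {
    stop("count sample(s) not among the selected extreme animals: ",
         paste(ids[is.na(grp)], collapse = ", "))
  }
  count_matrix(m, factor(grp, levels = c("low", "high")))
}

#' Run the analysis pipeline on in-memory objects
#'
#' The computational core of [run_pipeline()]; also accepts the output of
#' [simulate_dataset()] directly. Count layers may be plain matrices
#' (group labels are then derived from the phenotype extremes) or
#' [count_matrix()] objects.
#'
#' @param data list with `genotypes`, `phenotype`, optional `growth`,
#'   `peaks`, `tads`, `genes`, `counts` (list `rna`/`atac` of per-tissue
#'   matrices).
#' @param config a [pipeline_config()] or a plain list of the threshold
#'   fields (paths are ignored here).
#' @return list of class `pipeline_result` with per-stage outputs:
#'   `pheno_qc`, `geno_qc`, `assoc`, `diff` (per layer/tissue), `links`,
#'   `report`, `counts_used`, `config`.
#' @export
run_analysis <- function(data, config = list()) {
  cfg <- function(key, default) config[[key]] %||na% default
  trait <- cfg("trait", "fcr")
  pheno <- data$phenotype

  # --- stage 1: phenotype QC ------------------------------------------
  pheno_qc <- list()
  if (!is.null(data$growth)) {
    fits <- fit_growth_lines(data$growth)
    flag <- flag_outlier_animals(fits, k = cfg("outlier_k", 3))
    pheno_qc$growth_fits <- fits
    pheno_qc$excluded <- flag$excluded
    pheno <- pheno[!pheno$animal %in% flag$excluded, , drop = FALSE]
  }
  pheno_qc$describe <- describe_trait(pheno, trait)
  extremes <- select_extremes(pheno, trait, cfg("k_extremes", 3))
  pheno_qc$extremes <- extremes

  # --- stage 2: genotype QC -------------------------------------------
  G <- data$genotypes
  keep <- G$samples %in% pheno$animal
  if (!all(keep)) G <- genotype_matrix(G$dosages[keep, , drop = FALSE], G$variants)
  qc <- filter_variants(G, cfg("min_call_rate", 0.90), cfg("min_maf", 0.05))
  Gq <- qc$genotypes

  # --- stage 3: GWAS ---------------------------------------------------
  pheno <- pheno[match(Gq$samples, pheno$animal), , drop = FALSE]
  y <- pheno[[trait]]
  grms <- compute_grm_set(Gq)
  n_pcs <- cfg("n_pcs", 5)
  X <- matrix(1, length(y), 1)
  if (n_pcs > 0) X <- cbind(X, compute_pcs(grms$full, n_pcs))
  for (cc in cfg("covariates", character(0))) {
    f <- factor(pheno[[cc]])
    if (nlevels(f) > 1) {
      X <- cbind(X, stats::model.matrix(~f)[, -1, drop = FALSE])
    }
  }
  assoc <- mlma_loco_scan(y, X, Gq, grms, alpha = cfg("gwas_alpha", 0.05))
  threshold <- cfg("gwas_threshold", NULL) %||na% attr(assoc, "threshold")

  # --- stage 4: differential testing ----------------------------------
  diff <- list(rna = list(), atac = list())
  counts_used <- list(rna = list(), atac = list())
  presets <- c(rna = "rna", atac = "atac")
  for (layer in c("rna", "atac")) {
    for (tis in names(data$counts[[layer]])) {
      cm <- data$counts[[layer]][[tis]]
      if (!inherits(cm, "count_matrix")) {
        ext <- select_extremes(pheno, trait, ncol(cm) / 2)
        cm <- label_counts(cm, ext)
      }
      counts_used[[layer]][[tis]] <- cm
      diff[[layer]][[tis]] <- suppressWarnings(diff_test(
        cm, preset = presets[[layer]],
        lfc_threshold = if (layer == "rna") cfg("rna_lfc", 1) else cfg("atac_lfc", 0.58),
        p_threshold = cfg("p_threshold", 0.05)
      ))
    }
  }

  # --- stage 5: integration -------------------------------------------
  peaks_ann <- do.call(rbind, lapply(names(diff$atac), function(tis) {
    annotate_peaks(data$peaks, diff$atac[[tis]], tis)
  }))
  links <- link_variants_to_genes(
    assoc, peaks_ann, data$tads, data$genes, diff$rna,
    threshold = threshold, genotypes = Gq, pheno = pheno, trait = trait
  )
  report <- if (nrow(links)) prioritize(links) else links

  structure(list(
    pheno_qc = pheno_qc, geno_qc = qc$report, assoc = assoc,
    threshold = threshold, diff = diff, links = links, report = report,
    counts_used = counts_used, genotypes_qc = Gq, config = config
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  variants post-QC: %d (of %d)\n", sum(x$geno_qc$kept),
              nrow(x$geno_qc)))
  cat(sprintf("  GWAS: %d significant at %.3g\n",
              sum(x$assoc$p < x$threshold), x$threshold))
  for (layer in names(x$diff)) {
    for (tis in names(x$diff[[layer]])) {
      d <- x$diff[[layer]][[tis]]
      cat(sprintf("  %s/%s: %d up, %d down of %d features\n", layer, tis,
                  sum(d$status == "up"), sum(d$status == "down"), nrow(d)))
    }
  }
  cat(sprintf("  ranked variant-gene links: %d\n", nrow(x$report)))
  invisible(x)
}

write_report_bundle <- function(bundle, config) {
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  utils::write.table(bundle$geno_qc, p("genotype_qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(bundle$assoc), p("assoc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  export_manhattan_data(bundle$assoc, p("manhattan.tsv"))
  counts <- list()
  for (layer in names(bundle$diff)) {
    for (tis in names(bundle$diff[[layer]])) {
      f <- sprintf("diff_%s_%s.tsv", layer, tis)
      utils::write.table(as.data.frame(bundle$diff[[layer]][[tis]]), p(f),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      counts[[paste0("diff_", layer, "_", tis)]] <-
        nrow(bundle$diff[[layer]][[tis]])
    }
  }
  utils::write.table(as.data.frame(bundle$report), p("links_ranked.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "outdir")],
                               auto_unbox = TRUE, force = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("feedomics")),
    r_version = R.version.string,
    row_counts = c(
      list(
        variants_post_qc = sum(bundle$geno_qc$kept),
        gwas_tests = nrow(bundle$assoc),
        gwas_significant = sum(bundle$assoc$p < bundle$threshold),
        links = nrow(bundle$report)
      ),
      counts
    )
  )
  unlink(tmp)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}
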