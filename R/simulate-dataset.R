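#' Simulate a complete study dataset with planted truth
#'
#' One call produces everything the pipeline consumes: genotypes,
#' covariates, phenotype, growth records, regulatory landscape, and RNA /
#' ATAC count matrices for two tissues. The planted signal (causal
#' variants, differential peaks, DE genes) is placed in the `duodenum`
#' tissue; the `muscle` tissue is an all-null layer. RNA and ATAC samples
#' are the phenotype-extreme animals (group sizes from
#' `config$group_sizes`).
#'
#' @param config a [sim_config()].
#' @param tissues character vector; the first tissue carries the planted
#'   signal.
#' @return list with elements `genotypes`, `phenotype`, `growth`, `peaks`,
#'   `tads`, `genes`, `counts` (nested list `rna`/`atac` by tissue),
#'   `groups` (extreme animal ids per layer), `truth`, `config`.
#' @export
simulate_dataset <- function(config = default_sim_config(),
                             tissues = c("duodenum", "muscle")) {
  G <- simulate_genotypes(config)
  n <- config$n_samples

  set.seed(substream_seed(config$seed, "covariates"))
  covariates <- data.frame(
    animal = G$samples,
    pen = sample(paste0("pen", 1:4), n, replace = TRUE),
    birth_month = sample(month.abb[1:6], n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  ph <- simulate_phenotype(G, config, covariates = covariates)
  growth <- simulate_growth_records(
    n, noise_sd = 1, outlier_fraction = 0.02,
    seed = config$seed, animal_ids = G$samples
  )
  land <- simulate_regulatory_landscape(config, G)

  gene_ids <- land$genes$id
  peak_ids <- land$peaks$id
  links <- land$truth$expected_links
  gene_lfc <- stats::setNames(rep(0, length(gene_ids)), gene_ids)
  peak_lfc <- stats::setNames(rep(0, length(peak_ids)), peak_ids)
  if (!is.null(links) && nrow(links)) {
    gene_lfc[links$gene_id] <- links$lfc
    peak_lfc[links$peak_id] <- links$lfc
  }

  set.seed(substream_seed(config$seed, "baselines"))
  gene_base <- stats::rlnorm(length(gene_ids), log(150), 0.8)
  peak_base <- stats::rlnorm(length(peak_ids), log(150), 0.8)
  # keep planted features away from the low-count regime so the small
  # replicate groups retain power
  gene_base[gene_lfc != 0] <- pmax(gene_base[gene_lfc != 0], 100)
  peak_base[peak_lfc != 0] <- pmax(peak_base[peak_lfc != 0], 100)

  k_rna <- config$group_sizes$rna
  k_atac <- config$group_sizes$atac
  ext_rna <- select_extremes(ph$phenotype, "fcr", k_rna)
  ext_atac <- select_extremes(ph$phenotype, "fcr", k_atac)

  counts <- list(rna = list(), atac = list())
  for (ti in seq_along(tissues)) {
    tis <- tissues[ti]
    signal <- ti == 1L
    # ATAC groups of 2 trip the small-group warning by design; expected here
    counts$rna[[tis]] <- simulate_counts(
      gene_ids, c(k_rna, k_rna),
      lfc = if (signal) gene_lfc else 0,
      baseline_mean = gene_base, nb_dispersion = config$nb_dispersion,
      seed = substream_seed(config$seed, paste0("rna_", tis)),
      sample_ids = c(ext_rna$high, ext_rna$low)
    )$counts
    counts$atac[[tis]] <- suppressWarnings(simulate_counts(
      peak_ids, c(k_atac, k_atac),
      lfc = if (signal) peak_lfc else 0,
      baseline_mean = peak_base, nb_dispersion = config$nb_dispersion,
      seed = substream_seed(config$seed, paste0("atac_", tis)),
      sample_ids = c(ext_atac$high, ext_atac$low)
    ))$counts
  }

  truth <- list(
    causal_variants = ph$truth$causal_variants,
    expected_links = links,
    de_features = list(
      rna = data.frame(id = names(gene_lfc)[gene_lfc != 0],
                       lfc = unname(gene_lfc[gene_lfc != 0]),
                       tissue = tissues[1], stringsAsFactors = FALSE),
      atac = data.frame(id = names(peak_lfc)[peak_lfc != 0],
                        lfc = unname(peak_lfc[peak_lfc != 0]),
                        tissue = tissues[1], stringsAsFactors = FALSE)
    ),
    growth_outliers = growth$truth$outliers,
    h2 = config$h2
  )

  list(genotypes = G, phenotype = ph$phenotype, growth = growth$records,
       peaks = land$peaks, tads = land$tads, genes = land$genes,
       counts = counts,
       groups = list(rna = ext_rna, atac = ext_atac),
       truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits the formats the pipeline readers consume: a VCF for genotypes,
#' BED6 for peaks/TADs/genes, TSV for phenotype, growth and counts, and a
#' JSON truth file.
#'
#' @param data output of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_dataset <- function(data, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  paths <- c(
    genotypes = p("genotypes.vcf"), phenotype = p("phenotype.tsv"),
    growth = p("growth.tsv"), peaks = p("peaks.bed"), tads = p("tads.bed"),
    genes = p("genes.bed"), truth = p("truth.json")
  )
  write_vcf(data$genotypes, paths["genotypes"])
  write_phenotypes(data$phenotype, paths["phenotype"])
  write_growth(data$growth, paths["growth"])
  write_bed(data$peaks, paths["peaks"])
  write_bed(data$tads, paths["tads"])
  write_bed(data$genes, paths["genes"])
  for (layer in names(data$counts)) {
    for (tis in names(data$counts[[layer]])) {
      f <- p(sprintf("counts_%s_%s.tsv", layer, tis))
      write_counts(data$counts[[layer]][[tis]], f)
      paths[paste0("counts_", layer, "_", tis)] <- f
    }
  }
  jsonlite::write_json(data$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}
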