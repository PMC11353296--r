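#' Simulate a regulatory landscape (TADs, ATAC peaks, gene models)
#'
#' Non-overlapping topologically associated domains (TADs) partition each
#' chromosome (with gaps); peaks and genes are placed inside TADs. For every
#' planted link the causal variant's position ends up inside a dedicated
#' peak, and the peak and its target gene lie inside the same TAD — the
#' structure the downstream integration stage is meant to recover.
#'
#' @param config a [sim_config()]; uses `n_tads`, `n_peaks`, `n_genes`,
#'   `planted_links`, `chrom_length`, `n_chromosomes`, `seed`.
#' @param G the [genotype_matrix()] whose coordinates the landscape must be
#'   consistent with (required when links are planted).
#' @param peak_width,gene_width ranges (bp) for random peak and gene sizes.
#' @return list with `peaks`, `tads`, `genes` (each an [interval_set()],
#'   0-based half-open) and `truth` (`expected_links` data.frame of
#'   variant id / peak id / gene id / lfc).
#' @export
simulate_regulatory_landscape <- function(config, G = NULL,
                                          peak_width = c(300, 800),
                                          gene_width = c(2000, 20000)) {
  set.seed(substream_seed(config$seed, "landscape"))
  n_chr <- config$n_chromosomes
  L <- config$chrom_length
  tads_per_chr <- rep(config$n_tads %/% n_chr, n_chr)
  if (config$n_tads %% n_chr) {
    tads_per_chr[seq_len(config$n_tads %% n_chr)] <-
      tads_per_chr[seq_len(config$n_tads %% n_chr)] + 1
  }
  if (max(gene_width) * 2 > L / max(tads_per_chr)) {
    stop("gene_width too large for the TAD sizes implied by chrom_length")
  }

  tad_rows <- list()
  k <- 0
  for (ch in seq_len(n_chr)) {
    nt <- tads_per_chr[ch]
    if (!nt) next
    # random partition into nt segments, then shave a small gap off each end
    cuts <- sort(sample.int(L - 1, nt - 1))
    bounds <- c(0, cuts, L)
    for (i in seq_len(nt)) {
      k <- k + 1
      s <- bounds[i]
      e <- bounds[i + 1]
      gap <- floor(min(0.05 * (e - s), 5000))
      tad_rows[[k]] <- data.frame(
        chrom = as.character(ch), start = s + gap, end = e - gap,
        id = sprintf("tad%03d", k), stringsAsFactors = FALSE
      )
    }
  }
  tads <- do.call(rbind, tad_rows)
  tads <- tads[tads$end > tads$start, , drop = FALSE]

  links <- config$planted_links
  expected <- NULL
  planted_peaks <- NULL
  planted_genes <- NULL
  if (!is.null(links) && nrow(links)) {
    if (is.null(G)) stop("planted links require the genotype matrix")
    planted_peaks <- vector("list", nrow(links))
    planted_genes <- vector("list", nrow(links))
    expected <- links
    expected$variant_id <- G$variants$id[links$variant]
    for (i in seq_len(nrow(links))) {
      v <- G$variants[links$variant[i], ]
      # variant pos is 1-based; its 0-based coordinate is pos - 1
      p0 <- v$pos - 1
      hit <- which(tads$chrom == v$chrom & tads$start <= p0 & p0 < tads$end)
      if (!length(hit)) {
        # variant fell in an inter-TAD gap: extend the nearest TAD over it
        cand <- which(tads$chrom == v$chrom)
        if (!length(cand)) stop("no TAD on the causal variant's chromosome")
        d <- pmin(abs(tads$start[cand] - p0), abs(tads$end[cand] - 1 - p0))
        hit <- cand[which.min(d)]
        tads$start[hit] <- min(tads$start[hit], p0)
        tads$end[hit] <- max(tads$end[hit], p0 + 1)
      } else {
        hit <- hit[1]
      }
      tad <- tads[hit, ]
      w <- round(stats::runif(1, peak_width[1], peak_width[2]))
      if (w > tad$end - tad$start) {
        stop("planted peak (", w, " bp) longer than its TAD")
      }
      ps <- max(tad$start, min(p0 - w %/% 2, tad$end - w))
      planted_peaks[[i]] <- data.frame(
        chrom = v$chrom, start = ps, end = ps + w,
        id = sprintf("peak_planted%d", i), stringsAsFactors = FALSE
      )
      gw <- round(stats::runif(1, gene_width[1], gene_width[2]))
      gw <- min(gw, tad$end - tad$start)
      gs <- round(stats::runif(1, tad$start, tad$end - gw))
      planted_genes[[i]] <- data.frame(
        chrom = v$chrom, start = gs, end = gs + gw,
        id = sprintf("gene_planted%d", i), stringsAsFactors = FALSE
      )
      expected$peak_id[i] <- planted_peaks[[i]]$id
      expected$gene_id[i] <- planted_genes[[i]]$id
      expected$tad_id[i] <- tad$id
    }
    planted_peaks <- do.call(rbind, planted_peaks)
    planted_genes <- do.call(rbind, planted_genes)
  }

  place_in_tads <- function(n, width_range, prefix) {
    if (!n) return(NULL)
    rows <- vector("list", n)
    ti <- sample(nrow(tads), n, replace = TRUE)
    for (i in seq_len(n)) {
      tad <- tads[ti[i], ]
      w <- round(stats::runif(1, width_range[1], width_range[2]))
      w <- min(w, tad$end - tad$start)
      s <- round(stats::runif(1, tad$start, tad$end - w))
      rows[[i]] <- data.frame(chrom = tad$chrom, start = s, end = s + w,
                              id = sprintf("%s%04d", prefix, i),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  n_extra_peaks <- config$n_peaks - NROW(planted_peaks)
  n_extra_genes <- config$n_genes - NROW(planted_genes)
  peaks <- rbind(planted_peaks, place_in_tads(n_extra_peaks, peak_width, "peak"))
  genes <- rbind(planted_genes, place_in_tads(n_extra_genes, gene_width, "gene"))
  peaks$strand <- "."
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)

  list(
    peaks = interval_set(peaks),
    tads = interval_set(tads),
    genes = interval_set(genes),
    truth = list(expected_links = expected)
  )
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Counts are drawn NB with mean
#' `size_factor * baseline * 2^(lfc * group_indicator)` and variance
#' `mu + alpha * mu^2`; `alpha = 0` degenerates to Poisson. The group
#' indicator is 1 for "high" samples.
#'
#' @param feature_ids character feature ids.
#' @param group_sizes integer vector `c(high, low)` (or one value used for
#'   both groups).
#' @param lfc per-feature true log2 fold change (high vs low); recycled.
#' @param baseline_mean per-feature baseline mean (> 0); recycled.
#' @param nb_dispersion NB dispersion alpha >= 0.
#' @param size_factors per-sample positive factors (default all 1).
#' @param seed integer seed.
#' @param sample_ids optional sample ids (high group first).
#' @return list with `counts` (a [count_matrix()], group levels
#'   `low`/`high`) and `truth` (`de_features`: id + lfc of features with
#'   nonzero planted lfc).
#' @export
simulate_counts <- function(feature_ids, group_sizes, lfc = 0,
                            baseline_mean = 100, nb_dispersion = 0,
                            size_factors = NULL, seed = 1,
                            sample_ids = NULL) {
  nf <- length(feature_ids)
  if (length(group_sizes) == 1) group_sizes <- rep(group_sizes, 2)
  ns <- sum(group_sizes)
  lfc <- rep_len(lfc, nf)
  baseline_mean <- rep_len(baseline_mean, nf)
  check_range(baseline_mean, "baseline_mean", lo = 0, lo_open = TRUE)
  check_range(nb_dispersion, "nb_dispersion", lo = 0)
  if (is.null(size_factors)) size_factors <- rep(1, ns)
  check_range(size_factors, "size_factors", lo = 0, lo_open = TRUE)
  stopifnot(length(size_factors) == ns)
  set.seed(substream_seed(seed, "counts"))
  grp <- factor(rep(c("high", "low"), group_sizes), levels = c("low", "high"))
  if (is.null(sample_ids)) {
    sample_ids <- paste0(rep(c("high", "low"), group_sizes), "_",
                         c(seq_len(group_sizes[1]), seq_len(group_sizes[2])))
  }
  ind <- as.numeric(grp == "high")
  mu <- outer(baseline_mean, rep(1, ns)) *
    2^(outer(lfc, ind)) *
    outer(rep(1, nf), size_factors)
  counts <- if (nb_dispersion == 0) {
    matrix(stats::rpois(nf * ns, lambda = mu), nf, ns)
  } else {
    matrix(stats::rnbinom(nf * ns, mu = mu, size = 1 / nb_dispersion), nf, ns)
  }
  dimnames(counts) <- list(feature_ids, sample_ids)
  de <- lfc != 0
  list(
    counts = count_matrix(counts, grp),
    truth = list(de_features = data.frame(id = feature_ids[de],
                                          lfc = lfc[de],
                                          stringsAsFactors = FALSE))
  )
}
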