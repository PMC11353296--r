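#' Read genotypes from a VCF
#'
#' Diploid GT genotypes become alternate-allele dosages (0/1/2); `./.`
#' becomes missing. Multi-allelic records and malformed GT strings are
#' rejected with the offending record named.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)    # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic record(s) at VCF data line(s): ",
         paste(utils::head(which(multi), 5), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  core <- gsub("[|]", "/", gt)
  dos <- matrix(NA_real_, nrow(core), ncol(core), dimnames = dimnames(core))
  dos[core %in% c("0/0")] <- 0
  dos[core %in% c("0/1", "1/0")] <- 1
  dos[core %in% c("1/1")] <- 2
  known_missing <- is.na(core) | core %in% c("./.", ".")
  bad <- which(is.na(dos) & !known_missing)
  if (length(bad)) {
    stop("malformed GT value(s), e.g. record ", ((bad[1] - 1) %% nrow(core)) + 1,
         ": '", core[bad[1]], "'")
  }
  ids <- fix$ID
  need_id <- is.na(ids) | ids == "."
  ids[need_id] <- paste0(fix$CHROM[need_id], "_", fix$POS[need_id])
  variants <- data.frame(
    id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  genotype_matrix(t(dos), variants)
}

#' Write genotypes to a VCF (GT field only)
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(G, path) {
  v <- G$variants
  gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- apply(G$dosages, 2, function(col) {
    ifelse(is.na(col), "./.", gt[as.character(col)])
  })                                  # samples x variants -> transpose below
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$samples), collapse = "\t")
  )
  recs <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".", "GT",
                apply(t(body), 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, recs), path)
  invisible(path)
}

#' Read an interval set from a BED file
#'
#' BED3+ with optional name, score, strand columns; coordinates are kept
#' verbatim (0-based half-open) and validated.
#'
#' @param path BED file.
#' @return an [interval_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("BED needs at least 3 columns: ", path)
  names(d)[1:min(6, ncol(d))] <-
    c("chrom", "start", "end", "id", "score", "strand")[1:min(6, ncol(d))]
  d$chrom <- as.character(d$chrom)
  interval_set(d)
}

#' Write an interval set to a BED6 file
#'
#' @param x an [interval_set()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  x <- if (inherits(x, "interval_set")) x else interval_set(x)
  d <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end, id = x$id,
    score = if (is.null(x$score)) 0 else x$score,
    strand = if (is.null(x$strand)) "." else x$strand
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample count matrix from TSV
#'
#' First column = feature id, remaining columns = samples (header row
#' mandatory). Duplicate feature or sample ids are rejected.
#'
#' @param path TSV file.
#' @return integer matrix with feature rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(d[[1]])) stop("duplicate feature ids in ", path)
  if (anyDuplicated(names(d)[-1])) stop("duplicate sample ids in ", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers in ", path)
  }
  m
}

#' Write a count matrix to TSV
#'
#' @param x a [count_matrix()] or plain matrix.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_counts <- function(x, path) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  d <- data.frame(feature = rownames(m), m, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table from TSV
#'
#' One row per animal; column `animal` mandatory, duplicates rejected.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = c(animal = "character"))
  if (!"animal" %in% names(d)) stop("phenotype table needs an `animal` column")
  if (anyDuplicated(d$animal)) stop("duplicate animal ids in ", path)
  d
}

#' @rdname read_phenotypes
#' @param x phenotype data.frame.
#' @export
write_phenotypes <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read growth records from TSV
#'
#' Columns `animal`, `age_days`, `weight`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_growth <- function(path) {
  if (!file.exists(path)) stop("growth file not found: ", path)
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = c(animal = "character"))
  need <- c("animal", "age_days", "weight")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("growth table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(d$age_days) || !is.numeric(d$weight)) {
    stop("age_days and weight must be numeric in ", path)
  }
  d
}

#' @rdname read_growth
#' @param x growth data.frame.
#' @export
write_growth <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a plain dosage TSV (test dialect)
#'
#' Columns `id`, `chrom`, `pos`, `ref`, `alt`, then one column per sample;
#' missing dosages are the literal `NA`.
#'
#' @param path TSV file.
#' @return a [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  meta <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(meta, names(d))
  if (length(miss)) stop("dosage TSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  dos <- t(as.matrix(d[, setdiff(names(d), meta), drop = FALSE]))
  colnames(dos) <- d$id
  genotype_matrix(dos, d[meta])
}

#' @rdname read_dosage_tsv
#' @param G a [genotype_matrix()].
#' @export
write_dosage_tsv <- function(G, path) {
  d <- cbind(G$variants, as.data.frame(t(G$dosages), check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
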