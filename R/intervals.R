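#' Genomic interval set (0-based half-open)
#'
#' A validated data.frame of intervals in BED convention: `start` is
#' 0-based, `end` exclusive, `start < end`, ids unique. Chromosome names
#' are normalized (leading "chr" stripped).
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `id` (generated when absent), `score`, `strand`, plus any extra
#'   annotation columns.
#' @return data.frame of class `interval_set`.
#' @export
interval_set <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("interval set lacks column(s): ",
                         paste(miss, collapse = ", "))
  x$chrom <- normalize_chrom(x$chrom)
  if (!is.numeric(x$start) || !is.numeric(x$end)) {
    stop("interval start/end must be numeric")
  }
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    stop("malformed interval(s) with start >= end at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(x$start < 0)) stop("interval starts must be >= 0")
  if (is.null(x$id)) x$id <- sprintf("iv%05d", seq_len(nrow(x)))
  if (anyDuplicated(x$id)) stop("interval ids must be unique")
  rownames(x) <- NULL
  class(x) <- c("interval_set", "data.frame")
  x
}

# IRanges view of an interval set in 1-based closed coordinates, per
# chromosome; a 0-based half-open [start, end) covers 1-based start+1..end.
iranges_by_chrom <- function(x) {
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(i) {
    list(idx = i, ir = IRanges::IRanges(start = x$start[i] + 1L,
                                        end = x$end[i]))
  })
}

#' Variants overlapping regions
#'
#' A variant at 1-based position `p` overlaps a 0-based half-open region
#' `[start, end)` iff `start < p <= end`. All (variant, region) pairs are
#' returned; the implementation uses indexed interval overlap but is
#' contract-identical to the double loop.
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based);
#'   an `mlma_scan` works directly.
#' @param regions an [interval_set()].
#' @return data.frame with columns `variant_id`, `region_id` (zero rows
#'   when nothing overlaps).
#' @export
snps_in_regions <- function(variants, regions) {
  variants <- as.data.frame(variants)
  stopifnot(all(c("id", "chrom", "pos") %in% names(variants)))
  regions <- if (inherits(regions, "interval_set")) regions else interval_set(regions)
  out <- list()
  vchrom <- normalize_chrom(variants$chrom)
  by_chr <- iranges_by_chrom(regions)
  for (ch in names(by_chr)) {
    vi <- which(vchrom == ch)
    if (!length(vi)) next
    q <- IRanges::IRanges(start = variants$pos[vi], width = 1L)
    hits <- IRanges::findOverlaps(q, by_chr[[ch]]$ir)
    if (!length(hits)) next
    out[[ch]] <- data.frame(
      variant_id = variants$id[vi][S4Vectors::queryHits(hits)],
      region_id = regions$id[by_chr[[ch]]$idx][S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(variant_id = character(0), region_id = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Validate that TADs are non-overlapping per chromosome
#'
#' @param tads an [interval_set()].
#' @return invisibly, the TADs; errors listing offending ids otherwise.
#' @export
validate_tads <- function(tads) {
  tads <- if (inherits(tads, "interval_set")) tads else interval_set(tads)
  for (ch in unique(tads$chrom)) {
    t_c <- tads[tads$chrom == ch, ]
    t_c <- t_c[order(t_c$start), ]
    ov <- which(t_c$start[-1] < t_c$end[-nrow(t_c)])
    if (length(ov)) {
      stop("overlapping TADs on chromosome ", ch, ": ",
           paste(sprintf("%s/%s", t_c$id[ov], t_c$id[ov + 1]), collapse = ", "))
    }
  }
  invisible(tads)
}

#' Assign positions or intervals to their containing TAD
#'
#' A 1-based position gets the unique TAD containing it, or `NA` in an
#' inter-TAD gap. An interval is assigned only when fully contained
#' (features straddling a TAD boundary get `NA`).
#'
#' @param x either a data.frame with `chrom` and `pos` (1-based
#'   positions), or one with `chrom`, `start`, `end` (0-based half-open
#'   intervals).
#' @param tads an [interval_set()]; validated to be non-overlapping per
#'   chromosome.
#' @return character vector of TAD ids (NA where unassigned), one per row
#'   of `x`.
#' @export
assign_tad <- function(x, tads) {
  tads <- validate_tads(tads)
  x <- as.data.frame(x)
  out <- rep(NA_character_, nrow(x))
  xchrom <- normalize_chrom(x$chrom)
  as_pos <- "pos" %in% names(x)
  if (!as_pos) stopifnot(all(c("start", "end") %in% names(x)))
  by_chr <- iranges_by_chrom(tads)
  for (ch in names(by_chr)) {
    xi <- which(xchrom == ch)
    if (!length(xi)) next
    q <- if (as_pos) {
      IRanges::IRanges(start = x$pos[xi], width = 1L)
    } else {
      IRanges::IRanges(start = x$start[xi] + 1L, end = x$end[xi])
    }
    hits <- IRanges::findOverlaps(q, by_chr[[ch]]$ir, type = "within")
    out[xi[S4Vectors::queryHits(hits)]] <-
      tads$id[by_chr[[ch]]$idx][S4Vectors::subjectHits(hits)]
  }
  out
}
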