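#' @keywords internal
"_PACKAGE"

# Coordinate conventions: variant positions are 1-based (VCF); all interval
# records are 0-based half-open (BED). These two helpers own the conversion;
# nothing else in the package re-derives it.

#' Convert 1-based positions to 0-based half-open intervals
#'
#' @param pos integer vector of 1-based positions.
#' @return a two-column matrix with `start` (0-based) and `end` (exclusive),
#'   each interval covering exactly the input base.
#' @export
pos_to_interval <- function(pos) {
  stopifnot(is.numeric(pos), all(pos >= 1))
  cbind(start = as.integer(pos) - 1L, end = as.integer(pos))
}

#' Does a 0-based half-open interval contain a 1-based position?
#'
#' A 1-based position `p` lies inside `[start, end)` iff `start < p <= end`.
#'
#' @param start,end interval bounds, 0-based half-open.
#' @param pos 1-based position(s).
#' @return logical vector.
#' @export
interval_contains_pos <- function(start, end, pos) {
  start < pos & pos <= end
}

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix so that "chr2" and "2" compare equal.
#' Applied symmetrically at every file load.
#'
#' @param x character vector of chromosome names.
#' @return normalized character vector.
#' @export
normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x))
}

# Deterministic per-stage substreams: all randomness flows from one config
# seed; each named stage derives its own seed so stages can be re-run in
# isolation without disturbing each other. Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Shared argument check with a message naming the violated bound.
check_range <- function(x, name, lo = -Inf, hi = Inf,
                        lo_open = FALSE, hi_open = FALSE) {
  ok_lo <- if (lo_open) x > lo else x >= lo
  ok_hi <- if (hi_open) x < hi else x <= hi
  if (!all(is.finite(x)) || !all(ok_lo) || !all(ok_hi)) {
    stop(sprintf(
      "`%s` must lie in %s%s, %s%s; got %s", name,
      if (lo_open) "(" else "[", format(lo), format(hi),
      if (hi_open) ")" else "]", paste(format(x), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}
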