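#' Coverage configuration for the exome target
#'
#' @param min_depth minimum read depth that counts a base as covered
#'   (default 20, the ">20 reads" summary threshold)
#' @return object of class `coverage_config`
#' @export
coverage_config <- function(min_depth = 20L) {
  if (min_depth < 1) stop("min_depth must be >= 1")
  structure(list(min_depth = as.integer(min_depth)), class = "coverage_config")
}

#' Summarise per-base depth over the capture target
#'
#' The fraction of target bases with depth at or above the threshold, plus a
#' depth histogram (counts of bases per depth value; the histogram sums to
#' the target length). Intervals, when given, are normalised
#' (sorted and merged) before use, and `depths` must then have one value per
#' normalised target base.
#'
#' @param depths integer vector of per-base depths over the target
#' @param cfg a [coverage_config()]
#' @param intervals optional data.frame (chrom, start, end, 1-based
#'   inclusive) describing the target; only used to validate/normalise length
#' @return list(fraction, histogram, n_bases)
#' @export
coverage_summary <- function(depths, cfg = coverage_config(),
                             intervals = NULL) {
  if (!length(depths)) stop("empty target")
  if (anyNA(depths) || any(depths < 0)) stop("depths must be non-negative")
  if (!is.null(intervals)) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      intervals$chrom, IRanges::IRanges(intervals$start, intervals$end)))
    width <- sum(GenomicRanges::width(gr))
    if (width != length(depths))
      stop("depth track length (", length(depths),
           ") does not match normalised target width (", width, ")")
  }
  tab <- tabulate(depths + 1L, nbins = max(depths) + 1L)
  names(tab) <- 0:max(depths)
  list(fraction = mean(depths >= cfg$min_depth),
       histogram = tab,
       n_bases = length(depths))
}
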