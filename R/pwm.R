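#' Splicing-factor position weight matrix
#'
#' A 4 x L additive scoring matrix of the kind ESEfinder uses for SR-protein
#' motifs (SRSF1/SRSF2(SC35)/...), with a threshold above which a window is
#' called a motif hit. The window score is the sum of the per-position
#' entries for the window's bases (the score ESEfinder reports for a motif).
#'
#' @param scores numeric matrix with rownames A,C,G,T and L >= 1 columns
#' @param factor splicing-factor name (e.g. "SRSF2")
#' @param threshold hit threshold
#' @return object of class `weight_matrix`
#' @export
weight_matrix <- function(scores, factor = "factor", threshold = 0) {
  stopifnot(is.matrix(scores), is.numeric(scores))
  if (!identical(rownames(scores), DNA_BASES))
    stop("scores must have rownames A,C,G,T")
  if (ncol(scores) < 1L) stop("matrix width must be >= 1")
  if (anyNA(scores)) stop("all four bases must be scored at every position")
  structure(list(scores = scores, factor = factor, threshold = threshold,
                 width = ncol(scores)),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("weight_matrix %s: width %d, threshold %.3g\n",
              x$factor, x$width, x$threshold))
  invisible(x)
}

#' Read / write a weight matrix as TSV
#'
#' Format: two header lines `factor<TAB>NAME` and `threshold<TAB>VALUE`
#' followed by four rows `A/C/G/T<TAB>s1<TAB>...<TAB>sL`. This is the shape
#' in which the published ESEfinder matrices are distributed as text, so a
#' user-supplied copy of the real SRSF2/SC35 matrix can be dropped in.
#'
#' @param path TSV file path
#' @return a [weight_matrix()]
#' @export
read_pwm_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  toks <- strsplit(lines, "\t")
  keyed <- setNames(toks, vapply(toks, `[[`, "", 1L))
  if (is.null(keyed[["factor"]]) || is.null(keyed[["threshold"]]))
    stop("missing factor/threshold header lines")
  rows <- lapply(DNA_BASES, function(b) {
    r <- keyed[[b]]
    if (is.null(r)) stop("missing row for base ", b)
    as.numeric(r[-1L])
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- DNA_BASES
  weight_matrix(scores, factor = keyed[["factor"]][2L],
                threshold = as.numeric(keyed[["threshold"]][2L]))
}

#' @rdname read_pwm_tsv
#' @param wm a [weight_matrix()]
#' @export
write_pwm_tsv <- function(wm, path) {
  lines <- c(paste("factor", wm$factor, sep = "\t"),
             paste("threshold", format(wm$threshold), sep = "\t"),
             vapply(DNA_BASES, function(b)
               paste(c(b, format(wm$scores[b, ])), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Score a single window against a weight matrix
#'
#' @param window sequence of exactly the matrix width (A/C/G/T only)
#' @param wm a [weight_matrix()]
#' @return the additive window score
#' @export
score_window <- function(window, wm) {
  if (nchar(window) != wm$width)
    stop("window length must equal matrix width")
  assert_dna(window, "window")
  b <- strsplit(window, "")[[1L]]
  sum(wm$scores[cbind(match(b, DNA_BASES), seq_len(wm$width))])
}

#' Scan a sequence for splicing-factor motif hits
#'
#' Every window of the matrix width is scored left to right; windows scoring
#' above the threshold are flagged as hits.
#'
#' @param sequence query sequence (length >= matrix width, A/C/G/T only)
#' @param wm a [weight_matrix()]
#' @param report_all if TRUE, return every window; otherwise only
#'   above-threshold hits
#' @return data.table with columns start (1-based), window, score,
#'   above_threshold
#' @export
scan_ese <- function(sequence, wm, report_all = FALSE) {
  n <- nchar(sequence)
  if (n < wm$width) stop("sequence shorter than matrix width")
  assert_dna(sequence, "sequence")
  idx <- match(strsplit(sequence, "")[[1L]], DNA_BASES)
  n_win <- n - wm$width + 1L
  score <- numeric(n_win)
  for (j in seq_len(wm$width))
    score <- score + wm$scores[cbind(idx[j:(n_win + j - 1L)], j)]
  hits <- data.table::data.table(
    start = seq_len(n_win),
    window = substring(sequence, seq_len(n_win), seq_len(n_win) + wm$width - 1L),
    score = score,
    above_threshold = score > wm$threshold)
  if (report_all) hits else hits[hits$above_threshold, ]
}

#' Contrast the motif strength of two alleles at a site
#'
#' All matrix-width windows overlapping the variant position are scored with
#' the reference and with the alternate base substituted; the maxima and
#' their difference quantify whether the substitution strengthens the motif
#' (the allele contrast ESEfinder-style analyses report, e.g. 3.19 vs 2.82
#' for the G vs A allele of the reference lesion with the published SRSF2
#' matrix).
#'
#' @param context context sequence containing the variant
#' @param offset 1-based position of the variant within `context`
#' @param ref,alt reference / alternate base; `ref` must match the context
#' @param wm a [weight_matrix()]
#' @return list(ref_max, alt_max, delta = alt_max - ref_max, ref_hits,
#'   alt_hits) where the hit tables cover the overlapping windows only
#' @export
compare_alleles <- function(context, offset, ref, alt, wm) {
  n <- nchar(context)
  stopifnot(offset >= 1, offset <= n)
  if (substr(context, offset, offset) != ref)
    stop("reference allele mismatch at offset ", offset)
  alt_context <- context
  substr(alt_context, offset, offset) <- alt
  lo <- max(1L, offset - wm$width + 1L)
  hi <- min(n - wm$width + 1L, offset)
  if (hi < lo)
    return(list(ref_max = NA_real_, alt_max = NA_real_, delta = 0,
                ref_hits = NULL, alt_hits = NULL))
  window_of <- function(s, st) substr(s, st, st + wm$width - 1L)
  starts <- lo:hi
  ref_hits <- data.table::data.table(
    start = starts,
    window = vapply(starts, function(s) window_of(context, s), ""),
    score = vapply(starts, function(s) score_window(window_of(context, s), wm),
                   numeric(1L)))
  alt_hits <- data.table::data.table(
    start = starts,
    window = vapply(starts, function(s) window_of(alt_context, s), ""),
    score = vapply(starts, function(s)
      score_window(window_of(alt_context, s), wm), numeric(1L)))
  list(ref_max = max(ref_hits$score), alt_max = max(alt_hits$score),
       delta = max(alt_hits$score) - max(ref_hits$score),
       ref_hits = ref_hits, alt_hits = alt_hits)
}
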