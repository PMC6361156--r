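#' SNP QC thresholds
#'
#' Defaults follow standard array QC for a family cohort: drop markers with
#' call rate < 0.90, minor allele frequency < 0.05, or an exact
#' Hardy-Weinberg test p-value < 1e-3.
#'
#' @param min_call_rate,min_maf,hwe_alpha thresholds, each in (0, 1)
#' @return object of class `qc_thresholds`
#' @export
qc_thresholds <- function(min_call_rate = 0.90, min_maf = 0.05,
                          hwe_alpha = 1e-3) {
  vals <- c(min_call_rate, min_maf, hwe_alpha)
  if (any(vals <= 0 | vals >= 1)) stop("thresholds must be in (0,1)")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha), class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided conditional exact test: given the observed allele counts, sums
#' the probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count (the usual exact HWE test; a
#' chi-squared variant is available via `method = "chisq"` for the asymptotic
#' flavour).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, sum > 0)
#' @param method "exact" (default) or "chisq"
#' @return p-value in \[0, 1\]
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa, method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  N <- n_AA + n_Aa + n_aa
  if (N == 0) stop("no genotyped individuals")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (method == "chisq") {
    p <- nA / (2 * N)
    e <- c(N * p^2, 2 * N * p * (1 - p), N * (1 - p)^2)
    o <- c(n_AA, n_Aa, n_aa)
    if (any(e == 0)) return(1)
    x2 <- sum((o - e)^2 / e)
    return(pchisq(x2, df = 1, lower.tail = FALSE))
  }
  if (nA == 0 || na == 0) return(1)  # single attainable outcome
  h <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  lp <- h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

## individuals treated as founders for allele-frequency purposes: no parent
## of theirs is also genotyped (avoids counting transmitted alleles twice)
effective_founders <- function(gm, ped) {
  ids <- colnames(gm$geno)
  idx <- match(ids, ped$id)
  sire_in <- !is.na(ped$sire[idx]) & ped$sire[idx] %in% ids
  dam_in <- !is.na(ped$dam[idx]) & ped$dam[idx] %in% ids
  ids[!(sire_in | dam_in)]
}

marker_maf <- function(geno_rows) {
  p <- rowMeans(geno_rows, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' SNP-array quality control filter
#'
#' Removes markers in three ordered steps: call rate (over all genotyped
#' animals), minor allele frequency, and exact Hardy-Weinberg test. Allele
#' frequency and HWE are computed on the `maf_population` ("founders":
#' genotyped animals without genotyped parents, the default, avoiding
#' pedigree-induced genotype correlations; or "all").
#'
#' @param gm a `genotype_matrix`
#' @param ped a [pedigree()]
#' @param thresholds a [qc_thresholds()]
#' @param maf_population "founders" or "all"
#' @return list(gm = filtered matrix, report = per-step removal table)
#' @export
qc_filter <- function(gm, ped, thresholds = qc_thresholds(),
                      maf_population = c("founders", "all")) {
  maf_population <- match.arg(maf_population)
  if (nrow(gm$geno) == 0L) stop("empty genotype matrix")
  freq_ids <- if (maf_population == "founders")
    effective_founders(gm, ped) else colnames(gm$geno)
  if (!length(freq_ids)) freq_ids <- colnames(gm$geno)

  steps <- list()
  keep <- rep(TRUE, nrow(gm$geno))

  cr <- rowMeans(!is.na(gm$geno))
  fail <- keep & cr < thresholds$min_call_rate
  steps$call_rate <- c(n_in = sum(keep), n_removed = sum(fail))
  keep <- keep & !fail

  maf <- marker_maf(gm$geno[, freq_ids, drop = FALSE])
  fail <- keep & (!is.na(maf) & maf < thresholds$min_maf | is.na(maf))
  steps$maf <- c(n_in = sum(keep), n_removed = sum(fail))
  keep <- keep & !fail

  g <- gm$geno[, freq_ids, drop = FALSE]
  hwe_p <- vapply(which(keep), function(i) {
    gi <- g[i, ]
    hwe_exact_p(sum(gi == 0L, na.rm = TRUE), sum(gi == 1L, na.rm = TRUE),
                sum(gi == 2L, na.rm = TRUE))
  }, numeric(1L))
  fail_i <- which(keep)[hwe_p < thresholds$hwe_alpha]
  steps$hwe <- c(n_in = sum(keep), n_removed = length(fail_i))
  keep[fail_i] <- FALSE

  report <- data.table::data.table(
    step = names(steps),
    n_in = vapply(steps, `[[`, 0, "n_in"),
    n_removed = vapply(steps, `[[`, 0, "n_removed"))
  report[, n_out := n_in - n_removed]
  out <- gm
  out$geno <- gm$geno[keep, , drop = FALSE]
  out$map <- gm$map[keep, ]
  list(gm = out, report = report[])
}
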