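# shared fixtures and small simulation helpers

fx <- enumap::make_duox2_like_fixture()

# tiny single-chromosome genome for focused breeding tests
tiny_spec <- function(len = 100e6, rate = 1) {
  enumap::genome_spec(data.frame(name = "chr1", length = len),
                      recombination_rate = rate)
}

# a founder trio pedigree: two founders and n_off offspring
trio_pedigree <- function(n_off = 1) {
  enumap::pedigree(data.frame(
    id = c("F", "M", sprintf("K%02d", seq_len(n_off))),
    sire = c(NA, NA, rep("F", n_off)),
    dam = c(NA, NA, rep("M", n_off)),
    sex = c("male", "female", rep(c("male", "female"), length.out = n_off)),
    generation = c("G0", "G0", rep("G1", n_off)),
    family = "FAM1", stringsAsFactors = FALSE))
}

# a lean cohort configuration for replicated runs inside the test budget
lean_cfg <- function(...) {
  base <- list(
    sim = list(n_markers = 1500L, enu_mean = 150, n_common = 60L,
               n_decoys = 8L, n_decoys_in_region = 3L),
    tdt = list(n_perm = 200L))
  do.call(enumap::default_run_config, modifyList(base, list(...)))
}

# exhaustive double-loop scanner oracle
oracle_scan <- function(sequence, wm) {
  bases <- strsplit(sequence, "")[[1]]
  n_win <- length(bases) - wm$width + 1
  vapply(seq_len(n_win), function(s) {
    tot <- 0
    for (j in seq_len(wm$width))
      tot <- tot + wm$scores[bases[s + j - 1], j]
    tot
  }, numeric(1))
}

# brute-force TDT oracle: enumerate parental allele picks per trio
oracle_tdt <- function(genotypes, ped) {
  b <- 0L; c_ <- 0L
  ids <- names(genotypes)
  for (i in seq_len(nrow(ped))) {
    if (ped$phenotype[i] != "affected") next
    kid <- ped$id[i]; f <- ped$sire[i]; m <- ped$dam[i]
    if (is.na(f) || !all(c(kid, f, m) %in% ids)) next
    gk <- genotypes[[kid]]; gf <- genotypes[[f]]; gm_ <- genotypes[[m]]
    if (anyNA(c(gk, gf, gm_))) next
    alleles <- function(g) if (g == 0) c(0, 0) else if (g == 1) c(0, 1) else c(1, 1)
    totals <- NULL
    for (af in unique(alleles(gf))) for (am in unique(alleles(gm_))) {
      if (af + am != gk) next
      db <- 0L; dc <- 0L
      if (gf == 1) { if (af == 1) db <- db + 1L else dc <- dc + 1L }
      if (gm_ == 1) { if (am == 1) db <- db + 1L else dc <- dc + 1L }
      totals <- rbind(totals, c(db, dc))
    }
    if (is.null(totals)) next                      # Mendelian inconsistency
    totals <- unique(totals)
    stopifnot(nrow(totals) == 1L)                  # resolution is unique
    b <- b + totals[1L, 1L]; c_ <- c_ + totals[1L, 2L]
  }
  list(b = b, c = c_)
}

# independent exact-HWE oracle: enumerate genotype configurations with the
# observed allele counts and sum probabilities no larger than the observed one
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  N <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hs <- seq.int(nA %% 2, min(nA, 2 * N - nA), by = 2)
  lp <- vapply(hs, function(h) {
    naa <- (nA - h) / 2; nbb <- N - naa - h
    lfactorial(N) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) - (lfactorial(2 * N) - lfactorial(nA) - lfactorial(2 * N - nA))
  }, numeric(1))
  pr <- exp(lp)
  sum(pr[pr <= pr[match(n_Aa, hs)] * (1 + 1e-12)]) / sum(pr)
}
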