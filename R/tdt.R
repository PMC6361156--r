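## -- transmission counting --------------------------------------------------

## Trios usable by the TDT: affected, genotyped child with both parents
## genotyped. Columns are indices into the genotype-matrix columns.
tdt_trios <- function(gm, ped) {
  ids <- colnames(gm$geno)
  ok <- ped$id %in% ids & ped$phenotype == "affected" &
    !is.na(ped$sire) & ped$sire %in% ids & ped$dam %in% ids
  data.frame(child = ped$id[ok], sire = ped$sire[ok], dam = ped$dam[ok],
             ci = match(ped$id[ok], ids), fi = match(ped$sire[ok], ids),
             mi = match(ped$dam[ok], ids), stringsAsFactors = FALSE)
}

## Transmission resolution for one marker (vectors) or many (matrices).
## f, m, c = minor-allele counts of father, mother, affected child.
## Returns TF/TM: per-(father|mother) transmission indicator of the minor
## allele (1 transmitted, 0 untransmitted, NA = parent uninformative, trio
## incomplete or Mendelian-inconsistent). A doubly-heterozygous trio with a
## heterozygous child is jointly resolved as one transmission and one
## non-transmission from the two parents.
tdt_resolve <- function(f, m, c) {
  ok <- !is.na(f) & !is.na(m) & !is.na(c) &
    c >= (f == 2L) + (m == 2L) & c <= 2L - ((f == 0L) + (m == 0L))
  tf <- array(NA_real_, dim = if (is.matrix(f)) dim(f) else length(f))
  tm <- tf
  fh <- ok & f == 1L; mh <- ok & m == 1L
  ## het father, homozygous mother: mother's transmitted count is m/2
  i <- fh & m != 1L; tf[i] <- (c - m / 2)[i]
  i <- mh & f != 1L; tm[i] <- (c - f / 2)[i]
  bh <- fh & mh
  i <- bh & c == 0L; tf[i] <- 0; tm[i] <- 0
  i <- bh & c == 2L; tf[i] <- 1; tm[i] <- 1
  i <- bh & c == 1L; tf[i] <- 1; tm[i] <- 0  # joint (1 transmitted, 1 not)
  list(TF = tf, TM = tm)
}

#' TDT transmission counts at one marker
#'
#' Over all (heterozygous parent, affected offspring) pairs in complete
#' trios, counts transmissions (`b`) and non-transmissions (`c`) of the
#' minor allele. Doubly-heterozygous trios with a heterozygous child
#' contribute one transmission and one non-transmission jointly; trios with
#' a missing genotype or a Mendelian inconsistency at the marker are skipped.
#'
#' @param genotypes named integer vector of minor-allele counts (0/1/2, NA
#'   allowed), names = individual ids
#' @param ped a [pedigree()] with phenotypes
#' @return list(b, c, n_informative)
#' @export
tdt_counts <- function(genotypes, ped) {
  if (is.null(names(genotypes))) stop("genotypes must be named by individual")
  gm <- list(geno = matrix(genotypes, nrow = 1L,
                           dimnames = list("m", names(genotypes))))
  tr <- tdt_trios(gm, ped)
  if (!nrow(tr)) return(list(b = 0L, c = 0L, n_informative = 0L))
  r <- tdt_resolve(genotypes[tr$fi], genotypes[tr$mi], genotypes[tr$ci])
  tt <- c(r$TF, r$TM)
  list(b = sum(tt == 1, na.rm = TRUE), c = sum(tt == 0, na.rm = TRUE),
       n_informative = sum(!is.na(tt)))
}

#' TDT chi-squared statistic and nominal p-value
#'
#' `chi2 = (b - c)^2 / (b + c)`, referred to a chi-squared distribution with
#' one degree of freedom. With no informative transmissions (`b + c = 0`)
#' both values are NA.
#'
#' @param b,c transmitted / untransmitted counts
#' @return list(chi2, p_nominal)
#' @export
tdt_statistic <- function(b, c) {
  n <- b + c
  chi2 <- ifelse(n > 0, (b - c)^2 / n, NA_real_)
  list(chi2 = chi2,
       p_nominal = ifelse(n > 0, pchisq(chi2, df = 1, lower.tail = FALSE),
                          NA_real_))
}

## minor-allele recode: returns the genotype matrix with counts of the minor
## allele (minor defined over all genotyped animals; ties keep allele 2)
minor_recode <- function(geno) {
  p <- rowMeans(geno, na.rm = TRUE) / 2
  flip <- !is.na(p) & p > 0.5
  geno[flip, ] <- 2L - geno[flip, , drop = FALSE]
  geno
}

## per-marker transmission tables for the whole panel: matrices TF/TM of
## dimension markers x trios
tdt_panel_events <- function(gm, ped) {
  tr <- tdt_trios(gm, ped)
  geno <- minor_recode(gm$geno)
  if (!nrow(tr)) {
    e <- matrix(NA_real_, nrow(geno), 0L)
    return(list(trios = tr, TF = e, TM = e, geno = geno))
  }
  F_ <- geno[, tr$fi, drop = FALSE]
  M_ <- geno[, tr$mi, drop = FALSE]
  C_ <- geno[, tr$ci, drop = FALSE]
  r <- tdt_resolve(F_, M_, C_)
  list(trios = tr, TF = r$TF, TM = r$TM, geno = geno)
}

#' Genome-wide TDT scan
#'
#' Applies the transmission disequilibrium test at every marker of the panel
#' over all complete affected-offspring trios.
#'
#' @param gm a `genotype_matrix`
#' @param ped a [pedigree()] with phenotypes
#' @return data.table: marker, chrom, pos, b, c, chi2, p_nominal
#' @export
tdt_scan <- function(gm, ped) {
  ev <- tdt_panel_events(gm, ped)
  TT <- cbind(ev$TF, ev$TM)
  b <- rowSums(TT == 1, na.rm = TRUE)
  c_ <- rowSums(TT == 0, na.rm = TRUE)
  st <- tdt_statistic(b, c_)
  data.table::data.table(marker = gm$map$marker, chrom = gm$map$chrom,
                         pos = gm$map$pos, b = b, c = c_,
                         chi2 = st$chi2, p_nominal = st$p_nominal)
}

#' maxT permutation correction for the TDT scan
#'
#' Each permutation flips, with probability 1/2, the transmitted /
#' untransmitted labels of every (parent, offspring) transmission unit; a
#' flip is drawn once per unit per permutation and applied at every marker,
#' preserving the between-marker correlation that the family-wise maxT
#' correction relies on. The corrected p-value of a marker is
#' `(1 + #\{permutations whose maximum statistic >= observed\}) /
#' (n_perm + 1)`.
#'
#' @param gm a `genotype_matrix`
#' @param ped a [pedigree()] with phenotypes
#' @param n_perm number of permutations (>= 1)
#' @param seed integer seed (flips are deterministic given the seed)
#' @return data.table: the [tdt_scan()] columns plus `p_corrected`
#' @export
permutation_maxT <- function(gm, ped, n_perm, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  ev <- tdt_panel_events(gm, ped)
  n_trio <- nrow(ev$trios)
  TT <- cbind(ev$TF, ev$TM)           # markers x (2 * n_trio) pair units
  b <- rowSums(TT == 1, na.rm = TRUE)
  n <- rowSums(!is.na(TT))
  st <- tdt_statistic(b, n - b)
  res <- data.table::data.table(marker = gm$map$marker, chrom = gm$map$chrom,
                                pos = gm$map$pos, b = b, c = n - b,
                                chi2 = st$chi2, p_nominal = st$p_nominal)
  if (n_trio == 0L || all(n == 0)) {
    res[, p_corrected := NA_real_]
    return(res[])
  }
  A <- ifelse(is.na(TT), 0, 1 - 2 * TT)  # markers x pairs
  Fm <- matrix(rbinom(ncol(A) * n_perm, 1L, 0.5), ncol(A), n_perm)
  B <- as.numeric(b) + A %*% Fm          # markers x n_perm
  CHI <- sweep(B * 2, 1, n)^2 / ifelse(n > 0, n, NA_real_)
  maxs <- apply(CHI, 2L, max, na.rm = TRUE)
  cnt <- vapply(st$chi2, function(x)
    if (is.na(x)) NA_integer_ else sum(maxs >= x - 1e-9), integer(1L))
  res[, p_corrected := (1 + cnt) / (n_perm + 1)]
  res[]
}

#' Call significant regions from corrected TDT results
#'
#' Markers with `p_corrected < alpha` on the same chromosome are merged into
#' one region whenever consecutive significant markers are at most
#' `merge_gap_bp` apart; region bounds are the outermost significant markers
#' and the peak is the marker with the largest statistic.
#'
#' @param results data.table from [permutation_maxT()]
#' @param alpha family-wise significance level (default 0.05)
#' @param merge_gap_bp merge gap in bp (default 10 Mb, reflecting the long
#'   linkage disequilibrium of closed pig populations)
#' @return data.table: chrom, start, end, n_significant_markers, peak_marker,
#'   peak_chi2 (zero rows when nothing is significant)
#' @export
call_significant_region <- function(results, alpha = 0.05,
                                    merge_gap_bp = 10e6) {
  sig <- results[!is.na(results$p_corrected) & results$p_corrected < alpha, ]
  out <- data.table::data.table(chrom = character(), start = numeric(),
                                end = numeric(),
                                n_significant_markers = integer(),
                                peak_marker = character(),
                                peak_chi2 = numeric())
  if (!nrow(sig)) return(out)
  sig <- sig[order(sig$chrom, sig$pos), ]
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, ]
    grp <- cumsum(c(1, diff(s$pos) > merge_gap_bp))
    for (g in unique(grp)) {
      sg <- s[grp == g, ]
      pk <- which.max(sg$chi2)
      out <- rbind(out, data.table::data.table(
        chrom = ch, start = min(sg$pos), end = max(sg$pos),
        n_significant_markers = nrow(sg), peak_marker = sg$marker[pk],
        peak_chi2 = sg$chi2[pk]))
    }
  }
  out[]
}

#' Write significant regions as BED (0-based half-open)
#' @param regions output of [call_significant_region()]
#' @param path output path
#' @export
write_regions_bed <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%.3f", regions$chrom,
                   as.integer(regions$start - 1), as.integer(regions$end),
                   regions$peak_marker, regions$peak_chi2)
  writeLines(lines, path)
  invisible(path)
}
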