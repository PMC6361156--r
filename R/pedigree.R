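#' Construct a pedigree
#'
#' A pedigree is a data.frame-backed object, one row per individual, ordered
#' so that parents precede their offspring. Founders have both parent ids
#' missing (`NA`); non-founders have both.
#'
#' @param df data.frame with columns `id`, `sire`, `dam`, `sex`
#'   ("male"/"female"), `generation` ("G0".."G3"), `family`; optional
#'   `phenotype` ("affected"/"unaffected"/"unknown"), `genotyped` (logical),
#'   `carrier` (logical design flag: this individual was selected to carry
#'   one copy of the founder mutation, emulating the test crosses that a
#'   breeding program performs)
#' @return object of class `pedigree` (also a data.frame)
#' @export
pedigree <- function(df) {
  req <- c("id", "sire", "dam", "sex", "generation", "family")
  stopifnot(is.data.frame(df), all(req %in% names(df)))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"phenotype" %in% names(df)) df$phenotype <- "unknown"
  if (!"genotyped" %in% names(df)) df$genotyped <- FALSE
  if (!"carrier" %in% names(df)) df$carrier <- FALSE
  if (anyDuplicated(df$id)) stop("duplicate individual ids")
  one_parent <- xor(is.na(df$sire), is.na(df$dam))
  if (any(one_parent)) stop("individuals must have zero or two parents")
  for (col in c("sire", "dam")) {
    known <- !is.na(df[[col]])
    if (!all(df[[col]][known] %in% df$id)) stop("unresolved parent id")
    idx <- match(df[[col]][known], df$id)
    if (any(idx >= which(known))) stop("parents must precede offspring")
  }
  if (!all(df$sex %in% c("male", "female"))) stop("sex must be male/female")
  if (!all(df$phenotype %in% c("affected", "unaffected", "unknown")))
    stop("bad phenotype value")
  ## parents precede offspring in list order, so the pedigree is acyclic
  class(df) <- c("pedigree", "data.frame")
  df
}

is_founder <- function(ped) is.na(ped$sire) & is.na(ped$dam)

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d founders), %d affected, %d genotyped\n",
              nrow(x), sum(is_founder(x)),
              sum(x$phenotype == "affected"), sum(x$genotyped)))
  invisible(x)
}

#' Default three-generation mapping-cross design
#'
#' Emulates the breeding scheme behind a recessive ENU screen pedigree:
#' one mutagenized G0 male mated to two wild-type females; four G1 carriers
#' (two per dam) each outcrossed to an unrelated wild-type mate; two G2
#' carriers per G1 cross, paired across families into four G2 carrier-pair
#' couples whose G3 litters segregate the recessive phenotype.
#'
#' The `carrier` flag records which animals the (simulated) breeder selected
#' as heterozygotes; gene dropping honours it by conditioning the transmitted
#' gamete at the causal site, exactly as progeny testing selects carriers in
#' a real program.
#'
#' @param n_families number of G2 carrier-pair families (default 4)
#' @param g3_per_family litter total per family (default 25, giving an
#'   expected 25% affected in G3)
#' @return a `pedigree`
#' @export
design_pedigree <- function(n_families = 4, g3_per_family = 25) {
  stopifnot(n_families >= 1, n_families %% 2 == 0, g3_per_family >= 1)
  rows <- list()
  add <- function(id, sire, dam, sex, gen, fam, carrier = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, sire = sire, dam = dam, sex = sex, generation = gen,
      family = fam, carrier = carrier, stringsAsFactors = FALSE)
  }
  add("G0_M1", NA, NA, "male", "G0", "F0", carrier = TRUE)
  add("G0_F1", NA, NA, "female", "G0", "F0")
  add("G0_F2", NA, NA, "female", "G0", "F0")
  ## G1: n_families carriers (alternating sex) + unrelated wild-type mates
  g1 <- character(n_families); mate <- character(n_families)
  for (i in seq_len(n_families)) {
    dam <- if (i <= ceiling(n_families / 2)) "G0_F1" else "G0_F2"
    sex <- if (i %% 2 == 1) "male" else "female"
    g1[i] <- sprintf("G1_C%d", i)
    add(g1[i], "G0_M1", dam, sex, "G1", "F0", carrier = TRUE)
    mate[i] <- sprintf("G1_W%d", i)
    add(mate[i], NA, NA, if (sex == "male") "female" else "male", "G1", "F0")
  }
  ## G2: two carriers per G1 cross (one of each sex)
  g2m <- character(n_families); g2f <- character(n_families)
  for (i in seq_len(n_families)) {
    carrier_is_male <- i %% 2 == 1
    sire <- if (carrier_is_male) g1[i] else mate[i]
    dam <- if (carrier_is_male) mate[i] else g1[i]
    g2m[i] <- sprintf("G2_M%d", i)
    g2f[i] <- sprintf("G2_F%d", i)
    add(g2m[i], sire, dam, "male", "G2", "F0", carrier = TRUE)
    add(g2f[i], sire, dam, "female", "G2", "F0", carrier = TRUE)
  }
  ## G2 carrier pairs across G1 families -> G3 litters
  pair_of <- function(i) if (i %% 2 == 1) i + 1L else i - 1L
  for (i in seq_len(n_families)) {
    fam <- sprintf("FAM%d", i)
    sire <- g2m[i]; dam <- g2f[pair_of(i)]
    for (k in seq_len(g3_per_family)) {
      add(sprintf("G3_%d_%02d", i, k), sire, dam,
          if (k %% 2 == 1) "female" else "male", "G3", fam)
    }
  }
  pedigree(do.call(rbind, rows))
}

#' Select the genotyped cohort
#'
#' Marks as genotyped: all G2 parents of G3 litters plus `n_affected` affected
#' and enough unaffected G3 animals to reach `n_unaffected` unaffected in
#' total (parents included), mirroring the 15 mutant / 25 wild-type cohort of
#' the real cross. Phenotypes must have been assigned first.
#'
#' @param ped pedigree with phenotypes
#' @param n_affected,n_unaffected cohort targets (defaults 15 / 25)
#' @param seed RNG seed used when subsampling
#' @return the pedigree with an updated `genotyped` column
#' @export
select_cohort <- function(ped, n_affected = 15, n_unaffected = 25, seed = 1) {
  stopifnot(inherits(ped, "pedigree"))
  set.seed(seed)
  ped$genotyped <- FALSE
  g3 <- ped$generation == "G3"
  parents <- ped$id %in% c(ped$sire[g3], ped$dam[g3])
  ped$genotyped[parents] <- TRUE
  aff <- which(g3 & ped$phenotype == "affected")
  una <- which(g3 & ped$phenotype == "unaffected")
  take_aff <- if (length(aff) > n_affected)
    sort(sample(aff, n_affected)) else aff
  n_un_needed <- max(0L, n_unaffected - sum(parents & ped$phenotype != "affected"))
  take_una <- if (length(una) > n_un_needed)
    sort(sample(una, n_un_needed)) else una
  ped$genotyped[c(take_aff, take_una)] <- TRUE
  ped
}
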