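## -- site tables ------------------------------------------------------------

site_id <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

empty_sites <- function() {
  data.table::data.table(id = character(), chrom = character(), pos = numeric(),
                         ref = character(), alt = character(), type = character(),
                         maf = numeric())
}

#' Simulate the ENU point-mutation burden of a mutagenized founder
#'
#' Draws a Poisson number of substitutions, places them uniformly along the
#' genome and assigns reference/alternate bases from the genome base
#' composition and the ENU substitution spectrum. The returned table is
#' sorted by chromosome and position; duplicated positions are dropped.
#'
#' @param spec a [genome_spec()]
#' @param enu an [enu_model()]
#' @param seed integer seed (the draw is deterministic given the seed)
#' @return data.table with columns id, chrom, pos, ref, alt, type ("enu"), maf
#' @export
simulate_founder_mutations <- function(spec, enu, seed) {
  stopifnot(inherits(spec, "genome_spec"), inherits(enu, "enu_model"))
  if (any(spec$chromosomes$length <= 0)) stop("zero-length genome")
  set.seed(seed)
  n <- rpois(1L, enu$mutations_per_genome)
  if (n == 0L) return(empty_sites())
  chr <- sample(spec$chromosomes$name, n, replace = TRUE,
                prob = spec$chromosomes$length)
  pos <- floor(runif(n, 1, spec$chromosomes$length[
    match(chr, spec$chromosomes$name)] + 1))
  ref <- sample(DNA_BASES, n, replace = TRUE, prob = spec$base_composition)
  alt <- vapply(ref, function(b)
    sample(DNA_BASES, 1L, prob = enu$spectrum[b, ]), "")
  dt <- data.table::data.table(chrom = chr, pos = pos, ref = ref, alt = alt,
                               type = "enu", maf = 0)
  dt <- unique(dt, by = c("chrom", "pos"))
  data.table::setorder(dt, chrom, pos)
  dt[, id := site_id(chrom, pos, ref, alt)]
  data.table::setcolorder(dt, c("id", "chrom", "pos", "ref", "alt", "type", "maf"))
  dt[]
}

## Standing variation shared with outside populations (used by the novelty
## filter as the non-novel background).
simulate_common_variants <- function(spec, n, seed,
                                     maf_distribution = function(k) runif(k, 0.05, 0.5)) {
  set.seed(seed)
  if (n == 0L) return(empty_sites())
  chr <- sample(spec$chromosomes$name, n, replace = TRUE,
                prob = spec$chromosomes$length)
  pos <- floor(runif(n, 1, spec$chromosomes$length[
    match(chr, spec$chromosomes$name)] + 1))
  ref <- sample(DNA_BASES, n, replace = TRUE, prob = spec$base_composition)
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  dt <- data.table::data.table(chrom = chr, pos = pos, ref = ref, alt = alt,
                               type = "common", maf = maf_distribution(n))
  dt <- unique(dt, by = c("chrom", "pos"))
  data.table::setorder(dt, chrom, pos)
  dt[, id := site_id(chrom, pos, ref, alt)]
  data.table::setcolorder(dt, c("id", "chrom", "pos", "ref", "alt", "type", "maf"))
  dt[]
}

## -- meiosis ----------------------------------------------------------------

## One gamete plan per chromosome: crossover positions (Haldane: Poisson
## count, uniform placement, no interference) and which parental haplotype
## the telomere-proximal segment copies.
make_gamete_plan <- function(spec) {
  lapply(seq_len(nrow(spec$chromosomes)), function(i) {
    L_morgan <- spec$chromosomes$length[i] / 1e6 * spec$recombination_rate / 100
    k <- rpois(1L, L_morgan)
    list(start = rbinom(1L, 1L, 0.5),
         xpos = sort(runif(k, 0, spec$chromosomes$length[i])))
  }) |> setNames(spec$chromosomes$name)
}

## Apply a gamete plan to a parent's two haplotypes at the given sites.
apply_gamete_plan <- function(h1, h2, plan, sites) {
  out <- integer(nrow(sites))
  for (chrom in names(plan)) {
    idx <- which(sites$chrom == chrom)
    if (!length(idx)) next
    p <- plan[[chrom]]
    use_h2 <- (p$start + findInterval(sites$pos[idx], p$xpos)) %% 2L == 1L
    out[idx] <- ifelse(use_h2, h2[idx], h1[idx])
  }
  out
}

swap_plan_chrom <- function(plan, chrom) {
  plan[[chrom]]$start <- 1L - plan[[chrom]]$start
  plan
}

## Drop founder haplotypes through stored meioses; sites and founder_haps may
## differ from the ones used when the meioses were created (same recombination
## realisations reused for any site set -- this is what ties markers to the
## causal site).
propagate_haplotypes <- function(ped, sites, founder_haps, meioses) {
  n_site <- nrow(sites)
  H1 <- matrix(0L, n_site, nrow(ped), dimnames = list(sites$id, ped$id))
  H2 <- H1
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (is_founder(ped)[i]) {
      fh <- founder_haps[[id]]
      if (is.null(fh)) stop("missing founder haplotype for ", id)
      H1[, i] <- fh$h1; H2[, i] <- fh$h2
    } else {
      m <- meioses[[id]]
      si <- match(ped$sire[i], ped$id); di <- match(ped$dam[i], ped$id)
      H1[, i] <- apply_gamete_plan(H1[, si], H2[, si], m$sire, sites)
      H2[, i] <- apply_gamete_plan(H1[, di], H2[, di], m$dam, sites)
    }
  }
  list(H1 = H1, H2 = H2)
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Every transmitted gamete is a recombinant of the parent's two haplotypes
#' under the Haldane model (Poisson crossover count at the uniform cM/Mb rate
#' of `spec`, uniform crossover placement, no interference). Individuals
#' flagged `carrier` in the design are conditioned to receive the causal
#' allele from their heterozygous parent by swapping the gamete's haplotype
#' labels on the causal chromosome - an exact conditional sampler that leaves
#' the crossover process untouched (this emulates the progeny testing used to
#' pick carriers in a breeding program).
#'
#' @param ped a [pedigree()] (design order: parents before offspring)
#' @param spec a [genome_spec()]
#' @param founder_haps named list: founder id -> list(h1, h2) integer vectors
#'   of alternate-allele indicators over `sites`
#' @param sites site table (id, chrom, pos, ...)
#' @param seed integer seed
#' @param causal_id site id to condition carriers on (NULL disables forcing)
#' @return a `truth_set`: list with pedigree, spec, sites, haplotype matrices
#'   `H1`/`H2` (sites x individuals), and per-meiosis crossover plans
#' @export
breed_pedigree <- function(ped, spec, founder_haps, sites, seed,
                           causal_id = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(spec, "genome_spec"))
  set.seed(seed)
  founder_ids <- ped$id[is_founder(ped)]
  missing <- setdiff(founder_ids, names(founder_haps))
  if (length(missing)) stop("missing founder haplotype for ", missing[1L])
  ci <- if (is.null(causal_id)) NA_integer_ else match(causal_id, sites$id)
  if (!is.null(causal_id) && is.na(ci)) stop("causal_id not in sites")

  n_site <- nrow(sites)
  H1 <- matrix(0L, n_site, nrow(ped), dimnames = list(sites$id, ped$id))
  H2 <- H1
  meioses <- vector("list", nrow(ped)); names(meioses) <- ped$id
  causal_chrom <- if (is.na(ci)) NA_character_ else sites$chrom[ci]

  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (is_founder(ped)[i]) {
      fh <- founder_haps[[id]]
      H1[, i] <- fh$h1; H2[, i] <- fh$h2
      next
    }
    si <- match(ped$sire[i], ped$id); di <- match(ped$dam[i], ped$id)
    plan_s <- make_gamete_plan(spec)
    plan_d <- make_gamete_plan(spec)
    if (isTRUE(ped$carrier[i]) && !is.na(ci)) {
      ## condition on inheriting the causal allele from a heterozygous parent
      for (side in c("s", "d")) {
        pi <- if (side == "s") si else di
        het <- H1[ci, pi] + H2[ci, pi] == 1L
        if (!het) next
        plan <- if (side == "s") plan_s else plan_d
        gam <- apply_gamete_plan(H1[, pi], H2[, pi], plan, sites)
        if (gam[ci] == 0L) plan <- swap_plan_chrom(plan, causal_chrom)
        if (side == "s") plan_s <- plan else plan_d <- plan
        break
      }
    }
    meioses[[id]] <- list(sire = plan_s, dam = plan_d)
    H1[, i] <- apply_gamete_plan(H1[, si], H2[, si], plan_s, sites)
    H2[, i] <- apply_gamete_plan(H1[, di], H2[, di], plan_d, sites)
  }
  structure(list(pedigree = ped, spec = spec, sites = sites,
                 H1 = H1, H2 = H2, meioses = meioses,
                 founder_haps = founder_haps, causal_id = causal_id),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d sites x %d individuals (causal: %s)\n",
              nrow(x$sites), ncol(x$H1), x$causal_id %||% "none"))
  invisible(x)
}

#' Genotypes (alternate-allele counts) from a truth set
#'
#' @param truth a `truth_set`
#' @param ids individual ids (default all)
#' @param site_ids site ids (default all)
#' @return integer matrix sites x individuals with values 0/1/2
#' @export
truth_genotypes <- function(truth, ids = NULL, site_ids = NULL) {
  ids <- ids %||% colnames(truth$H1)
  site_ids <- site_ids %||% rownames(truth$H1)
  truth$H1[site_ids, ids, drop = FALSE] + truth$H2[site_ids, ids, drop = FALSE]
}

#' Assign phenotypes from the causal genotype
#'
#' Under the recessive model an animal is affected iff it is homozygous for
#' the alternate allele, with probability `plant$penetrance`; all other
#' animals are unaffected. With `null_model = TRUE` phenotypes are instead
#' drawn independently of genotype (25% affected among the final generation),
#' which is the null world used for type-I-error checks.
#'
#' @param truth a `truth_set`
#' @param plant a [causal_plant()]
#' @param seed integer seed
#' @param null_model logical
#' @return the truth set with `pedigree$phenotype` filled in
#' @export
assign_phenotypes <- function(truth, plant, seed, null_model = FALSE) {
  set.seed(seed)
  ped <- truth$pedigree
  if (null_model) {
    ped$phenotype <- "unaffected"
    g3 <- ped$generation == "G3"
    ped$phenotype[g3][runif(sum(g3)) < 0.25] <- "affected"
  } else {
    ci <- match(site_id(plant$chromosome, plant$position, plant$ref, plant$alt),
                rownames(truth$H1))
    if (is.na(ci)) stop("causal site absent from truth set")
    g <- truth$H1[ci, ] + truth$H2[ci, ]
    aff <- g == 2L & runif(length(g)) < plant$penetrance
    ped$phenotype <- ifelse(aff, "affected", "unaffected")
  }
  truth$pedigree <- ped
  truth
}

## -- SNP-array simulation ---------------------------------------------------

#' Simulate a SNP-array genotyping run over the pedigree
#'
#' Markers are placed uniformly along the genome; founder haplotype alleles
#' are Bernoulli draws from a per-marker minor allele frequency taken from
#' `maf_distribution`. Marker alleles are dropped through the *same* stored
#' meioses as the truth set, so linkage between markers and the causal site
#' is real. Calls are then set missing at `missing_rate` and replaced by one
#' of the two other genotypes at `error_rate`.
#'
#' @param truth a `truth_set` from [breed_pedigree()]
#' @param n_markers number of array markers (> 0)
#' @param maf_distribution function(k) returning k allele frequencies
#' @param missing_rate,error_rate per-call rates in \[0,1\]
#' @param seed integer seed
#' @param individuals ids to genotype (default: the `genotyped` cohort, or
#'   everyone if no cohort was selected)
#' @return a `genotype_matrix`: list(geno = markers x individuals integer
#'   matrix of allele-2 counts with NA for no-calls, map = marker table)
#' @export
genotype_markers <- function(truth, n_markers,
                             maf_distribution = function(k) runif(k, 0.05, 0.5),
                             missing_rate = 0.02, error_rate = 0.005,
                             seed = 1, individuals = NULL) {
  if (n_markers <= 0) stop("n_markers must be > 0")
  if (missing_rate < 0 || missing_rate > 1 || error_rate < 0 || error_rate > 1)
    stop("rates must be in [0,1]")
  set.seed(seed)
  ped <- truth$pedigree
  spec <- truth$spec
  individuals <- individuals %||%
    (if (any(ped$genotyped)) ped$id[ped$genotyped] else ped$id)
  if (!all(individuals %in% ped$id)) stop("unknown individual id")

  chr <- sample(spec$chromosomes$name, n_markers, replace = TRUE,
                prob = spec$chromosomes$length)
  pos <- floor(runif(n_markers, 1, spec$chromosomes$length[
    match(chr, spec$chromosomes$name)] + 1))
  map <- data.table::data.table(chrom = chr, pos = pos)
  map <- unique(map, by = c("chrom", "pos"))
  data.table::setorder(map, chrom, pos)
  alle <- t(vapply(seq_len(nrow(map)),
                   function(i) sample(DNA_BASES, 2L), character(2L)))
  map[, `:=`(marker = sprintf("snp_%s_%d", chrom, pos),
             a1 = alle[, 1L], a2 = alle[, 2L],
             maf = maf_distribution(nrow(map)))]
  data.table::setcolorder(map, c("marker", "chrom", "pos", "a1", "a2", "maf"))

  msites <- data.table::data.table(id = map$marker, chrom = map$chrom,
                                   pos = map$pos)
  founder_ids <- ped$id[is_founder(ped)]
  fh <- lapply(founder_ids, function(id)
    list(h1 = as.integer(runif(nrow(map)) < map$maf),
         h2 = as.integer(runif(nrow(map)) < map$maf)))
  names(fh) <- founder_ids
  H <- propagate_haplotypes(ped, msites, fh, truth$meioses)
  geno <- H$H1[, individuals, drop = FALSE] + H$H2[, individuals, drop = FALSE]

  if (error_rate > 0) {
    err <- which(matrix(runif(length(geno)) < error_rate, nrow(geno)))
    if (length(err)) {
      shift <- sample(1:2, length(err), replace = TRUE)
      geno[err] <- (geno[err] + shift) %% 3L
    }
  }
  if (missing_rate > 0) geno[runif(length(geno)) < missing_rate] <- NA_integer_
  structure(list(geno = geno, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d individuals (call rate %.3f)\n",
              nrow(x$geno), ncol(x$geno), mean(!is.na(x$geno))))
  invisible(x)
}

## -- PLINK text emission ----------------------------------------------------

#' Write PED/MAP files (PLINK text dialect)
#'
#' One PED row per pedigree member (ungenotyped members get missing calls),
#' columns family, individual, sire, dam, sex (1/2), phenotype (2 affected,
#' 1 unaffected, 0 unknown), then two allele columns per marker; missing
#' allele = 0. MAP columns: chromosome, marker id, genetic position (cM,
#' uniform rate), bp position.
#'
#' @param gm a `genotype_matrix`
#' @param ped a [pedigree()]
#' @param prefix output path prefix (writes `prefix.ped`, `prefix.map`)
#' @param spec optional [genome_spec()] for the cM column (default 1 cM/Mb)
#' @return invisibly, the two file paths
#' @export
write_plink <- function(gm, ped, prefix, spec = NULL) {
  rate <- if (is.null(spec)) 1 else spec$recombination_rate
  map <- gm$map
  map_lines <- sprintf("%s\t%s\t%.6g\t%d", sub("^chr", "", map$chrom),
                       map$marker, map$pos / 1e6 * rate, as.integer(map$pos))
  writeLines(map_lines, paste0(prefix, ".map"))

  pheno_code <- c(affected = "2", unaffected = "1", unknown = "0")
  a1 <- map$a1; a2 <- map$a2
  lines <- vapply(seq_len(nrow(ped)), function(i) {
    id <- ped$id[i]
    lead <- paste(ped$family[i], id,
                  ifelse(is.na(ped$sire[i]), "0", ped$sire[i]),
                  ifelse(is.na(ped$dam[i]), "0", ped$dam[i]),
                  ifelse(ped$sex[i] == "male", "1", "2"),
                  pheno_code[[ped$phenotype[i]]])
    if (id %in% colnames(gm$geno)) {
      g <- gm$geno[, id]
      al1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, a2, a1))
      al2 <- ifelse(is.na(g), "0", ifelse(g == 2L, a2, a1))
      paste(lead, paste(al1, al2, collapse = " "))
    } else {
      paste(lead, paste(rep("0 0", nrow(map)), collapse = " "))
    }
  }, "")
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Read PED/MAP files written in the same dialect
#'
#' Allele 2 (the counted allele) is taken as the lexicographically larger of
#' the alleles observed at each marker; the TDT statistic is invariant under
#' this labelling.
#'
#' @param ped_path,map_path file paths
#' @return list with a `genotype_matrix` (`gm`) and the pedigree table
#'   (`ped`) recovered from the leading PED columns
#' @export
read_plink <- function(ped_path, map_path) {
  map <- data.table::fread(map_path, header = FALSE,
                           col.names = c("chrom", "marker", "cm", "pos"))
  map[, chrom := ifelse(grepl("^chr", chrom), as.character(chrom),
                        paste0("chr", chrom))]
  toks <- strsplit(readLines(ped_path), " +")
  n_mark <- nrow(map)
  lead <- t(vapply(toks, function(x) x[1:6], character(6L)))
  ids <- lead[, 2L]
  A1 <- vapply(toks, function(x) x[6L + 2L * seq_len(n_mark) - 1L],
               character(n_mark))
  A2 <- vapply(toks, function(x) x[6L + 2L * seq_len(n_mark)],
               character(n_mark))
  if (n_mark == 1L) { A1 <- matrix(A1, 1L); A2 <- matrix(A2, 1L) }
  colnames(A1) <- colnames(A2) <- ids
  alleles <- lapply(seq_len(n_mark), function(m) {
    obs <- setdiff(unique(c(A1[m, ], A2[m, ])), "0")
    sort(obs)
  })
  a1 <- vapply(alleles, function(a) if (length(a)) a[1L] else "A", "")
  a2 <- vapply(alleles, function(a) if (length(a) > 1L) a[2L]
               else if (length(a)) a[1L] else "B", "")
  geno <- (A1 == a2) + (A2 == a2)
  geno[A1 == "0" | A2 == "0"] <- NA_integer_
  typed <- colSums(!is.na(geno)) > 0L
  gm <- structure(list(
    geno = matrix(as.integer(geno[, typed, drop = FALSE]), nrow = n_mark,
                  dimnames = list(map$marker, ids[typed])),
    map = data.table::data.table(marker = map$marker, chrom = map$chrom,
                                 pos = as.numeric(map$pos), a1 = a1, a2 = a2,
                                 maf = NA_real_)),
    class = "genotype_matrix")
  ped_df <- data.frame(
    family = lead[, 1L], id = ids,
    sire = ifelse(lead[, 3L] == "0", NA, lead[, 3L]),
    dam = ifelse(lead[, 4L] == "0", NA, lead[, 4L]),
    sex = ifelse(lead[, 5L] == "1", "male", "female"),
    generation = NA_character_,
    phenotype = c("0" = "unknown", "1" = "unaffected",
                  "2" = "affected")[lead[, 6L]],
    genotyped = typed, carrier = FALSE, stringsAsFactors = FALSE)
  list(gm = gm, ped = pedigree(ped_df))
}

## -- exome VCF emission -----------------------------------------------------

#' Emit an exome-style VCF for sequenced individuals
#'
#' Writes one VCF v4.2 record (GT:DP FORMAT) per truth-set variant carried by
#' at least one sequenced individual. Per-sample depths are Poisson draws
#' around `mean_depth`; QUAL is a rounded Gaussian around 60.
#'
#' @param truth a `truth_set`
#' @param sequenced ids of the sequenced individuals
#' @param path output path, or NULL for no file
#' @param seed integer seed (depth/qual noise)
#' @param mean_depth mean sequencing depth
#' @return invisibly, a `variant_set` (see [read_vcf_gt()]) with the emitted
#'   records
#' @export
emit_exome_vcf <- function(truth, sequenced, path = NULL, seed = 1,
                           mean_depth = 35) {
  ped <- truth$pedigree
  if (!all(sequenced %in% ped$id)) stop("unknown individual id in sequenced")
  set.seed(seed)
  keep <- if (length(sequenced)) {
    g <- truth_genotypes(truth, ids = sequenced)
    which(rowSums(g) > 0L)
  } else integer()
  sites <- truth$sites[keep, ]
  n <- nrow(sites)
  gt <- truth_genotypes(truth, ids = sequenced)[keep, , drop = FALSE]
  dp <- matrix(rpois(n * length(sequenced), mean_depth), nrow = n,
               dimnames = dimnames(gt))
  qual <- round(pmax(1, rnorm(n, 60, 10)), 1)
  vs <- structure(list(
    variants = data.table::data.table(id = sites$id, chrom = sites$chrom,
                                      pos = sites$pos, ref = sites$ref,
                                      alt = sites$alt, qual = qual,
                                      type = sites$type),
    gt = gt, dp = dp, samples = sequenced), class = "variant_set")
  if (!is.null(path)) write_vcf_gt(vs, path, spec = truth$spec)
  invisible(vs)
}

#' Write a `variant_set` as VCF v4.2 (GT:DP only)
#' @param vs a `variant_set`
#' @param path output file
#' @param spec optional [genome_spec()] for contig header lines
#' @return invisibly `path`
#' @export
write_vcf_gt <- function(vs, path, spec = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=enumap",
           if (!is.null(spec))
             sprintf("##contig=<ID=%s,length=%d>", spec$chromosomes$name,
                     as.integer(spec$chromosomes$length)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vs$samples), collapse = "\t"))
  v <- vs$variants
  if (nrow(v)) {
    gt_str <- c("0/0", "0/1", "1/1")[vs$gt + 1L]
    dim(gt_str) <- dim(vs$gt)
    cells <- matrix(paste0(gt_str, ":", vs$dp), nrow = nrow(v))
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\t.\t.\tGT:DP\t%s",
                    v$chrom, as.integer(v$pos), v$id, v$ref, v$alt,
                    format(v$qual, trim = TRUE),
                    apply(cells, 1L, paste, collapse = "\t"))
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a GT(/DP) VCF into a `variant_set`
#'
#' Minimal reader for the dialect this package writes (single-sample-field
#' GT-first FORMAT, biallelic records; multi-allelic ALT fields are split
#' into one biallelic variant per alternate allele on ingest).
#'
#' @param path VCF file path
#' @return a `variant_set`: list(variants, gt, dp, samples)
#' @export
read_vcf_gt <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1L], "\t")[[1L]]
  if (hdr[1L] != "#CHROM") stop("malformed VCF header")
  samples <- if (length(hdr) > 9L) hdr[-(1:9)] else character()
  body <- body[-1L]
  rows <- list(); gts <- list(); dps <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1L]]
    alts <- strsplit(f[5L], ",")[[1L]]
    fmt <- strsplit(f[9L], ":")[[1L]]
    gt_i <- match("GT", fmt); dp_i <- match("DP", fmt)
    cells <- if (length(samples)) strsplit(f[-(1:9)], ":") else list()
    for (ai in seq_along(alts)) {
      gt <- vapply(cells, function(cc) {
        al <- strsplit(gsub("\\|", "/", cc[gt_i]), "/")[[1L]]
        if (any(al == ".")) return(NA_integer_)
        sum(al == as.character(ai))
      }, integer(1L))
      dp <- vapply(cells, function(cc)
        if (is.na(dp_i)) NA_integer_ else as.integer(cc[dp_i]), integer(1L))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = f[1L], pos = as.numeric(f[2L]), ref = f[4L], alt = alts[ai],
        qual = suppressWarnings(as.numeric(f[6L])))
      gts[[length(gts) + 1L]] <- gt
      dps[[length(dps) + 1L]] <- dp
    }
  }
  v <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(chrom = character(), pos = numeric(),
                           ref = character(), alt = character(),
                           qual = numeric())
  v[, id := if (.N) site_id(chrom, pos, ref, alt) else character()]
  data.table::setcolorder(v, c("id", "chrom", "pos", "ref", "alt", "qual"))
  gt <- matrix(unlist(gts), ncol = length(samples), byrow = TRUE,
               dimnames = list(v$id, samples))
  dp <- matrix(unlist(dps), ncol = length(samples), byrow = TRUE,
               dimnames = list(v$id, samples))
  if (!nrow(v)) {
    gt <- matrix(integer(), 0L, length(samples), dimnames = list(NULL, samples))
    dp <- gt
  }
  structure(list(variants = v, gt = gt, dp = dp, samples = samples),
            class = "variant_set")
}

## -- Mendelian consistency --------------------------------------------------

#' Count Mendelian inconsistencies in a genotype matrix
#'
#' For every marker and every individual whose two parents are also in the
#' matrix, checks that the allele-count genotype is attainable from the
#' parental genotypes. Missing calls are skipped.
#'
#' @param gm a `genotype_matrix`
#' @param ped a [pedigree()]
#' @return number of (marker, trio) violations
#' @export
mendelian_errors <- function(gm, ped) {
  ids <- colnames(gm$geno)
  kids <- which(ped$id %in% ids & !is.na(ped$sire) &
                  ped$sire %in% ids & ped$dam %in% ids)
  bad <- 0L
  for (i in kids) {
    c_ <- gm$geno[, ped$id[i]]
    f <- gm$geno[, ped$sire[i]]
    m <- gm$geno[, ped$dam[i]]
    ok <- is.na(c_) | is.na(f) | is.na(m) |
      (c_ >= (f == 2L) + (m == 2L) & c_ <= 2L - ((f == 0L) + (m == 0L)))
    bad <- bad + sum(!ok)
  }
  bad
}
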