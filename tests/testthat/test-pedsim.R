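test_that("founder mutation simulation honours rate, spectrum and seed", {
  spec <- tiny_spec()
  expect_equal(nrow(simulate_founder_mutations(spec, enu_model(0), 1)), 0L)

  a <- simulate_founder_mutations(spec, enu_model(200), 42)
  b <- simulate_founder_mutations(spec, enu_model(200), 42)
  expect_identical(a, b)
  expect_true(all(a$ref != a$alt))
  expect_true(all(a$pos >= 1 & a$pos <= 100e6))

  # Monte-Carlo moment check against the Poisson model
  counts <- vapply(1:1000, function(s)
    nrow(simulate_founder_mutations(spec, enu_model(100), s)), numeric(1))
  se <- sqrt(100 / 1000)
  expect_lt(abs(mean(counts) - 100), 3 * se)
})

test_that("breeding respects the no-crossover limit and missing founders error", {
  spec0 <- tiny_spec(rate = 0)
  sites <- data.table::data.table(
    id = sprintf("s%d", 1:50), chrom = "chr1",
    pos = sort(sample.int(100e6, 50)), ref = "A", alt = "G",
    type = "marker", maf = 0.5)
  ped <- trio_pedigree(5)
  fh <- list(F = list(h1 = rep(1L, 50), h2 = rep(0L, 50)),
             M = list(h1 = rep(1L, 50), h2 = rep(0L, 50)))
  tr <- breed_pedigree(ped, spec0, fh, sites, seed = 7)
  for (k in sprintf("K%02d", 1:5)) {
    expect_true(all(tr$H1[, k] == 1L) || all(tr$H1[, k] == 0L))
    expect_true(all(tr$H2[, k] == 1L) || all(tr$H2[, k] == 0L))
  }
  expect_error(breed_pedigree(ped, spec0, fh["F"], sites, seed = 1),
               "missing founder haplotype")
})

test_that("crossover count follows the Haldane/Poisson model on a 100 cM chromosome", {
  spec <- tiny_spec(len = 100e6, rate = 1)  # 1 Morgan
  set.seed(11)
  n <- 10000
  k <- vapply(seq_len(n), function(i)
    length(enumap:::make_gamete_plan(spec)$chr1$xpos), numeric(1))
  expect_lt(abs(mean(k) - 1.0), 3 * sqrt(1 / n))
})

test_that("a carrier x carrier cross segregates 25% affected at full penetrance", {
  spec <- tiny_spec()
  ped <- trio_pedigree(400)
  causal <- data.table::data.table(id = "chr1:5e+07:A:G", chrom = "chr1",
                                   pos = 5e7, ref = "A", alt = "G",
                                   type = "causal", maf = 0)
  fh <- list(F = list(h1 = 1L, h2 = 0L), M = list(h1 = 1L, h2 = 0L))
  tr <- breed_pedigree(ped, spec, fh, causal, seed = 3,
                       causal_id = causal$id)
  plant <- causal_plant("chr1", 5e7, "A", "G", "g", 1)
  tr <- assign_phenotypes(tr, plant, seed = 4)
  frac <- mean(tr$pedigree$phenotype[-(1:2)] == "affected")
  ci_half <- 2.576 * sqrt(0.25 * 0.75 / 400)
  expect_lt(abs(frac - 0.25), ci_half)

  # segregation by construction: affected <=> homozygous alt
  g <- truth_genotypes(tr)[1, ]
  expect_identical(tr$pedigree$phenotype == "affected", unname(g == 2L))
})

test_that("phenotype assignment follows the recessive model", {
  spec <- tiny_spec()
  ped <- trio_pedigree(6)
  causal <- data.table::data.table(id = "chr1:5e+07:A:G", chrom = "chr1",
                                   pos = 5e7, ref = "A", alt = "G",
                                   type = "causal", maf = 0)
  fh <- list(F = list(h1 = 1L, h2 = 1L), M = list(h1 = 0L, h2 = 0L))
  tr <- breed_pedigree(ped, spec, fh, causal, seed = 5)
  plant <- causal_plant("chr1", 5e7, "A", "G", "g", 1)
  tr1 <- assign_phenotypes(tr, plant, seed = 6)
  ## every offspring is A/G heterozygous: unaffected; founder F is G/G: affected
  expect_identical(tr1$pedigree$phenotype[1], "affected")
  expect_true(all(tr1$pedigree$phenotype[-1] == "unaffected"))
  plant0 <- causal_plant("chr1", 5e7, "A", "G", "g", 1, penetrance = 0)
  tr0 <- assign_phenotypes(tr, plant0, seed = 6)
  expect_true(all(tr0$pedigree$phenotype == "unaffected"))
})

test_that("marker genotyping: call rate, Mendelian consistency, binomial missingness", {
  cfg <- lean_cfg()
  sim <- simulate_cohort(cfg, seed = 21)
  truth <- sim$truth

  gm0 <- genotype_markers(truth, 400, missing_rate = 0, error_rate = 0,
                          seed = 1, individuals = truth$pedigree$id)
  expect_true(all(!is.na(gm0$geno)))
  expect_identical(mendelian_errors(gm0, truth$pedigree), 0L)

  gm2 <- genotype_markers(truth, 5000, missing_rate = 0.2, error_rate = 0,
                          seed = 2)
  n_calls <- length(gm2$geno)
  se <- sqrt(0.8 * 0.2 / n_calls)
  expect_lt(abs(mean(!is.na(gm2$geno)) - 0.8), 3 * se)
  expect_error(genotype_markers(truth, 0), "n_markers")
})

test_that("PED/MAP emission is deterministic and round-trips", {
  cfg <- lean_cfg(sim = list(n_markers = 120L))
  sim <- simulate_cohort(cfg, seed = 8)
  p1 <- file.path(tempdir(), "rt1"); p2 <- file.path(tempdir(), "rt2")
  write_plink(sim$gm, sim$truth$pedigree, p1, sim$truth$spec)
  write_plink(sim$gm, sim$truth$pedigree, p2, sim$truth$spec)
  expect_identical(readLines(paste0(p1, ".ped")), readLines(paste0(p2, ".ped")))
  expect_identical(readLines(paste0(p1, ".map")), readLines(paste0(p2, ".map")))

  back <- read_plink(paste0(p1, ".ped"), paste0(p1, ".map"))
  expect_identical(dim(back$gm$geno), dim(sim$gm$geno))
  ## genotype counts agree up to allele relabelling: compare heterozygosity
  ## and missingness patterns, and counts after harmonising the labels
  expect_identical(is.na(back$gm$geno), is.na(sim$gm$geno))
  expect_identical(back$gm$geno == 1L, sim$gm$geno == 1L)
  flip <- back$gm$map$a2 != sim$gm$map$a2
  harmon <- back$gm$geno
  harmon[flip, ] <- 2L - harmon[flip, , drop = FALSE]
  expect_identical(unname(harmon), unname(sim$gm$geno))
})

test_that("exome VCF carries homozygous causal genotypes and round-trips", {
  cfg <- lean_cfg(sim = list(n_markers = 120L))
  sim <- simulate_cohort(cfg, seed = 9)
  causal_id <- sim$vs$variants$id[sim$vs$variants$type == "causal"]
  expect_length(causal_id, 1L)
  expect_true(all(sim$vs$gt[causal_id, ] == 2L))

  path <- file.path(tempdir(), "exome_rt.vcf")
  write_vcf_gt(sim$vs, path, sim$truth$spec)
  back <- read_vcf_gt(path)
  expect_identical(back$samples, sim$vs$samples)
  expect_identical(unname(back$gt), unname(sim$vs$gt))
  expect_identical(back$variants$pos, sim$vs$variants$pos)

  ## determinism: re-emitting with the same seed is byte-identical
  path2 <- file.path(tempdir(), "exome_rt2.vcf")
  vs2 <- emit_exome_vcf(sim$truth, sim$sequenced, path2,
                        seed = derive_seed(9, "vcf"))
  write_vcf_gt(sim$vs, path, sim$truth$spec)
  expect_identical(readLines(path), readLines(path2))

  ## header-only VCF for zero sequenced individuals
  p0 <- file.path(tempdir(), "empty.vcf")
  emit_exome_vcf(sim$truth, character(), p0, seed = 1)
  lines <- readLines(p0)
  expect_true(all(startsWith(lines, "#")))
  expect_error(emit_exome_vcf(sim$truth, "nobody", seed = 1),
               "unknown individual")
})

test_that("markers linked to the causal site show larger TDT statistics", {
  ## stochastic-dominance check: over replicates, the best chi2 within 10 cM
  ## of the causal site exceeds the median unlinked chi2
  reps <- 25
  wins <- 0L
  for (s in seq_len(reps)) {
    cfg <- lean_cfg(sim = list(n_markers = 400L, missing_rate = 0,
                               error_rate = 0))
    sim <- simulate_cohort(cfg, seed = 3000 + s)
    res <- tdt_scan(sim$gm, sim$truth$pedigree)
    near <- res$chrom == sim$plant$chromosome &
      abs(res$pos - sim$plant$position) <= 10e6
    if (!any(near) || !any(!near)) next
    if (max(res$chi2[near], na.rm = TRUE) >
        stats::median(res$chi2[!near], na.rm = TRUE)) wins <- wins + 1L
  }
  expect_gt(wins / reps, 0.9)
})

test_that("fixture reproduces the planted-gene arithmetic", {
  cds <- fx$transcript$seq
  expect_identical(substr(cds, 1226, 1226), "A")
  expect_equal(fx$transcript$exons$length[10], 103)
  tr409 <- translate_cds(substr(cds, 3 * 409 - 2, 3 * 409 + 3))
  expect_identical(substr(tr409$protein, 1, 1), "D")
  expect_identical(substr(cds, 1225, 1233), "GATCTGAGG")
  ## the motif context G[A/G]TCTGAGG sits at the causal position
  expect_identical(substr(fx$causal_context, fx$causal_context_offset - 1,
                          fx$causal_context_offset + 7), "GATCTGAGG")
  ## fixture is byte-stable and does not disturb the caller's RNG
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(make_duox2_like_fixture()); after <- runif(1)
  expect_identical(before, after)
  expect_identical(make_duox2_like_fixture()$transcript$seq, cds)
})
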