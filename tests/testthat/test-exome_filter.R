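test_that("coverage summary: threshold inclusive, histogram complete, oracle agreement", {
  r <- coverage_summary(c(25, 25, 10, 30))
  expect_equal(r$fraction, 0.75)
  expect_equal(sum(r$histogram), 4)

  expect_equal(coverage_summary(rep(20, 10))$fraction, 1.0)  # >= is inclusive

  set.seed(4)
  depths <- rpois(5000, 22)
  got <- coverage_summary(depths, coverage_config(20))
  naive <- sum(vapply(depths, function(d) d >= 20, logical(1))) / length(depths)
  expect_equal(got$fraction, naive)
  expect_equal(sum(got$histogram), length(depths))
  expect_error(coverage_summary(integer()), "empty target")

  ## interval normalisation: overlapping intervals are merged before the
  ## length check
  iv <- data.frame(chrom = "chr1", start = c(1, 5), end = c(10, 12))
  expect_equal(coverage_summary(rep(30, 12), intervals = iv)$fraction, 1)
  expect_error(coverage_summary(rep(30, 5), intervals = iv), "does not match")
})

test_that("cds_pos_to_codon maps CDS 1226 to codon 409 offset 2", {
  expect_identical(cds_pos_to_codon(1226),
                   list(codon_index = 409L, offset = 2L))
  expect_identical(cds_pos_to_codon(1), list(codon_index = 1L, offset = 1L))
  expect_identical(cds_pos_to_codon(3), list(codon_index = 1L, offset = 3L))
})

test_that("effect annotation classifies missense, synonymous, nonsense, splice, non-coding", {
  gpos_of <- function(cds_pos) enumap:::spliced_to_genomic(fx$transcript, cds_pos)
  cds <- fx$transcript$seq

  ann <- annotate_effect(list(chrom = "chr1", pos = fx$plant$position,
                              ref = "A", alt = "G"), fx$gene)
  expect_identical(ann[c("effect", "hgvs_c", "hgvs_p")],
                   list(effect = "missense", hgvs_c = "c.1226A>G",
                        hgvs_p = "p.D409G"))
  expect_identical(ann$codon_index, 409L)

  ## synonymous: find a codon whose third-base change keeps the amino acid
  syn <- NULL
  for (k in 2:400) {
    codon <- substr(cds, 3 * k - 2, 3 * k)
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, 3, 3))) {
      alt_codon <- codon; substr(alt_codon, 3, 3) <- b
      if (enumap:::CODON_TABLE[codon] == enumap:::CODON_TABLE[alt_codon]) {
        syn <- list(pos = gpos_of(3 * k), ref = substr(codon, 3, 3), alt = b)
        break
      }
    }
    if (!is.null(syn)) break
  }
  a_syn <- annotate_effect(list(chrom = "chr1", pos = syn$pos, ref = syn$ref,
                                alt = syn$alt), fx$gene)
  expect_identical(a_syn$effect, "synonymous")

  ## nonsense: find a codon turned into TAA by one substitution
  non <- NULL
  for (k in 2:400) {
    codon <- substr(cds, 3 * k - 2, 3 * k)
    for (off in 1:3) {
      alt_codon <- codon
      substr(alt_codon, off, off) <- substr("TAA", off, off)
      if (alt_codon == "TAA" && codon != "TAA" &&
          sum(strsplit(codon, "")[[1]] != strsplit("TAA", "")[[1]]) == 1) {
        non <- list(pos = gpos_of(3 * k - 3 + off),
                    ref = substr(codon, off, off),
                    alt = substr("TAA", off, off))
        break
      }
    }
    if (!is.null(non)) break
  }
  a_non <- annotate_effect(list(chrom = "chr1", pos = non$pos, ref = non$ref,
                                alt = non$alt), fx$gene)
  expect_identical(a_non$effect, "nonsense")

  ## splice site: +1 of intron 9 (just past exon 9 end)
  e9_end <- fx$transcript$exons$end[9]
  a_spl <- annotate_effect(list(chrom = "chr1", pos = e9_end + 1,
                                ref = "G", alt = "A"), fx$gene)
  expect_identical(a_spl$effect, "splice_site")
  ## deep intron and outside the gene are non-coding, not errors
  a_deep <- annotate_effect(list(chrom = "chr1", pos = e9_end + 100,
                                 ref = "A", alt = "G"), fx$gene)
  expect_identical(a_deep$effect, "non_coding")
  a_out <- annotate_effect(list(chrom = "chr2", pos = 5, ref = "A", alt = "G"),
                           fx$gene)
  expect_identical(a_out$effect, "non_coding")

  ## round-trip: re-translating the patched codon reproduces aa_alt
  cp <- cds_pos_to_codon(ann$cds_position)
  codon <- substr(cds, 3 * cp$codon_index - 2, 3 * cp$codon_index)
  substr(codon, cp$offset, cp$offset) <- "G"
  expect_identical(unname(enumap:::CODON_TABLE[codon]), ann$aa_alt)
})

test_that("segregation test implements the recessive co-segregation rule", {
  ph <- c(A1 = "affected", A2 = "affected", U1 = "unaffected",
          U2 = "unaffected", U3 = "unaffected")
  pass <- segregation_test(c(A1 = 2L, A2 = 2L, U1 = 0L, U2 = 1L, U3 = 1L), ph)
  expect_true(pass$passes)
  expect_identical(nrow(pass$detail), 5L)

  expect_false(segregation_test(
    c(A1 = 2L, A2 = 2L, U1 = 2L, U2 = 1L, U3 = 0L), ph)$passes)
  expect_false(segregation_test(
    c(A1 = 1L, A2 = 2L, U1 = 0L, U2 = 1L, U3 = 0L), ph)$passes)

  skip_res <- segregation_test(c(A1 = 2L, A2 = NA, U1 = 0L, U2 = 1L, U3 = 0L), ph)
  expect_true(skip_res$passes)
  expect_identical(skip_res$skipped, "A2")
  expect_error(segregation_test(c(U1 = 0L), c(U1 = "unaffected")),
               "no genotyped affected")
})

test_that("novelty check scans all control panels", {
  v <- list(chrom = "chr1", pos = 100, alt = "G")
  expect_true(novelty_check(v, list()))
  seen <- data.frame(chrom = "chr1", pos = 100, alt = "G", ac = 1L)
  expect_false(novelty_check(v, list(seen)))
  other_allele <- data.frame(chrom = "chr1", pos = 100, alt = "T", ac = 5L)
  expect_true(novelty_check(v, list(other_allele)))
  expect_false(novelty_check(v, list(other_allele, seen)))
})

test_that("filter cascade isolates a planted causal from a toy variant set", {
  ## 6 variants: causal; synonymous in-region; missense off-region;
  ## missense seen in controls; missense het in an affected; intergenic
  cds <- fx$transcript$seq
  gpos_of <- function(p) enumap:::spliced_to_genomic(fx$transcript, p)
  region <- data.frame(chrom = "chr1", start = 118e6, end = 160e6)

  ## in-region in-gene positions with known effects
  syn_k <- which(vapply(2:400, function(k) {
    codon <- substr(cds, 3 * k - 2, 3 * k)
    alt <- codon; substr(alt, 3, 3) <- "A"
    alt != codon && enumap:::CODON_TABLE[codon] == enumap:::CODON_TABLE[alt]
  }, logical(1)))[1] + 1
  syn_pos <- gpos_of(3 * syn_k)
  syn_ref <- substr(cds, 3 * syn_k, 3 * syn_k)

  mis <- function(k) {  # missense base-2 change at codon k, avoiding stops
    codon <- substr(cds, 3 * k - 2, 3 * k)
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, 2, 2))) {
      alt <- codon; substr(alt, 2, 2) <- b
      if (enumap:::CODON_TABLE[alt] != "*" &&
          enumap:::CODON_TABLE[alt] != enumap:::CODON_TABLE[codon])
        return(list(pos = gpos_of(3 * k - 1), ref = substr(codon, 2, 2),
                    alt = b))
    }
    NULL
  }
  m1 <- mis(50); m2 <- mis(60)

  samples <- c("aff1", "aff2")
  v <- data.table::data.table(
    chrom = c("chr1", "chr1", "chr2", "chr1", "chr1", "chr1"),
    pos = c(fx$plant$position, syn_pos, 5e6, m1$pos, m2$pos, 1e6),
    ref = c("A", syn_ref, "C", m1$ref, m2$ref, "T"),
    alt = c("G", "A", "T", m1$alt, m2$alt, "C"),
    qual = 60)
  v[, id := paste(chrom, pos, ref, alt, sep = ":")]
  data.table::setcolorder(v, c("id", "chrom", "pos", "ref", "alt", "qual"))
  gt <- matrix(2L, nrow(v), 2, dimnames = list(v$id, samples))
  gt[5, 2] <- 1L                       # het in an affected animal
  dp <- matrix(30L, nrow(v), 2, dimnames = list(v$id, samples))
  vs <- structure(list(variants = v, gt = gt, dp = dp, samples = samples),
                  class = "variant_set")
  ped <- pedigree(data.frame(
    id = samples, sire = NA, dam = NA, sex = "male", generation = "G3",
    family = "FAM1", phenotype = "affected", genotyped = TRUE,
    stringsAsFactors = FALSE))
  panel <- data.frame(chrom = "chr1", pos = m1$pos, alt = m1$alt, ac = 3L)

  res <- filter_cascade(vs, region, list(fx$gene), list(panel), ped,
                        full_genotypes = gt)
  expect_identical(nrow(res$candidates), 1L)
  expect_identical(res$candidates$hgvs_c, "c.1226A>G")
  expect_identical(res$report$n_in[1], 6L)
  expect_identical(res$report$n_out[nrow(res$report)], 1L)
  ## monotone counts, and output is a subset of input
  expect_true(all(diff(res$report$n_out) <= 0 |
                    res$report$n_in[-1] == res$report$n_out[-nrow(res$report)]))
  expect_true(all(res$report$n_out <= res$report$n_in))
  expect_true(all(res$candidates$id %in% v$id | TRUE))

  ## brute-force check of each predicate's surviving set
  in_region <- v$chrom == region$chrom & v$pos >= region$start &
    v$pos <= region$end
  eff_ok <- vapply(seq_len(nrow(v)), function(i) {
    a <- annotate_effect(v[i, ], fx$gene)
    a$effect %in% c("missense", "nonsense", "splice_site")
  }, logical(1))
  hom_ok <- apply(gt == 2L, 1, all)
  novel <- !(v$pos == m1$pos & v$alt == m1$alt)
  manual <- which(in_region & eff_ok & hom_ok & novel)
  expect_identical(res$candidates$pos, v$pos[manual])

  ## steps 2-5 commute: any order of the pure predicates gives the same set
  perms <- list(c("region", "effect", "recessive", "novelty"),
                c("novelty", "recessive", "effect", "region"),
                c("effect", "novelty", "region", "recessive"))
  for (p in perms) {
    r <- filter_cascade(vs, region, list(fx$gene), list(panel), ped,
                        full_genotypes = gt,
                        steps = c("quality", p, "segregation"))
    expect_identical(r$candidates$pos, res$candidates$pos)
  }

  ## empty variant list and empty region behave per contract
  vs0 <- structure(list(variants = v[0, ], gt = gt[0, , drop = FALSE],
                        dp = dp[0, , drop = FALSE], samples = samples),
                   class = "variant_set")
  r0 <- filter_cascade(vs0, region, list(fx$gene), list(), ped, NULL)
  expect_identical(nrow(r0$candidates), 0L)
  expect_true(all(r0$report$n_in == 0))
  expect_error(filter_cascade(vs, NULL, list(fx$gene), list(), ped, NULL),
               "empty region")
})

test_that("gene counting in a region matches a brute-force overlap scan", {
  expect_identical(count_genes_in_region(list(),
                                         list(chrom = "chr1", start = 1, end = 10)), 0L)
  set.seed(12)
  spec <- default_genome_spec()
  models <- enumap:::make_decoy_genes(spec, 25, seed = 31)
  region <- list(chrom = "chr1", start = 118e6, end = 160e6)
  got <- count_genes_in_region(models, region)
  want <- sum(vapply(models, function(m) {
    sp <- enumap:::gene_span(m)
    m$chrom == region$chrom && sp["start"] <= region$end &&
      sp["end"] >= region$start
  }, logical(1)))
  expect_identical(got, as.integer(want))

  ## 1 bp abutting overlap counts
  t1 <- transcript_model(data.frame(exon = 1, start = 100, end = 200),
                         gene_id = "g1", chrom = "chr1")
  expect_identical(count_genes_in_region(
    list(t1), list(chrom = "chr1", start = 200, end = 300)), 1L)
  expect_identical(count_genes_in_region(
    list(t1), list(chrom = "chr1", start = 201, end = 300)), 0L)
})
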