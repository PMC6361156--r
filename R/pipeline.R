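#' Default run configuration
#'
#' One nested list drives a whole simulate-map-filter-splice run. Defaults
#' encode the cohort of the reference cross (4 families, 15 affected / 25
#' unaffected genotyped), a 5,000-marker panel on the 420 Mb toy genome
#' (12 markers/Mb, a scaled stand-in for the 62k porcine chip), a founder
#' ENU burden of 300 point mutations, full penetrance, and the standard QC /
#' TDT parameters.
#'
#' @param ... named overrides, nested lists are merged field-wise
#' @return a `run_config` list
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    sim = list(
      n_families = 4L, g3_per_family = 25L,
      n_affected = 15L, n_unaffected = 25L,
      n_markers = 5000L, missing_rate = 0.02, error_rate = 0.005,
      maf_min = 0.05, maf_max = 0.5,
      enu_mean = 300, n_common = 150L,
      n_decoys = 30L, n_decoys_in_region = 6L,
      penetrance = 1, null_model = FALSE,
      n_sequenced_affected = 2L, mean_depth = 35,
      control_panel_n = 20L),
    qc = list(min_call_rate = 0.90, min_maf = 0.05, hwe_alpha = 1e-3),
    tdt = list(n_perm = 1000L, alpha = 0.05, merge_gap_bp = 10e6),
    cascade = list(min_qual = 20, min_dp = 5,
                   steps = c("quality", "region", "effect", "recessive",
                             "novelty", "segregation")),
    splice = list(matrix_path = NULL))
  overrides <- list(...)
  merge_lists <- function(base, ov) {
    for (nm in names(ov)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(ov[[nm]]))
        merge_lists(base[[nm]], ov[[nm]]) else ov[[nm]]
    }
    base
  }
  merge_lists(cfg, overrides)
}

#' Read / write a run configuration (YAML, JSON also accepted on read)
#' @param path config file
#' @return a `run_config` (defaults filled in for unset fields)
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(default_run_config, cfg)
}

#' @rdname read_run_config
#' @param cfg a config list
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

## snap reference alleles of simulated variants that fall inside a gene
## fragment to the fragment base (keeps effect annotation consistent);
## alternate alleles equal to the snapped reference are rotated away
snap_refs <- function(sites, models) {
  if (!nrow(sites)) return(sites)
  for (m in models) {
    span <- gene_span(m)
    lo <- m$fragment_start; hi <- m$fragment_start + nchar(m$fragment) - 1
    i <- which(sites$chrom == m$chrom & sites$pos >= lo & sites$pos <= hi)
    for (j in i) {
      b <- fragment_base(m, sites$pos[j])
      sites$ref[j] <- b
      if (sites$alt[j] == b)
        sites$alt[j] <- DNA_BASES[match(b, DNA_BASES) %% 4L + 1L]
    }
  }
  sites[, id := site_id(chrom, pos, ref, alt)]
  sites
}

#' Simulate one complete mapping cohort
#'
#' Generates everything a mapping run consumes: the planted DUOX2-like gene
#' fixture, decoy gene models, the ENU mutation burden and standing common
#' variants, the bred pedigree with phenotypes and cohort selection, the
#' SNP-array genotype matrix, the exome variant set of the sequenced affected
#' animals, confirmatory whole-pedigree genotypes, a control panel for the
#' novelty filter and a per-base depth track over the exome target.
#'
#' @param cfg a [default_run_config()] list
#' @param seed root seed (overrides `cfg$seed` when given)
#' @return list: truth, gm, vs, models, panel, plant, fixture,
#'   full_genotypes, depths, targets, sequenced
#' @export
simulate_cohort <- function(cfg = default_run_config(), seed = NULL) {
  seed <- seed %||% cfg$seed
  sim <- cfg$sim
  fixture <- make_duox2_like_fixture()
  plant <- fixture$plant
  plant$penetrance <- sim$penetrance
  spec <- default_genome_spec()
  enu <- enu_model(sim$enu_mean)
  region0 <- list(chrom = "chr1", start = 118e6, end = 160e6)
  decoys <- make_decoy_genes(spec, sim$n_decoys, derive_seed(seed, "decoys"),
                             region = region0,
                             n_in_region = sim$n_decoys_in_region)
  models <- c(list(fixture$gene), decoys)

  maf_dist <- function(k) runif(k, sim$maf_min, sim$maf_max)
  enu_sites <- simulate_founder_mutations(spec, enu,
                                          derive_seed(seed, "founders"))
  common <- simulate_common_variants(spec, sim$n_common,
                                     derive_seed(seed, "common"),
                                     maf_distribution = maf_dist)
  causal_row <- data.table::data.table(
    id = site_id(plant$chromosome, plant$position, plant$ref, plant$alt),
    chrom = plant$chromosome, pos = plant$position, ref = plant$ref,
    alt = plant$alt, type = "causal", maf = 0)
  sites <- data.table::rbindlist(list(causal_row, enu_sites, common))
  sites <- unique(sites, by = c("chrom", "pos"))  # causal row wins collisions
  sites <- snap_refs(sites, models)
  sites[sites$type == "causal", `:=`(ref = plant$ref, alt = plant$alt,
                                     id = causal_row$id)]
  data.table::setorder(sites, chrom, pos)

  ped <- design_pedigree(sim$n_families, sim$g3_per_family)
  founder_ids <- ped$id[is_founder(ped)]
  set.seed(derive_seed(seed, "cohort"))
  founder_haps <- lapply(founder_ids, function(id) {
    mut <- if (id == "G0_M1") as.integer(sites$type %in% c("enu", "causal"))
           else integer(nrow(sites))
    h1 <- mut + ifelse(sites$type == "common",
                       as.integer(runif(nrow(sites)) < sites$maf), 0L)
    h2 <- ifelse(sites$type == "common",
                 as.integer(runif(nrow(sites)) < sites$maf), 0L)
    list(h1 = pmin(h1, 1L), h2 = h2)
  })
  names(founder_haps) <- founder_ids

  truth <- breed_pedigree(ped, spec, founder_haps, sites,
                          derive_seed(seed, "breed"),
                          causal_id = causal_row$id)
  truth <- assign_phenotypes(truth, plant, derive_seed(seed, "phenotype"),
                             null_model = isTRUE(sim$null_model))
  truth$pedigree <- select_cohort(truth$pedigree, sim$n_affected,
                                  sim$n_unaffected,
                                  derive_seed(seed, "select"))
  truth$plant <- plant

  gm <- genotype_markers(truth, sim$n_markers, maf_dist,
                         sim$missing_rate, sim$error_rate,
                         derive_seed(seed, "markers"))

  ped2 <- truth$pedigree
  aff <- ped2$id[ped2$phenotype == "affected" & ped2$genotyped]
  sequenced <- if (length(aff)) head(sort(aff), sim$n_sequenced_affected)
               else head(ped2$id[ped2$generation == "G3" & ped2$genotyped],
                         sim$n_sequenced_affected)
  vs <- emit_exome_vcf(truth, sequenced, path = NULL,
                       seed = derive_seed(seed, "vcf"),
                       mean_depth = sim$mean_depth)

  set.seed(derive_seed(seed, "controls"))
  cm <- sites[sites$type == "common", ]
  panel <- data.table::data.table(
    chrom = cm$chrom, pos = cm$pos, alt = cm$alt,
    ac = rbinom(nrow(cm), 2L * sim$control_panel_n, cm$maf))

  full_genotypes <- truth_genotypes(truth, site_ids = vs$variants$id)

  targets <- data.table::rbindlist(lapply(models, function(m)
    data.table::data.table(chrom = m$chrom, start = m$transcript$exons$start,
                           end = m$transcript$exons$end)))
  set.seed(derive_seed(seed, "depth"))
  depths <- rpois(sum(targets$end - targets$start + 1), sim$mean_depth)

  list(truth = truth, gm = gm, vs = vs, models = models, panel = panel,
       plant = plant, fixture = fixture, full_genotypes = full_genotypes,
       depths = depths, targets = targets, sequenced = sequenced)
}

#' Run the full mapping pipeline on a simulated cohort
#'
#' simulate -> QC -> TDT + maxT permutation -> region call -> coverage
#' summary -> filter cascade -> splice consequence for candidates in the
#' planted gene -> truth evaluation. Identical seeds and configs give
#' identical reports.
#'
#' @param cfg a [default_run_config()]
#' @param seed root seed (default `cfg$seed`)
#' @return a `run_report` list; see fields in the source or the vignette
#' @export
run_all <- function(cfg = default_run_config(), seed = NULL) {
  seed <- seed %||% cfg$seed
  stage <- "simulate"
  report <- list(seed = seed, config = cfg)
  out <- tryCatch({
    sim <- simulate_cohort(cfg, seed)
    report$provenance <- list(sites = content_hash(sim$truth$sites),
                              genotypes = content_hash(sim$gm$geno))

    stage <- "qc"
    qc <- qc_filter(sim$gm, sim$truth$pedigree,
                    qc_thresholds(cfg$qc$min_call_rate, cfg$qc$min_maf,
                                  cfg$qc$hwe_alpha))
    report$qc <- as.data.frame(qc$report)

    stage <- "tdt"
    tdt <- permutation_maxT(qc$gm, sim$truth$pedigree, cfg$tdt$n_perm,
                            derive_seed(seed, "perm"))
    regions <- call_significant_region(tdt, cfg$tdt$alpha,
                                       cfg$tdt$merge_gap_bp)
    report$regions <- as.data.frame(regions)

    stage <- "coverage"
    cov <- coverage_summary(sim$depths, coverage_config(),
                            intervals = NULL)
    report$coverage <- list(fraction_ge_20 = cov$fraction,
                            n_target_bases = cov$n_bases)

    stage <- "filter"
    if (nrow(regions)) {
      top <- regions[which.max(regions$peak_chi2), ]
      casc <- filter_cascade(sim$vs, top, sim$models, list(sim$panel),
                             sim$truth$pedigree, sim$full_genotypes,
                             thresholds = cfg$cascade[c("min_qual", "min_dp")],
                             steps = cfg$cascade$steps)
      report$cascade <- as.data.frame(casc$report)
      report$candidates <- as.data.frame(casc$candidates)
      report$genes_in_region <- count_genes_in_region(sim$models, top)
    } else {
      report$cascade <- NULL
      report$candidates <- data.frame()
      report$genes_in_region <- NA_integer_
    }

    stage <- "splice"
    wm <- if (!is.null(cfg$splice$matrix_path))
      read_pwm_tsv(cfg$splice$matrix_path) else sim$fixture$wm
    splice <- list()
    if (nrow(report$candidates)) {
      for (i in seq_len(nrow(report$candidates))) {
        cand <- report$candidates[i, ]
        if (identical(cand$gene, sim$fixture$gene$gene_id) &&
            !is.na(cand$pos) && cand$pos == sim$plant$position) {
          fx <- sim$fixture
          cmp <- compare_alleles(fx$causal_context, fx$causal_context_offset,
                                 cand$ref, cand$alt, wm)
          cons <- consequence_of_skip(fx$transcript, 10L)
          amp_full <- amplicon_length(fx$transcript, fx$primers)
          amp_skip <- amplicon_length(skip_exon(fx$transcript, 10L),
                                      fx$primers)
          splice[[cand$hgvs_c]] <- list(
            ese_ref_max = cmp$ref_max, ese_alt_max = cmp$alt_max,
            ese_delta = cmp$delta, consequence = cons,
            amplicon_full = amp_full, amplicon_skip = amp_skip)
        }
      }
    }
    report$splice <- splice

    stage <- "evaluate"
    report$truth_eval <- evaluate_against_truth(report, sim$truth)
    structure(report, class = "run_report")
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  out
}

#' Compare a run report against the simulation truth
#'
#' @param report a `run_report` (or a list with `regions` and `candidates`)
#' @param truth the `truth_set` of the simulated cohort (must carry `plant`)
#' @return list(region_hit, precision, recall, n_candidates)
#' @export
evaluate_against_truth <- function(report, truth) {
  plant <- truth$plant
  if (is.null(plant)) stop("truth set carries no planted causal variant")
  regions <- report$regions
  region_hit <- !is.null(regions) && nrow(regions) > 0 &&
    any(regions$chrom == plant$chromosome &
          regions$start <= plant$position & regions$end >= plant$position)
  cand <- report$candidates
  hit <- if (!is.null(cand) && nrow(cand))
    cand$chrom == plant$chromosome & cand$pos == plant$position &
      cand$alt == plant$alt else logical()
  list(region_hit = region_hit,
       precision = if (length(hit)) mean(hit) else NA_real_,
       recall = as.numeric(any(hit)),
       n_candidates = length(hit))
}

#' @export
print.run_report <- function(x, ...) {
  cat("enumap run report (seed", x$seed, ")\n")
  cat(sprintf("  regions called: %d\n", nrow(x$regions)))
  cat(sprintf("  candidates: %d\n",
              if (is.null(x$candidates)) 0L else nrow(x$candidates)))
  cat(sprintf("  causal recovered: %s\n",
              isTRUE(x$truth_eval$recall == 1)))
  invisible(x)
}

#' Serialise a run report to JSON
#' @param report a `run_report`
#' @param path output file
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}
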