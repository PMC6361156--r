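#' Recessive co-segregation test at one variant
#'
#' Passes iff every genotyped affected individual is homozygous for the
#' alternate allele and no genotyped unaffected individual is; individuals
#' with a missing genotype are skipped and listed. This is the decisive
#' whole-pedigree filter for a fully penetrant recessive lesion.
#'
#' @param genotypes named integer vector (0/1/2, NA = untyped), names =
#'   individual ids
#' @param phenotypes named character vector ("affected"/"unaffected"/
#'   "unknown")
#' @param model only "recessive" is implemented
#' @return list(passes, detail = per-individual table, skipped = ids with
#'   missing genotypes)
#' @export
segregation_test <- function(genotypes, phenotypes, model = "recessive") {
  model <- match.arg(model, "recessive")
  ids <- intersect(names(genotypes), names(phenotypes))
  g <- genotypes[ids]; ph <- phenotypes[ids]
  typed <- !is.na(g) & ph %in% c("affected", "unaffected")
  if (!any(ph[typed] == "affected"))
    stop("no genotyped affected individual (uninformative)")
  consistent <- ifelse(ph[typed] == "affected", g[typed] == 2L, g[typed] != 2L)
  detail <- data.table::data.table(id = ids[typed], phenotype = ph[typed],
                                   genotype = g[typed],
                                   consistent = consistent)
  list(passes = all(consistent), detail = detail,
       skipped = ids[!typed])
}

#' Novelty check against control panels
#'
#' A variant is novel iff its alternate allele is absent from every control
#' panel (other laboratory pedigrees, outside breeds, ...). Panels may be
#' `variant_set`s or data.frames with columns chrom, pos, alt and an allele
#' count column `ac` (or genotype columns). Empty panel lists are vacuously
#' novel.
#'
#' @param v variant row (chrom, pos, alt)
#' @param panels list of panels
#' @return TRUE if novel
#' @export
novelty_check <- function(v, panels) {
  if (!length(panels)) return(TRUE)
  for (p in panels) {
    if (inherits(p, "variant_set")) {
      i <- which(p$variants$chrom == v$chrom & p$variants$pos == v$pos &
                   p$variants$alt == v$alt)
      if (length(i) && sum(p$gt[i, ], na.rm = TRUE) > 0L) return(FALSE)
    } else {
      i <- which(p$chrom == v$chrom & p$pos == v$pos & p$alt == v$alt)
      if (length(i) && any(p$ac[i] > 0L)) return(FALSE)
    }
  }
  TRUE
}

#' Stepwise candidate-mutation filter cascade
#'
#' Applies six ordered predicates to an exome variant set and reports the
#' in/out counts of every step:
#' 1. site quality (QUAL and per-sample depth),
#' 2. position inside the mapped region,
#' 3. protein-affecting effect (missense / nonsense / splice site),
#' 4. homozygous alternate in every sequenced affected individual
#'    (recessive model),
#' 5. novelty against control panels,
#' 6. recessive co-segregation across the fully typed pedigree
#'    (confirmatory genotypes, e.g. from Sanger resequencing).
#'
#' Steps 2-5 are pure per-variant predicates and commute; the order here is
#' cheap-to-expensive. Individual steps can be disabled via `steps`.
#'
#' @param vs a `variant_set` (sequenced affected individuals as samples)
#' @param region one-row region (chrom, start, end) from
#'   [call_significant_region()] or user supplied
#' @param models list of [gene_model()]s for effect annotation
#' @param panels list of control panels for [novelty_check()]
#' @param ped a [pedigree()] with phenotypes
#' @param full_genotypes matrix variants x all-typed-individuals (0/1/2) used
#'   by the segregation step; NULL skips step 6
#' @param thresholds list(min_qual, min_dp)
#' @param steps character vector of enabled steps
#' @return list(candidates = annotated candidate table,
#'   report = `cascade_report` with monotone non-increasing counts)
#' @export
filter_cascade <- function(vs, region, models, panels = list(), ped,
                           full_genotypes = NULL,
                           thresholds = list(min_qual = 20, min_dp = 5),
                           steps = c("quality", "region", "effect",
                                     "recessive", "novelty", "segregation")) {
  if (is.null(region) || !nrow(as.data.frame(region)))
    stop("empty region")
  region <- as.data.frame(region)[1L, ]
  v <- vs$variants
  keep <- rep(TRUE, nrow(v))
  report <- list()
  note <- function(name, desc, fail) {
    report[[length(report) + 1L]] <<- data.table::data.table(
      step = name, description = desc, n_in = sum(keep),
      n_out = sum(keep & !fail))
    keep <<- keep & !fail
  }

  affected_samples <- intersect(vs$samples,
                                ped$id[ped$phenotype == "affected"])

  if ("quality" %in% steps) {
    dp_ok <- if (ncol(vs$dp)) apply(vs$dp >= thresholds$min_dp, 1L, all) else TRUE
    fail <- !(v$qual >= thresholds$min_qual & dp_ok)
    note("quality", sprintf("QUAL >= %g and depth >= %g in all samples",
                            thresholds$min_qual, thresholds$min_dp), fail)
  }
  if ("region" %in% steps) {
    fail <- !(v$chrom == region$chrom & v$pos >= region$start &
                v$pos <= region$end)
    note("region", sprintf("within %s:%.0f-%.0f", region$chrom,
                           region$start, region$end), fail)
  }
  ann <- vector("list", nrow(v))
  if ("effect" %in% steps) {
    for (i in which(keep)) ann[[i]] <- annotate_variant(v[i, ], models)
    eff <- vapply(seq_len(nrow(v)), function(i)
      if (keep[i]) ann[[i]]$effect else NA_character_, "")
    fail <- keep & !eff %in% c("missense", "nonsense", "splice_site")
    note("effect", "missense, nonsense or canonical splice site", fail)
  }
  if ("recessive" %in% steps) {
    hom <- if (length(affected_samples))
      apply(vs$gt[, affected_samples, drop = FALSE] == 2L, 1L,
            function(x) all(!is.na(x)) && all(x)) else rep(TRUE, nrow(v))
    note("recessive", "homozygous alternate in all sequenced affected",
         !hom)
  }
  if ("novelty" %in% steps) {
    novel <- vapply(seq_len(nrow(v)), function(i)
      if (keep[i]) novelty_check(v[i, ], panels) else TRUE, logical(1L))
    note("novelty", "alternate allele absent from control panels", !novel)
  }
  if ("segregation" %in% steps && !is.null(full_genotypes)) {
    ph <- setNames(ped$phenotype, ped$id)
    seg <- vapply(seq_len(nrow(v)), function(i) {
      if (!keep[i]) return(TRUE)
      segregation_test(full_genotypes[v$id[i], ], ph)$passes
    }, logical(1L))
    note("segregation", "recessive co-segregation in the whole pedigree",
         !seg)
  }

  cand_i <- which(keep)
  for (i in cand_i) if (is.null(ann[[i]]))
    ann[[i]] <- annotate_variant(v[i, ], models)
  candidates <- data.table::data.table(
    gene = vapply(cand_i, function(i) ann[[i]]$gene %||% NA_character_, ""),
    chrom = v$chrom[cand_i], pos = v$pos[cand_i],
    ref = v$ref[cand_i], alt = v$alt[cand_i],
    hgvs_c = vapply(cand_i, function(i) ann[[i]]$hgvs_c %||% NA_character_, ""),
    hgvs_p = vapply(cand_i, function(i) ann[[i]]$hgvs_p %||% NA_character_, ""),
    effect = vapply(cand_i, function(i) ann[[i]]$effect, ""))
  report <- data.table::rbindlist(report)
  structure(list(candidates = candidates, report = report),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("filter cascade:\n")
  print(x$report)
  cat(sprintf("%d candidate(s)\n", nrow(x$candidates)))
  invisible(x)
}
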