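#' Gene model with its local sequence fragment
#'
#' Bundles a [transcript_model()] (absolute genomic exon coordinates, plus
#' strand) with the genomic sequence fragment that covers the gene, so that
#' variants can be annotated without materialising whole chromosomes.
#'
#' @param transcript a [transcript_model()] with spliced sequence
#' @param fragment genomic sequence covering the gene (and flanks)
#' @param fragment_start 1-based genomic coordinate of `fragment`'s first base
#' @return object of class `gene_model`
#' @export
gene_model <- function(transcript, fragment, fragment_start) {
  stopifnot(inherits(transcript, "transcript_model"))
  assert_dna(fragment, "fragment")
  span <- range(c(transcript$exons$start, transcript$exons$end))
  if (span[1L] < fragment_start ||
      span[2L] > fragment_start + nchar(fragment) - 1L)
    stop("fragment does not cover the gene")
  structure(list(gene_id = transcript$gene_id, chrom = transcript$chrom,
                 strand = transcript$strand, transcript = transcript,
                 fragment = fragment, fragment_start = as.numeric(fragment_start)),
            class = "gene_model")
}

gene_span <- function(gm) {
  c(start = min(gm$transcript$exons$start), end = max(gm$transcript$exons$end))
}

fragment_base <- function(gm, gpos) {
  off <- gpos - gm$fragment_start + 1
  substr(gm$fragment, off, off)
}

#' Codon index and within-codon offset of a CDS position
#'
#' `codon_index = ((cds_position - 1) %/% 3) + 1`; CDS position 1226 is the
#' second base of codon 409.
#'
#' @param cds_position 1-based position in the coding sequence
#' @return list(codon_index, offset) with offset in 1..3
#' @export
cds_pos_to_codon <- function(cds_position) {
  stopifnot(cds_position >= 1)
  list(codon_index = as.integer((cds_position - 1) %/% 3 + 1),
       offset = as.integer((cds_position - 1) %% 3 + 1))
}

## genomic position -> 1-based spliced-transcript position (NA if intronic /
## outside)
genomic_to_spliced <- function(t, gpos) {
  ex <- t$exons
  i <- which(gpos >= ex$start & gpos <= ex$end)
  if (!length(i)) return(NA_integer_)
  as.integer(exon_spliced_starts(t)[i] + (gpos - ex$start[i]))
}

spliced_to_genomic <- function(t, spos) {
  starts <- exon_spliced_starts(t)
  i <- findInterval(spos, starts)
  t$exons$start[i] + (spos - starts[i])
}

#' Annotate the coding effect of a variant on a gene model
#'
#' Maps the genomic position into the CDS (plus strand), swaps the codon base
#' and classifies the substitution under the standard genetic code. Positions
#' outside the gene (or in deep intron) annotate as `non_coding`, the first
#' and last two intronic bases flanking an exon as `splice_site`.
#'
#' @param v list or one-row data.frame with `chrom`, `pos`, `ref`, `alt`
#' @param model a [gene_model()]
#' @return list: gene, effect (synonymous/missense/nonsense/splice_site/
#'   non_coding), cds_position, codon_index, aa_ref, aa_alt, hgvs_c, hgvs_p
#' @export
annotate_effect <- function(v, model) {
  non_coding <- list(gene = NA_character_, effect = "non_coding",
                     cds_position = NA_integer_, codon_index = NA_integer_,
                     aa_ref = NA_character_, aa_alt = NA_character_,
                     hgvs_c = NA_character_, hgvs_p = NA_character_)
  t <- model$transcript
  span <- gene_span(model)
  if (v$chrom != model$chrom || v$pos < span["start"] || v$pos > span["end"])
    return(non_coding)
  spos <- genomic_to_spliced(t, v$pos)
  if (is.na(spos)) {
    ## intronic: canonical splice site = first/last 2 bases of the intron
    d_don <- v$pos - t$exons$end      # bases past an exon end
    d_acc <- t$exons$start - v$pos    # bases before an exon start
    if (any(d_don >= 1 & d_don <= 2) || any(d_acc >= 1 & d_acc <= 2)) {
      ann <- non_coding
      ann$gene <- model$gene_id
      ann$effect <- "splice_site"
      return(ann)
    }
    return(non_coding)
  }
  cds_pos <- spos - t$cds_offset + 1L
  cds_len <- nchar(t$seq) - t$cds_offset + 1L
  if (cds_pos < 1L || cds_pos > cds_len) return(non_coding)
  cp <- cds_pos_to_codon(cds_pos)
  cds <- substr(t$seq, t$cds_offset, nchar(t$seq))
  codon <- substr(cds, 3L * cp$codon_index - 2L, 3L * cp$codon_index)
  if (substr(codon, cp$offset, cp$offset) != v$ref)
    stop("reference allele mismatch at ", v$chrom, ":", v$pos)
  alt_codon <- codon
  substr(alt_codon, cp$offset, cp$offset) <- v$alt
  aa_ref <- unname(CODON_TABLE[codon])
  aa_alt <- unname(CODON_TABLE[alt_codon])
  effect <- if (aa_ref == aa_alt) "synonymous"
            else if (aa_alt == "*") "nonsense"
            else if (aa_ref == "*") "stop_lost"
            else "missense"
  list(gene = model$gene_id, effect = effect,
       cds_position = as.integer(cds_pos), codon_index = cp$codon_index,
       aa_ref = aa_ref, aa_alt = aa_alt,
       hgvs_c = sprintf("c.%d%s>%s", cds_pos, v$ref, v$alt),
       hgvs_p = sprintf("p.%s%d%s", aa_ref, cp$codon_index, aa_alt))
}

#' Annotate a variant against a list of gene models
#'
#' Returns the first coding (non-`non_coding`) annotation, or the
#' `non_coding` annotation if no model covers the variant.
#' @param v variant row (chrom, pos, ref, alt)
#' @param models list of [gene_model()]s
#' @export
annotate_variant <- function(v, models) {
  ann <- NULL
  for (m in models) {
    a <- annotate_effect(v, m)
    if (a$effect != "non_coding") return(a)
    ann <- a
  }
  ann %||% annotate_effect(v, models[[1L]])
}

## -- synthetic decoy genes --------------------------------------------------

## A handful of small protein-coding genes scattered along the toy genome so
## that the exome filter's effect and region predicates have real work to do.
make_decoy_genes <- function(spec, n = 30, seed = 1,
                             region = NULL, n_in_region = 0) {
  set.seed(seed)
  models <- vector("list", n)
  for (g in seq_len(n)) {
    if (g <= n_in_region && !is.null(region)) {
      chrom <- region$chrom
      gstart <- floor(runif(1, region$start, region$end - 1e5))
    } else {
      chrom <- sample(spec$chromosomes$name, 1L, prob = spec$chromosomes$length)
      clen <- spec$chromosomes$length[match(chrom, spec$chromosomes$name)]
      gstart <- floor(runif(1, 1e5, clen - 1e5))
    }
    n_ex <- sample(2:4, 1L)
    ex_len <- sample(60:220, n_ex, replace = TRUE) * 3L
    intr_len <- sample(150:600, max(0L, n_ex - 1L), replace = TRUE)
    n_codon <- sum(ex_len) / 3L
    sense <- names(CODON_TABLE)[CODON_TABLE != "*"]
    cds <- paste0("ATG",
                  paste(sample(sense, n_codon - 2L, replace = TRUE), collapse = ""),
                  "TAA")
    introns <- vapply(intr_len, function(L)
      paste0("GT", random_dna(L - 4L), "AG"), "")
    starts <- gstart + cumsum(c(0L, head(ex_len, -1L) + intr_len))
    exons <- data.frame(exon = seq_len(n_ex), start = starts,
                        end = starts + ex_len - 1L)
    pieces <- character(2L * n_ex - 1L)
    sp <- exon_starts <- cumsum(c(1L, head(ex_len, -1L)))
    for (i in seq_len(n_ex)) {
      pieces[2L * i - 1L] <- substr(cds, sp[i], sp[i] + ex_len[i] - 1L)
      if (i < n_ex) pieces[2L * i] <- introns[i]
    }
    flank5 <- random_dna(200L); flank3 <- random_dna(200L)
    fragment <- paste0(flank5, paste(pieces, collapse = ""), flank3)
    tr <- transcript_model(exons, cds, cds_offset = 1L,
                           gene_id = sprintf("decoy_%02d", g), chrom = chrom)
    models[[g]] <- gene_model(tr, fragment, gstart - 200L)
  }
  models
}

## -- GFF3 / FASTA emission --------------------------------------------------

#' Write gene models as GFF3 (gene/mRNA/exon/CDS features)
#' @param models list of [gene_model()]s
#' @param path output file
#' @return invisibly `path`
#' @export
write_gene_models_gff3 <- function(models, path) {
  grl <- lapply(models, function(m) {
    ex <- m$transcript$exons
    gid <- m$gene_id; mid <- paste0(gid, ".t1")
    span <- gene_span(m)
    GenomicRanges::GRanges(
      seqnames = m$chrom,
      ranges = IRanges::IRanges(
        start = c(span["start"], span["start"], ex$start, ex$start),
        end = c(span["end"], span["end"], ex$end, ex$end)),
      strand = m$strand,
      type = c("gene", "mRNA", rep("exon", nrow(ex)), rep("CDS", nrow(ex))),
      ID = c(gid, mid, paste0(mid, ".exon", ex$exon), paste0(mid, ".cds", ex$exon)),
      Parent = c(NA, gid, rep(mid, 2L * nrow(ex))),
      phase = c(rep(NA_integer_, 2L + nrow(ex)),
                (3L - (cumsum(c(0L, head(ex$end - ex$start + 1L, -1L))) %% 3L)) %% 3L))
  })
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models (coordinates only) from a GFF3 file
#'
#' Recovers exon structures written by [write_gene_models_gff3()]. Sequence
#' fragments are not stored in GFF3, so the returned models carry coordinates
#' only unless `fragments` supplies them (named by gene id, with a
#' `fragment_start` attribute each).
#' @param path GFF3 path
#' @return list of [transcript_model()]s keyed by gene id
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  parents <- vapply(ex$Parent, function(p) p[[1L]], "")
  out <- list()
  for (mid in unique(parents)) {
    e <- ex[parents == mid]
    gid <- sub("\\.t1$", "", mid)
    df <- data.frame(exon = seq_along(e),
                     start = GenomicRanges::start(e),
                     end = GenomicRanges::end(e))
    out[[gid]] <- transcript_model(df, NULL, 1L, gene_id = gid,
                                   chrom = as.character(GenomicRanges::seqnames(e)[1L]),
                                   strand = as.character(GenomicRanges::strand(e)[1L]))
  }
  out
}

#' Write gene-model fragments as FASTA
#'
#' One record per model, named `<gene_id>` with a ` fragment_start=` tag in
#' the description so coordinates can be reconstructed.
#' @param models list of [gene_model()]s
#' @param path output file
#' @export
write_fragments_fasta <- function(models, path) {
  seqs <- Biostrings::DNAStringSet(vapply(models, `[[`, "", "fragment"))
  names(seqs) <- vapply(models, function(m)
    sprintf("%s %s fragment_start=%.0f", m$gene_id, m$chrom, m$fragment_start), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Count gene models overlapping a region (1-based inclusive, any overlap)
#'
#' @param models list of [gene_model()]s (or `transcript_model`s)
#' @param region list/row with chrom, start, end
#' @return integer count
#' @export
count_genes_in_region <- function(models, region) {
  if (!length(models)) return(0L)
  spans <- lapply(models, function(m) {
    t <- if (inherits(m, "gene_model")) m$transcript else m
    data.frame(chrom = t$chrom, start = min(t$exons$start),
               end = max(t$exons$end))
  })
  df <- do.call(rbind, spans)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  q <- GenomicRanges::GRanges(region$chrom,
                              IRanges::IRanges(region$start, region$end))
  sum(GenomicRanges::countOverlaps(gr, q) > 0L)
}
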