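#' Transcript model: ordered exons plus the spliced sequence
#'
#' Coordinates are genomic, 1-based inclusive, plus strand (minus-strand
#' genes are handled by reverse-complementing before model construction).
#' `cds_offset` is the 1-based position of the first CDS base in the spliced
#' transcript; fixtures use CDS-only transcripts (`cds_offset = 1`).
#'
#' @param exons data.frame with columns `exon` (integer id), `start`, `end`
#'   (genomic, ascending, non-overlapping)
#' @param seq spliced transcript sequence (concatenated exon sequence), or
#'   NULL for a coordinates-only model
#' @param cds_offset 1-based CDS start within the spliced sequence
#' @param gene_id,chrom,strand annotation fields
#' @return object of class `transcript_model`
#' @export
transcript_model <- function(exons, seq = NULL, cds_offset = 1L,
                             gene_id = "gene", chrom = "chr1", strand = "+") {
  stopifnot(is.data.frame(exons), all(c("exon", "start", "end") %in% names(exons)))
  exons <- as.data.frame(exons)[order(exons$start), ]
  if (any(exons$end < exons$start)) stop("exon end < start")
  if (any(head(exons$end, -1L) >= tail(exons$start, -1L)))
    stop("exons overlap or are unsorted")
  exons$length <- exons$end - exons$start + 1L
  if (!is.null(seq)) {
    assert_dna(seq, "spliced sequence")
    if (nchar(seq) != sum(exons$length))
      stop("spliced sequence length does not match exon lengths")
  }
  structure(list(exons = exons, seq = seq, cds_offset = as.integer(cds_offset),
                 gene_id = gene_id, chrom = chrom, strand = strand),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s: %d exons, %d bp spliced, CDS offset %d\n",
              x$gene_id, nrow(x$exons), sum(x$exons$length), x$cds_offset))
  invisible(x)
}

## 1-based spliced-transcript coordinate of the first base of each exon
exon_spliced_starts <- function(t) {
  c(1L, head(cumsum(t$exons$length), -1L) + 1L)
}

#' Remove one internal exon from a transcript (exon skipping)
#'
#' @param t a [transcript_model()]
#' @param exon_id id of an internal exon
#' @return a new `transcript_model` without that exon; the spliced sequence
#'   shortens by exactly the exon length
#' @export
skip_exon <- function(t, exon_id) {
  i <- match(exon_id, t$exons$exon)
  if (is.na(i)) stop("no such exon: ", exon_id)
  if (i == 1L || i == nrow(t$exons))
    stop("terminal exons cannot be skipped (not exon skipping)")
  seq <- t$seq
  if (!is.null(seq)) {
    s <- exon_spliced_starts(t)[i]
    e <- s + t$exons$length[i] - 1L
    seq <- paste0(substr(seq, 1L, s - 1L), substr(seq, e + 1L, nchar(seq)))
  }
  transcript_model(t$exons[-i, c("exon", "start", "end")], seq,
                   t$cds_offset, t$gene_id, t$chrom, t$strand)
}

#' Translate a CDS with the standard genetic code
#'
#' Translation halts at the first stop codon. A trailing partial codon
#' (sequence length not a multiple of 3, as after a frameshift) is ignored.
#'
#' @param cds coding sequence starting at the first codon base
#' @return list(protein, stop_found, stop_codon_index); `stop_codon_index`
#'   is the 1-based codon index of the stop (NA when no stop is reached)
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  assert_dna(cds, "CDS")
  n_codon <- nchar(cds) %/% 3L
  starts <- 3L * seq_len(n_codon) - 2L
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(CODON_TABLE[codons])
  stop_i <- match("*", aa)
  if (is.na(stop_i)) {
    list(protein = paste(aa, collapse = ""), stop_found = FALSE,
         stop_codon_index = NA_integer_)
  } else {
    list(protein = paste(aa[seq_len(stop_i - 1L)], collapse = ""),
         stop_found = TRUE, stop_codon_index = stop_i)
  }
}

#' Predict the consequence of skipping one exon
#'
#' A skipped length that is not a multiple of 3 shifts the reading frame of
#' all downstream codons (103 %% 3 == 1 for the 103 bp exon of the reference
#' fixture); the mutant ORF is translated to locate a premature termination
#' codon and the truncated protein length.
#'
#' @param t a [transcript_model()] carrying a spliced sequence
#' @param exon_id internal exon to skip
#' @return list: skipped_exon, skipped_length, frameshift, premature_stop,
#'   stop_codon_index (mutant ORF), protein_length (mutant),
#'   wt_protein_length
#' @export
consequence_of_skip <- function(t, exon_id) {
  if (is.null(t$seq)) stop("transcript model carries no sequence")
  skipped_len <- t$exons$length[match(exon_id, t$exons$exon)]
  mut <- skip_exon(t, exon_id)
  wt_tr <- translate_cds(substr(t$seq, t$cds_offset, nchar(t$seq)))
  mut_tr <- translate_cds(substr(mut$seq, mut$cds_offset, nchar(mut$seq)))
  wt_len <- nchar(wt_tr$protein)
  mut_len <- nchar(mut_tr$protein)
  list(skipped_exon = exon_id,
       skipped_length = as.integer(skipped_len),
       frameshift = skipped_len %% 3L != 0L,
       premature_stop = isTRUE(mut_tr$stop_found) && mut_len < wt_len,
       stop_codon_index = mut_tr$stop_codon_index,
       protein_length = mut_len,
       wt_protein_length = wt_len)
}

#' RT-PCR primer pair anchored on the spliced transcript
#'
#' The forward anchor is the first base of the amplicon (within its exon);
#' the reverse anchor is the last base.
#'
#' @param fwd_exon,fwd_offset exon id and 1-based offset of the amplicon start
#' @param rev_exon,rev_offset exon id and 1-based offset of the amplicon end
#' @return object of class `primer_pair`
#' @export
primer_pair <- function(fwd_exon, fwd_offset, rev_exon, rev_offset) {
  stopifnot(fwd_offset >= 1, rev_offset >= 1)
  structure(list(fwd_exon = fwd_exon, fwd_offset = as.integer(fwd_offset),
                 rev_exon = rev_exon, rev_offset = as.integer(rev_offset)),
            class = "primer_pair")
}

#' Length of an RT-PCR amplicon on a (possibly exon-skipped) transcript
#'
#' @param t a [transcript_model()]
#' @param primers a [primer_pair()]
#' @return amplicon length in bp (1-based inclusive on the spliced sequence)
#' @export
amplicon_length <- function(t, primers) {
  fi <- match(primers$fwd_exon, t$exons$exon)
  ri <- match(primers$rev_exon, t$exons$exon)
  if (is.na(fi) || is.na(ri))
    stop("primer anchor exon was skipped (primer dropout)")
  starts <- exon_spliced_starts(t)
  if (primers$fwd_offset > t$exons$length[fi] ||
      primers$rev_offset > t$exons$length[ri])
    stop("primer offset outside its exon")
  p1 <- starts[fi] + primers$fwd_offset - 1L
  p2 <- starts[ri] + primers$rev_offset - 1L
  if (p1 > p2) stop("forward anchor must precede reverse anchor")
  as.integer(p2 - p1 + 1L)
}

#' Minigene construct model
#'
#' A splicing-reporter plasmid: RT-PCR products are the vector contribution
#' (plasmid-specific primer arms) plus the lengths of the insert segments
#' retained in the mature message.
#'
#' @param segments data.frame with columns `id`, `length`, `includable`
#'   (logical: TRUE for the alternatively spliced segment)
#' @param vector_contribution bp contributed by the empty plasmid (e.g. 169)
#' @return object of class `minigene_model`
#' @export
minigene_model <- function(segments, vector_contribution = 169L) {
  stopifnot(is.data.frame(segments),
            all(c("id", "length", "includable") %in% names(segments)))
  if (any(segments$length <= 0) || vector_contribution <= 0)
    stop("all lengths must be > 0")
  structure(list(segments = as.data.frame(segments),
                 vector_contribution = as.integer(vector_contribution)),
            class = "minigene_model")
}

#' RT-PCR product lengths of a minigene under inclusion patterns
#'
#' @param m a [minigene_model()]
#' @param patterns list of character vectors, each naming the insert segments
#'   retained in one splice isoform (an empty vector is the empty-plasmid
#'   product)
#' @return integer vector of product lengths, one per pattern
#' @export
minigene_products <- function(m, patterns) {
  if (!is.list(patterns)) patterns <- list(patterns)
  vapply(patterns, function(p) {
    if (length(p) && !all(p %in% m$segments$id))
      stop("unknown segment id: ", paste(setdiff(p, m$segments$id), collapse = ","))
    as.integer(m$vector_contribution +
                 sum(m$segments$length[match(p, m$segments$id)]))
  }, integer(1L))
}
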