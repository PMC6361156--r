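## Run expr with the global RNG state preserved, using a fixed local seed, so
## deterministic fixtures never perturb a caller's random stream.
with_fixed_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Deterministic DUOX2-like gene fixture
#'
#' Builds a synthetic 11-exon plus-strand gene on chr1 (inside the 118-160 Mb
#' mapping interval) that reproduces the coordinate arithmetic of the real
#' causal gene while carrying an otherwise random coding sequence:
#'
#' * exon 10 is 103 bp (so skipping it shifts the reading frame, 103 %% 3 = 1);
#' * CDS position 1226 is the second base of codon 409, the codon is GAT
#'   (Asp), and an A>G substitution there gives GGT (Gly) - the D409G lesion;
#' * the sequence context at CDS 1225-1233 is the ESE motif G\[A/G\]TCTGAGG;
#' * RT-PCR primers anchored in exons 9 and 11 give a 377 bp product on the
#'   full transcript and 274 bp after exon-10 skipping;
#' * the minigene model carries insert segments of 91, 103 and 164 bp over a
#'   169 bp vector contribution (bands 527 / 424 / 169 bp).
#'
#' The fixture is byte-stable: it is generated from a fixed internal seed and
#' leaves the caller's RNG state untouched. The bundled weight matrix is a
#' clearly *synthetic* SRSF2-like stand-in (consensus GGTCTGAG, match score 1
#' per base, threshold 6.5); the published ESEfinder SRSF2/SC35 matrix can be
#' supplied via [read_pwm_tsv()] to reproduce published score values.
#'
#' @return list with elements `gene` ([gene_model()]), `transcript`,
#'   `plant` ([causal_plant()]), `wm` ([weight_matrix()]), `minigene`
#'   ([minigene_model()]), `primers` ([primer_pair()]), `causal_context`
#'   (exon-10 sequence) and `causal_context_offset` (variant offset therein)
#' @export
make_duox2_like_fixture <- function() {
  with_fixed_seed(20190115, {
    exon_len <- c(120L, 130L, 140L, 110L, 150L, 120L, 90L, 152L, 138L, 103L, 700L)
    stopifnot(sum(exon_len[1:9]) == 1150L, sum(exon_len) %% 3L == 0L)
    intron_len <- c(rep(300L, 8L), 350L, 420L)
    n_codon <- sum(exon_len) / 3L
    sense <- names(CODON_TABLE)[CODON_TABLE != "*"]
    cds <- paste0("ATG",
                  paste(sample(sense, n_codon - 2L, replace = TRUE),
                        collapse = ""),
                  "TAA")
    ## plant the ESE motif G[A]TCTGAGG at CDS 1225-1233 (codons 409-411 =
    ## GAT CTG AGG, all sense codons; codon 409 = GAT = Asp)
    substr(cds, 1225L, 1233L) <- "GATCTGAGG"

    fragment_start <- 138999500
    gene_start <- fragment_start + 500
    gstarts <- gene_start + cumsum(c(0L, head(exon_len, -1L) + intron_len))
    exons <- data.frame(exon = 1:11, start = gstarts,
                        end = gstarts + exon_len - 1L)
    introns <- vapply(intron_len, function(L)
      paste0("GT", random_dna(L - 4L), "AG"), "")
    sp <- cumsum(c(1L, head(exon_len, -1L)))
    pieces <- character(21L)
    for (i in 1:11) {
      pieces[2L * i - 1L] <- substr(cds, sp[i], sp[i] + exon_len[i] - 1L)
      if (i < 11L) pieces[2L * i] <- introns[i]
    }
    fragment <- paste0(random_dna(500L), paste(pieces, collapse = ""),
                       random_dna(500L))

    tr <- transcript_model(exons, cds, cds_offset = 1L, gene_id = "DUOX2L",
                           chrom = "chr1", strand = "+")
    gm <- gene_model(tr, fragment, fragment_start)

    causal_gpos <- spliced_to_genomic(tr, 1226L)
    stopifnot(substr(cds, 1226L, 1226L) == "A",
              fragment_base(gm, causal_gpos) == "A")
    plant <- causal_plant("chr1", causal_gpos, "A", "G", "DUOX2L", 1226L)

    ## skipping exon 10 must frameshift into a premature stop; true for this
    ## fixed sequence, asserted so regressions cannot go unnoticed
    cons <- consequence_of_skip(tr, 10L)
    stopifnot(cons$frameshift, cons$premature_stop)

    scores <- matrix(0, 4L, 8L, dimnames = list(DNA_BASES, NULL))
    consensus <- strsplit("GGTCTGAG", "")[[1L]]
    scores[cbind(match(consensus, DNA_BASES), 1:8)] <- 1
    wm <- weight_matrix(scores, factor = "SRSF2_synthetic", threshold = 6.5)

    minigene <- minigene_model(
      data.frame(id = c("ex9_part", "ex10", "ex11_part"),
                 length = c(91L, 103L, 164L),
                 includable = c(FALSE, TRUE, FALSE)),
      vector_contribution = 169L)

    primers <- primer_pair(fwd_exon = 9L, fwd_offset = 2L,
                           rev_exon = 11L, rev_offset = 137L)
    stopifnot(amplicon_length(tr, primers) == 377L)

    exon10_seq <- substr(cds, 1151L, 1253L)
    list(gene = gm, transcript = tr, plant = plant, wm = wm,
         minigene = minigene, primers = primers,
         causal_context = exon10_seq, causal_context_offset = 76L)
  })
}
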