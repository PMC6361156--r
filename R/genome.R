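#' Genome specification for the simulator
#'
#' A deliberately small stand-in for a mammalian reference build: a handful of
#' autosomes with a uniform sex-averaged recombination rate. Chromosome
#' sequence is never materialised genome-wide; only gene fragments carry
#' sequence.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp)
#' @param recombination_rate uniform rate in cM per Mb (Haldane model,
#'   no interference)
#' @param base_composition named probabilities over A,C,G,T (must sum to 1)
#' @return an object of class `genome_spec`
#' @export
genome_spec <- function(chromosomes,
                        recombination_rate = 1,
                        base_composition = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  if (nrow(chromosomes) == 0L) stop("genome has no chromosomes")
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(chromosomes$name)) stop("duplicate chromosome names")
  if (recombination_rate < 0) stop("recombination_rate must be >= 0")
  bc <- base_composition[DNA_BASES]
  if (anyNA(bc)) stop("base_composition must name all of A,C,G,T")
  if (abs(sum(bc) - 1) > 1e-9) stop("base probabilities must sum to 1")
  structure(list(chromosomes = data.frame(name = as.character(chromosomes$name),
                                          length = as.numeric(chromosomes$length),
                                          stringsAsFactors = FALSE),
                 recombination_rate = recombination_rate,
                 base_composition = bc),
            class = "genome_spec")
}

#' Default toy genome: three autosomes totalling 420 Mb at 1 cM/Mb
#'
#' Scaled stand-in for the 2.5 Gb pig genome; chr1 is long enough to hold the
#' 118-160 Mb mapping interval reported for the real cross.
#' @export
default_genome_spec <- function() {
  genome_spec(data.frame(name = c("chr1", "chr2", "chr3"),
                         length = c(160e6, 140e6, 120e6)))
}

#' ENU mutagenesis model
#'
#' ENU induces random point mutations; the burden is modelled as a Poisson
#' count of substitutions in the mutagenized founder genome, with a
#' substitution spectrum conditioned on the reference base. The default
#' spectrum is biased towards A:T base pairs (A>G / T>C transitions at
#' weight 0.5), matching ENU chemistry and the observed A>G causal lesion.
#'
#' @param mutations_per_genome Poisson mean for the founder burden
#' @param spectrum 4x4 matrix, rows = reference base A/C/G/T, columns = the
#'   alternate base; each row sums to 1 and has a zero diagonal
#' @return object of class `enu_model`
#' @export
enu_model <- function(mutations_per_genome = 300,
                      spectrum = default_enu_spectrum()) {
  if (mutations_per_genome < 0) stop("mutations_per_genome must be >= 0")
  stopifnot(is.matrix(spectrum),
            identical(rownames(spectrum), DNA_BASES),
            identical(colnames(spectrum), DNA_BASES))
  if (any(diag(spectrum) != 0)) stop("spectrum diagonal must be 0")
  if (any(abs(rowSums(spectrum) - 1) > 1e-9)) stop("spectrum rows must sum to 1")
  structure(list(mutations_per_genome = mutations_per_genome,
                 spectrum = spectrum),
            class = "enu_model")
}

#' @rdname enu_model
#' @export
default_enu_spectrum <- function() {
  m <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  m["A", c("G", "T", "C")] <- c(0.50, 0.30, 0.20)
  m["T", c("C", "A", "G")] <- c(0.50, 0.30, 0.20)
  m["G", c("A", "T", "C")] <- c(0.50, 0.25, 0.25)
  m["C", c("T", "A", "G")] <- c(0.50, 0.25, 0.25)
  m
}

#' Description of the planted causal variant
#'
#' @param chromosome chromosome name
#' @param position 1-based genomic bp
#' @param ref,alt single reference / alternate bases, ref != alt
#' @param gene id of the planted gene model
#' @param cds_position 1-based position in the coding sequence (e.g. 1226)
#' @param inheritance only "recessive" is supported
#' @param penetrance probability that a homozygous-alt animal is affected
#' @return object of class `causal_plant`
#' @export
causal_plant <- function(chromosome, position, ref, alt, gene, cds_position,
                         inheritance = "recessive", penetrance = 1) {
  stopifnot(position >= 1, cds_position >= 1)
  if (ref == alt) stop("alt must differ from ref")
  inheritance <- match.arg(inheritance, "recessive")
  if (penetrance < 0 || penetrance > 1) stop("penetrance must be in [0,1]")
  structure(list(chromosome = chromosome, position = as.numeric(position),
                 ref = ref, alt = alt, gene = gene,
                 cds_position = as.integer(cds_position),
                 inheritance = inheritance, penetrance = penetrance),
            class = "causal_plant")
}
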