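#' @importFrom stats pchisq rbinom rnorm rpois runif setNames
#' @importFrom utils head tail write.table read.table modifyList
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a per-stage RNG seed from a root seed
#'
#' All stochastic stages of the pipeline draw their seed from one root seed
#' through this function, so that a single integer reproduces a whole run
#' while stages remain decoupled (inserting markers does not perturb the
#' breeding randomness). Derived seeds stay below 2^31 - 1.
#'
#' @param seed root integer seed
#' @param stage stage label, one of the known stage names
#' @return an integer seed
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offsets <- c(
    founders = 101L, breed = 211L, phenotype = 307L, markers = 401L,
    vcf = 503L, perm = 601L, depth = 701L, nullpheno = 811L,
    decoys = 907L, common = 1009L, controls = 1117L, cohort = 1223L,
    select = 1327L
  )
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  s <- (abs(as.double(seed)) * 48271 + offsets[[stage]] * 99991) %% 2147483629
  as.integer(s)
}

## Standard genetic code, base order T,C,A,G with the third base cycling
## fastest (the conventional 64-codon layout).
CODON_TABLE <- local({
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), times = 4L),
                   rep(b, times = 16L))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1L]]
  setNames(aas, codons)
})

#' Reverse-complement a DNA string
#' @param x character scalar of A/C/G/T (case-insensitive)
#' @return reverse complement, upper case
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTacgt", "TGCATGCA",
         paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

random_dna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs[DNA_BASES]),
        collapse = "")
}

assert_dna <- function(x, what = "sequence") {
  if (grepl("[^ACGT]", x))
    stop(what, " contains non-ACGT characters (mask or remove Ns first)")
  invisible(x)
}

## Short provenance hash of any R object (stage bookkeeping only).
content_hash <- function(x) digest::digest(x, algo = "xxhash64")
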