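---
title: "enumap: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{enumap: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enumap)
```

# Scope

`enumap` implements the desk-scale analysis chain for mapping a recessive
point mutation in an ENU-mutagenized animal pedigree: synthetic cohort
generation, SNP-array QC, the family-based transmission disequilibrium test
(TDT) with maxT permutation correction and region calling, a stepwise exome
filter cascade, and splicing-consequence arithmetic for a lesion in an
exonic splicing enhancer (ESE). This vignette records the models, the
tunable parameters and why their defaults are what they are, the numerical
choices, and what a green test does and does not establish.

# The simulated world

## Genome and recombination

The toy genome is three autosomes of 160/140/120 Mb (420 Mb total) at a
uniform 1 cM/Mb — a scaled stand-in for a ~2.5 Gb mammalian genome chosen so
that chr1 can hold a 118–160 Mb mapping interval. Recombination follows the
Haldane model: per-gamete crossover counts are Poisson with mean equal to
the map length in Morgans, crossover positions are uniform, and there is no
interference. This is the simplest defensible meiosis model; interference
would slightly reduce double-crossover rates over the ~40 cM scale of the
mapping interval but does not change any qualitative behaviour the tests
assert.

## Pedigree design

The default design mirrors a recessive screen: one mutagenized G0 male mated
to two wild-type females; four G1 carriers, each outcrossed to an unrelated
wild-type mate; two G2 carriers per G1 cross, paired across families into
four carrier-pair couples; 25 G3 offspring per couple. The genotyped cohort
is the 8 G2 parents plus 15 affected and enough unaffected G3 animals to
reach 25 unaffected in total — the 15/25 cohort of the motivating screen.

Carrier selection is modelled by *conditional gamete sampling*: when the
design flags an animal as a carrier, the gamete transmitted by its
heterozygous parent is conditioned to carry the causal allele by swapping
the gamete's haplotype labels on the causal chromosome if needed. Because
the two label assignments of one crossover realisation are equally likely
and exactly one of them carries the allele from a heterozygous parent, this
is an exact conditional sampler that leaves the crossover process untouched.
It emulates the progeny testing a real breeding program performs, and it
does not bias the TDT: transmissions from a (conditioned) heterozygous G2
parent to its G3 offspring remain Mendelian.

## Mutation burden and the causal lesion

ENU induces point mutations; the burden is modelled as a Poisson number
(default mean 300 on the 420 Mb genome, ~0.7/Mb) of heterozygous
substitutions carried by the G0 founder genome, with a substitution spectrum
biased toward A:T base pairs (A→G and T→C at weight 0.5), matching ENU
chemistry and an A>G causal allele. Two simplifications are deliberate:
the per-genome mean is a free parameter (no published per-gamete load is
assumed), and all mutations are placed in the single founder genome rather
than drawn independently per G1 gamete — at desk scale this preserves what
matters (a heterogeneous background of rare linked variants segregating
through the pedigree) at a fraction of the bookkeeping.

A deterministic DUOX2-like fixture gene (`make_duox2_like_fixture()`)
carries the causal lesion: 11 exons, exon 10 of 103 bp, CDS position 1226 as
the second base of codon 409 (GAT, Asp), the ESE context G[A/G]TCTGAGG at
CDS 1225–1233, RT-PCR primers giving 377/274 bp products with exon 10
present/skipped, and a minigene with 91/103/164 bp insert segments over a
169 bp vector contribution. The fixture is generated from a fixed internal
seed, is byte-stable, and never perturbs the caller's RNG stream. Background
"common" variants (default 150, MAF uniform on 0.05–0.5) are shared with a
simulated outside population so that the novelty filter has real work;
decoy protein-coding genes (default 30, several inside the mapping interval)
give the effect and region predicates non-trivial inputs.

## What the generator does not emulate

Read-level sequencing (FASTQ, mapping, calling), capture bias, genotyping
batch effects, structural variants, X-linkage, population structure beyond
the single pedigree, interference, and sex-specific maps. A green
pipeline test therefore establishes the *statistical logic* of the chain —
QC thresholds, transmission counting, permutation calibration, cascade
soundness, coordinate arithmetic — not robustness to upstream artefacts.

# Analysis parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `qc$min_call_rate` | 0.90 | fraction | standard array QC threshold |
| `qc$min_maf` | 0.05 | fraction | standard; uninformative below |
| `qc$hwe_alpha` | 1e-3 | p-value | flags genotyping artefacts |
| `tdt$n_perm` | 1000 | permutations | corrected-p resolution 1/1001 |
| `tdt$alpha` | 0.05 | family-wise | conventional genome-wide level |
| `tdt$merge_gap_bp` | 10 Mb | bp | long LD in closed pig populations |
| `sim$n_markers` | 5000 | markers | ~12/Mb, scaled from a 60k chip |
| `sim$missing_rate` | 0.02 | per call | realistic array no-call rate |
| `sim$error_rate` | 0.005 | per call | realistic array error rate |
| `sim$enu_mean` | 300 | mutations | free parameter, ~0.7/Mb |
| `sim$mean_depth` | 35 | reads | gives >90% of target ≥ 20× |
| `cascade$min_qual` | 20 | QUAL | conventional site filter |
| `cascade$min_dp` | 5 | reads/sample | genotype trustworthiness |

# Numerical and procedural choices

* **HWE test flavour.** The text-book chi-squared test misbehaves at 40
  animals; the conditional exact test (summing heterozygote-count
  probabilities no larger than the observed one) is implemented as the
  default, with `method = "chisq"` exposed for the asymptotic variant.
* **Allele-frequency population.** MAF and HWE are computed on *effective
  founders* — genotyped animals none of whose parents are genotyped — to
  avoid counting transmitted alleles twice; configurable to all animals.
* **TDT ambiguity.** In a doubly-heterozygous trio with a heterozygous
  child the individual parental transmissions are unidentifiable; the two
  consistent resolutions have identical totals (one transmission, one
  non-transmission), which is what the counter records. Trios with missing
  genotypes or Mendelian inconsistencies at a marker are skipped there.
* **Permutation scheme.** Transmission sign-flips (probability ½ per
  parent–offspring unit, shared across markers within a permutation) are
  valid under the TDT null irrespective of population structure, and
  preserve between-marker correlation for the maxT family-wise correction.
  The corrected p uses the add-one formula, so its floor is
  `1/(n_perm + 1)`.
* **Region bounds.** A called region spans the outermost significant
  markers; neighbouring significant markers are merged across gaps up to
  10 Mb. Bounds are therefore marker positions, not LD boundaries.
* **Minor-allele labelling.** The TDT statistic is invariant under allele
  relabelling; the minor allele is recomputed from the analysed animals,
  and the PED reader labels alleles lexicographically.
* **Cascade order.** The six predicates are applied cheap-to-expensive;
  steps 2–5 are pure per-variant predicates and provably commute (tested by
  permuting their order). Counts are monotone non-increasing by
  construction. The Sanger confirmation stage is modelled as supplying
  whole-pedigree genotypes to the segregation step, not as a chemistry
  simulation. Multi-allelic VCF records are split on ingest.
* **Coordinates.** All genomic, CDS and transcript coordinates are 1-based
  inclusive (VCF/GFF3/HGVS convention); output BED is 0-based half-open.
  Fixtures are plus-strand; minus-strand genes are handled by
  reverse-complementing before scanning.
* **ESE scoring.** The "WMV score" is interpreted as the additive PWM
  window score of ESEfinder-style matrices. The quoted 9-nt motif context
  is wider than the 8-nt SRSF2-class matrices, so the allele contrast scores
  *all* matrix-width windows overlapping the variant under both alleles and
  reports the maxima — a width-agnostic definition that also answers whether
  published values refer to one fixed window or a maximum (both are
  available from `compare_alleles()`).
* **Weight matrices.** The published SRSF2/SC35 matrix is not
  redistributable here; the package ships a clearly-labelled *synthetic*
  SRSF2-like matrix (consensus GGTCTGAG, unit match scores, threshold 6.5)
  used by the tests, and `read_pwm_tsv()` loads a user-supplied copy of the
  published matrix, with which published score values (e.g. an allele
  contrast of 3.19 vs 2.82) become reproducible. No test asserts published
  scores against the synthetic matrix.
* **Determinism.** One root seed; every stochastic stage draws a derived
  seed (`derive_seed()`), all below 2^31, so inserting a stage never
  perturbs another stage's stream. Identical seed + config gives
  byte-identical PED/MAP/VCF files and JSON reports.
* **Null world for calibration.** The type-I check re-labels phenotypes at
  random (25% affected among G3, independent of genotype) rather than
  removing the causal variant, so that cohort structure, carrier forcing and
  marker LD are all retained under the null.
* **Config format.** YAML (one artifact of record per run), with JSON
  accepted; the effective config is embedded in every run report together
  with stage content hashes.

# What the acceptance checks establish

* Family-wise type-I error of the permutation-corrected TDT at or below
  nominal over 200 null cohorts.
* Causal-region recovery in at least 90% of 50 planted cohorts at the
  scaled panel density, with cascade recall of 1 whenever the mapped
  interval contains the lesion (the cascade never discards the causal
  variant that satisfies its own assumptions).
* Exact agreement of transmission counting, the exact HWE p-value, the
  motif scanner and interval overlap counting with independent brute-force
  oracles.
* The deterministic splicing arithmetic: 377/274 bp amplicons differing by
  the 103 bp exon, 527/424/169 bp minigene products, codon 409 from CDS
  1226, and the frameshift/premature-stop consequence of skipping a
  103 bp exon.

Quantities that depend on undeposited real data — the exact retained-marker
count of the original chip QC, the real 374-gene interval content, the seven
real candidate mutations — are out of reach by construction and are not
asserted.

# Known limitations

The TDT implementation requires complete trios (both parents genotyped);
sib-TDT style extensions are not provided. The permutation flips at the
transmission-unit level, which is exact for the statistic used but does not
model genotyping error correlation within families. The exome cascade
annotates against provided gene models only (first coding annotation wins);
overlapping genes on opposite strands are not resolved. Minus-strand
annotation is supported by construction of reverse-complemented models
rather than by strand-aware coordinate mapping. The simulator's ENU burden
resides in one founder genome; per-gamete mutation draws would be needed to
study mutation-load variance across G1 lineages.
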