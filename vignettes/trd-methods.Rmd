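---
title: "Detecting transmission ratio distortion and genetic incompatibilities in advanced intercross lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transmission ratio distortion and genetic incompatibilities in advanced intercross lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trdscan)
```

## The model

An advanced intercross line (AIL) starts from two fully inbred founder
lines, so every informative marker has exactly two founder alleles, here
called A and B. After the F1, each generation is produced by random mating
within the line; recombination accumulates, linkage blocks shrink, and the
line becomes a fine-grained founder-allele mosaic. Under Mendelian
segregation a parent heterozygous A/B transmits A to an offspring with
probability one half, independently at every meiosis. Transmission ratio
distortion (TRD) is a persistent departure from that half, and can arise
pre-meiotically (meiotic drive, gamete competition) or post-zygotically
(viability selection against genotypes, including selection against
*combinations* of genotypes at unlinked loci — Bateson–Dobzhansky–Muller
(BDM) incompatibilities).

`trdscan` estimates transmission from trios. For a focal parent that is
heterozygous at a marker, the transmitted allele is resolved exactly when
the co-parent is homozygous: the child's genotype then determines which
allele the focal parent contributed. When both parents are heterozygous the
transmission is ambiguous and the trio is skipped at that marker — counted
and reported, but never imputed. This trio logic replaces statistical
phasing entirely; the package consumes called genotypes, not phased
haplotypes.

### The marker-level test

With $n_A$ and $n_B$ resolved transmissions of the two founder alleles from
heterozygous parents of one sex,

$$\chi^2 = \frac{(n_A - n_B)^2}{n_A + n_B}$$

is the score test of the binomial null $\tau = 1/2$ on one degree of
freedom, applied without continuity correction. P-values are reported as
LOD scores $-\log_{10}(p)$. The signed distortion percent is
$100\,(n_A - n/2)/(n/2)$ with $n = n_A + n_B$, positive when founder A is
over-transmitted.

Two gates precede the test. First, at least `min_het_parents` (default 10)
*distinct* heterozygous parents of the focal sex must exist — parents are
shared among many trios in a litter-structured design, and a single
heterozygous parent with many offspring would otherwise masquerade as
replication. Second, the marker must be in Hardy–Weinberg equilibrium in
the offspring generation, tested with the exact conditional test (the
probability of each feasible heterozygote count given the allele counts,
two-sided by summing all configurations no more probable than the observed
one). The chi-square transmission test assumes the HWE sampling frame;
markers failing it (default `hwe_alpha = 0.01`; the exclusion level is a
tunable, since only the exclusion itself, not its level, is standard) are
excluded with a reason code.

### Region calling

Markers above the genome-wide 1 % LOD threshold are grouped into regions:
a region runs from the first to the last flanking significant marker of a
run, broken by a chromosome change, a change of preferred allele, a gap of
more than `merge_gap_bp` (default 5 Mb) between consecutive significant
markers, or more than `max_nonsig_run` (default 3) consecutive
sub-threshold markers. The published description of region bounds does not
fix a gap rule, so both knobs are explicit configuration with the defaults
above; setting `max_nonsig_run = 0` makes any sub-threshold marker split a
run. The top marker is the member with maximal LOD; ties resolve toward
the proximal marker, so a flat plateau reports its proximal flank. The
default marker-level thresholds (6.75 at 5 %, 7.45 at 1 %) are the
published genome-wide constants and are kept as configuration rather than
re-derived, because the published Bonferroni denominator is not
reconstructible from the stated marker counts; `bonferroni_lod_threshold()`
derives thresholds for any test count when a self-consistent scan is
preferred (the vignette's and README's examples do exactly that).

### The pairwise incompatibility scan

A BDM incompatibility removes particular genotype *combinations* at two
unlinked loci. For every pair of TRD regions on different chromosomes, the
3×3 table of genotype-class co-occurrences at the regions' top markers is
compared with the outer product of its margins (independent segregation)
by Pearson's chi-square on 4 df (reduced when marginal classes are empty;
a fully degenerate table errors). The genotype combination with the
largest percent reduction $100\,(E - O)/E$ is reported as the putative
incompatible combination. Same-chromosome pairs are never tested — linkage
alone would reject independence — and appear as `not_tested`.

Multiple-testing correction uses simpleM: per chromosome, markers are cut
into blocks of at most `fix_length` (default 1200); each block contributes
the smallest number of leading eigenvalues of its genotype (0/1/2 dosage)
correlation matrix covering `variance_fraction` (default 0.995) of the
total variance; the genome-wide effective test count $M_\mathrm{eff}$ is
the block sum. Dosage correlation with pairwise-complete observations is
used directly; such matrices can be slightly indefinite, so negative
eigenvalues are clamped to zero before the cumulative ratio. The pairwise
significance threshold is $-\log_{10}\!\big(\alpha / (M_\mathrm{eff}^2
\cdot 0.5)\big)$ — the half-square pair count, kept as printed in the
source method so that $M_\mathrm{eff} = 1008$ reproduces the published
thresholds 7.0 ($\alpha=0.05$) and 7.7 ($\alpha=0.01$) exactly; the exact
unordered-pair count $M(M-1)/2$ is available via `strict_pairs = TRUE`.

### Enrichment

The nsSNP permutation test draws `draw_size` distinct non-predicted
protein-coding genes per permutation (predicted genes are recognized by the
configurable regex `^Gm\d+$` or `Rik$`) and compares the observed total
nsSNP count against the permuted totals with the add-one estimator
$(1+r)/(n+1)$, which cannot report zero. The draw size defaults to the
observed gene count because the published description is ambiguous between
the drawn and the observed set size; both are supported. Gene-set
overrepresentation is a standard upper-tail hypergeometric test
(`stats::phyper`) with Benjamini–Hochberg adjustment, and the PPI overlay
keeps edges whose genes both carry nsSNPs and lie in different,
significantly interacting regions on different chromosomes.

## What the simulator emulates — and what it does not

`simulate_ail()` generates: two opposite-homozygous founders; a fully
heterozygous F1; `generations` of random mating with
`families_per_generation` pairs (full-sib pairings avoided when the pool
allows) and fixed conception counts per litter; meiosis under a Haldane
(no-interference) model on a uniform marker map, 1 cM = 1 % recombination;
physical positions at a constant 2 Mb/cM so outputs carry realistic mouse
autosome coordinates. Drive is injected at the gamete level: a heterozygous
carrier of the configured sex transmits founder A with probability $\tau$,
implemented by conditioning the sampled gamete (flipping the
whole-chromosome haplotype choice when the sampled allele disagrees with
the target), which preserves the crossover process exactly and biases
linked flanking markers in the attenuating-with-distance pattern expected
around a real drive locus. This conditioning is exact for a single
conditioned locus, hence the documented restriction of one drive locus per
chromosome. Two-locus viability selection removes conceptions with
probability given by the product of the configured 3×3 viability entries,
with up to 100 re-conceptions per litter slot; unfillable slots shrink the
litter, and a generation with no viable offspring aborts with an
extinction error rather than retrying forever.

Deliberately not modeled: genotyping error (quality control absorbs real
error; the misassignment threshold of 0.05 Mendelian-error fraction is a
package choice, as the published analysis removes wrongly assigned parents
without stating its criterion), mutation, crossover interference and
hotspots, sex chromosomes, varying litter sizes, and kinship-minimizing
mate choice beyond sib avoidance. Tests passing on this generator therefore
demonstrate the statistical machinery under idealized Mendelian noise, not
robustness to array artefacts or cryptic pedigree errors in real data.

Default desk scale is 5 chromosomes × 200 markers × 100 cM, 30 families ×
litter 4, 10 generations — sized to run in seconds while exhibiting real
linkage structure. The test suite's larger designs (up to 200 families ×
litter 6 over 7 generations, two chromosomes) are sized from power
arithmetic: the drive-recovery check pools transmissions across generations
until the binomial CI around the distortion estimate is a few percent wide,
and the incompatibility round trip needs the expected count of the deleted
genotype class, $n\,P(\mathrm{AA})P(\mathrm{BB})$, large enough that its
absence alone clears the genome-wide LOD threshold.

## Numerical choices and degenerate inputs

* Exact HWE probabilities are computed in log space (`lfactorial`) and
  normalized within the feasible set, so totals in the thousands do not
  overflow; the two-sided sum uses a `1 + 1e-12` relative slack when
  comparing probabilities to avoid ties lost to rounding.
* P-values below double-precision underflow are floored at
  `.Machine$double.xmin` and flagged `underflow`, keeping LOD scores
  finite (about 307.7 at the floor).
* `transmission_chi2` refuses `n_A + n_B = 0`; `pair_contingency` refuses
  same-chromosome pairs and empty intersections; `bdm_chi2` reduces df for
  empty marginal classes and errors at df 0.
* Ties for a region's top marker resolve proximally (`which.max` on the
  member LOD vector).
* Marker order is canonicalized to (chromosome, position) at construction,
  with numeric chromosome names sorted numerically.
* VCF records that are not biallelic are skipped with a counted warning,
  never split: the transmission test is defined only for biallelic
  founder-informative markers. Markers whose founders carry the same
  allele are retained but flagged uninformative and removed by
  `marker_qc()`; markers unpolarizable because both founders are missing
  keep arbitrary polarization and warn.

## Known limitations

The package reports both "markers loaded" and "marker tests performed"
because filtering (informativeness, call rate, heterozygous-parent floor,
HWE) makes these counts legitimately different, and published marker
counts for this kind of analysis often mix the two. Incompatibility
results are reported both as significant pair counts and as the count of
regions participating in a significant pair, since summaries of this
analysis are quoted both ways. The pairwise scan tests top markers only —
a deficit confined to a region flank can be missed — and the permutation
null draws genes, not length-matched regions, so gene-length confounding
is not corrected. None of the numerical results in this vignette or the
README are asserted anywhere the test suite does not itself compute them.
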