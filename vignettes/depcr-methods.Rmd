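---
title: "Models and methods behind depcr"
author: "depcr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind depcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depcr)
```

# Scope

`depcr` analyses primer utilization profiles (PUPs) from deconstructed PCR
(DePCR) amplicon experiments and ships a synthetic read generator that
emulates the DePCR vs standard (TAS) data-generating process. This vignette
records the models, the tunable parameters and their defaults, the numerical
choices, and the limits of what the simulation-based validation can show.
Everything quantitative below is computed by the package's test suite or by
`scripts/acceptance.R`; nothing is asserted from memory.

# Primer model

## Degenerate expansion and variant numbering

A degenerate IUPAC primer is expanded by enumerating the Cartesian product
of its per-position base sets. The order is canonical and reproducible from
the sequence alone: the leftmost degenerate position varies slowest and
bases are taken in A < C < G < T order; variant ids `RPV1`, `RPV2`, ... are
assigned in that order. For the 806R pool (`GGACTACHVGGGTWTCTAAT`;
H at position 8, V at 9, W at 14) this yields 18 variants, `RPV1 =
GGACTACAAGGGTATCTAAT` through `RPV18 = GGACTACTGGGGTTTCTAAT`. Published
figures of this system never print a variant-to-sequence mapping, so any
numbering is a convention; ours is documented and testable.

## Melting temperatures

`meltingTemperature()` uses the unified nearest-neighbor parameter set
(dinucleotide stacking enthalpies/entropies plus terminal A·T and G·C
initiation terms) with

$$T_m(\mathrm{K}) = \frac{\Delta H^\circ}{\Delta S^\circ + R \ln (C_T/f)},$$

followed by the Owczarzy divalent-cation correction evaluated at free
Mg²⁺ = max(0, Mg − dNTP), against a monovalent baseline of 50 mM. Two
conventions exist for the concentration factor $f$: $f = 4$ for equimolar
non-self-complementary duplexes, and $f = 1$ when the oligo strand is in
large excess over its template, which is the situation of a PCR primer and
the convention used by the common vendor calculators. The package defaults
to the excess-strand convention (`excessStrand = TRUE`): under it the 18
expanded 806R variants span 54.6–61.8 °C at 250 nM oligo, 2 mM Mg²⁺ and
0.2 mM dNTPs, matching the published 54.7–61 °C range of this primer pool
within the ±1 °C spread expected between thermodynamic parameter sets. With
$f = 4$ the same variants compute about 2 °C lower. All thermodynamic
constants live in one table (`NN_DH`, `NN_DS` in `R/primers.R`) for
auditability, and the uncorrected sums are exposed via
`nnThermodynamics()` so tests can check them against hand summation
exactly.

## Barcodes

`designBarcodes()` performs greedy rejection sampling: candidates are
accepted if they keep the minimum pairwise Hamming distance (default 3 at
width 10, the separation used by commercial 96-barcode amplicon panels),
are not the reverse complement of an accepted barcode, and contain no
homopolymer run longer than 3 (a practical sequencing constraint,
switchable off). Infeasible or overly tight requests fail with an explicit
error after a bounded number of draws rather than looping forever.

# The synthetic data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is validated.

## Community

`simulateCommunity()` builds `nTaxa` (default 40) template taxa with
lognormal(0, 1) relative abundances. Each taxon is assigned one variant
from the pool; its 20-base reverse-primer template site is the reverse
complement of that variant with an exact, specified number of substitutions
(default drawn from {0, 1, 2} with probabilities 0.5/0.3/0.2), giving a
controlled primer–template mismatch structure — the ingredient that makes
utilization template-specific rather than a pure ranking by melting
temperature. Insert lengths are uniform on 355–395 bases so that assembled
reads (22-base CS1 linker + 17-base forward primer + insert + 20-base
reverse-primer region + 22-base CS2 linker) fall inside the 400–500 base
window the filtering stage retains.

## Annealing model

No quantitative annealing model is published for this system, so the
variant-choice distribution is the package's own phenomenological model,
chosen once because it reproduces the qualitative findings (temperature-
dependent PUP narrowing in DePCR; near-uniform PUPs in TAS; utilization not
ranked purely by Tm when mismatches differ by taxon):

* **DePCR mode:** $p(v) \propto \sigma\!\big((T_m(v) - c \cdot mm(v) -
  T)/s\big)$ with $\sigma$ the logistic function, mismatch penalty
  $c = 3$ °C per mismatch, and softness $s = 3$ °C. The penalty magnitude
  is the textbook-scale destabilization of a single internal mismatch in a
  20-mer; the softness was set so that utilization narrows smoothly across
  the 40–60 °C gradient rather than switching abruptly, mirroring the
  smooth polynomial decline seen in gradient experiments.
* **TAS mode:** $(1 - w)\,\mathrm{uniform} + w\,p_{\mathrm{DePCR}}$ with
  $w = 0.05$. Standard PCR scrambles primer–template information because
  late-cycle primer–amplicon annealing tolerates mismatches; the simulator
  encodes that outcome phenomenologically (near-uniform utilization with a
  faint annealing-driven residual) without modelling cycle kinetics.
  Whether the near-uniformity truly arises from amplicon-phase mismatch
  tolerance is mechanistic speculation; the simulator only commits to the
  observable profile.

The mode flag changes nothing else except the default chimera probability.
Linear-vs-exponential cycle kinetics are deliberately not simulated: the
minimal structure the downstream analysis relies on is which variant ends
up in the read.

## Reads, depth, chimeras, errors

Per sample, depth is Poisson(inputNg × readsPerNg × lognormal(0, sd)) with
defaults 10 ng, 300 reads/ng and sd 0.4 — yielding a positive, noisy
input–yield relationship like the one observed when samples are pooled
after linear copying, and median depths comfortably above the default
rarefaction depth of 1800. With probability `chimeraProb` a read's insert
is a two-parent hybrid: parents are drawn abundance-weighted (abundant
templates recombine more often), the breakpoint is uniform over the shorter
insert's interior, and the primer-proximal parent supplies the variant
choice. Defaults are 0.06 in TAS mode and 0.0005 in DePCR mode, the orders
of magnitude reported for the two workflows. Substitution errors are
applied per base (default 0.001) to both the read and the observed sample
barcode; qualities are a constant Q30 — no quality-score model, no indels,
no paired-end structure (reads are emitted pre-merged).

# PUP extraction

Quality trimming is a single simplified 3′ sliding-window trimmer (window
4, threshold Q20): the read is truncated before the first window whose mean
quality drops below the threshold. It stands in for the heavier external
trimmers whose exact settings are rarely recorded; its parameters are
exposed. Length bounds (400–500) are inclusive — "shorter than 400 …
longer than 500 … removed" implies exactly this. Variant counting is an
exact substring search for each variant and its reverse complement; each
read increments exactly one variant, and when a spurious internal hit
coexists with the true primer hit the match closest to the 3′ end wins,
because that is where the reverse primer sits in merged orientation. Exact
ties between two different variants at one locus are impossible: variants
differ within the same 20-base window. Unassigned reads are reported and
excluded from PUP diversity, mirroring the exact-count procedure.
Rarefaction subsamples without replacement to exactly the target depth
(default 1800) and drops — with a message — samples below it.

# Statistics

Alpha diversity uses natural logarithms (Shannon `H`, richness, Pielou
evenness `H / ln(richness)`, defined as 1 for a single feature); the log
base is configurable. Bray–Curtis runs through `vegan::vegdist`; the
square-root transform used for community-level comparisons is exposed as a
flag and off by default for PUPs. Ordination is classical MDS via
`cmdscale` (double-centering plus eigendecomposition): that is what the
published "mMDS" analyses of this system actually called, so
stress-minimizing metric MDS is out of scope. Negative eigenvalues from
non-Euclidean dissimilarities are retained for inspection but excluded from
the proportion explained.

ANOSIM is implemented in the package (rank-based Clarke statistic,
mid-ranks on ties, seeded label permutations, p-value with the +1
correction; the default 9999 permutations make the minimum achievable p
equal to 1/10000). The two-way crossed design follows the within-block
averaging scheme: the statistic for factor A is the mean of one-way R
computed inside each level of B with block-local ranks, and permutations
relabel A only within B levels. The reference Primer software documents the
design but not the algorithm, so this scheme is stated explicitly here; the
one-way statistic is cross-checked against `vegan::anosim` in the tests.
Per-feature Kruskal–Wallis testing operates on relative abundances, filters
features below 1 % mean relative abundance, and reports both
Benjamini–Hochberg and Bonferroni adjusted p-values — published tables of
this kind are ambiguous about which "Bonferroni-Hochberg" correction was
meant, so both are given. Confidence ellipses assume a multivariate t:
location/shape from the iteratively reweighted t-covariance
(`MASS::cov.trob`, df = 4, the usual robust-covariance convention,
configurable) and radius from the F(2, n−2) quantile.

# Chimera detection

The detector is deliberately **not** UCHIME/USEARCH: it is reference-based
(the simulator provides the true template set), has no de novo mode, no
abundance-skew heuristic and no k-mer prefilter beyond an optional
reference cap. Rates it reports are validated against simulator ground
truth and should not be compared numerically with USEARCH output on real
data.

Scoring: for each read, cumulative match profiles against every reference
are computed in shared-prefix (left-aligned) and shared-suffix
(right-aligned) coordinates; under the simulator's substitution-only error
model these coincide with free-end-gap alignment profiles (the
alignment-based per-position profile is available separately as
`matchProfile()` and handles indels). The chimeric score maximizes, over
breakpoints with both segments ≥ 50 bases, the best prefix plus best suffix
match counts over two *distinct* references; a read is chimeric when this
beats the best single reference by ≥ 4 matches (`minGain`, an absolute
count so the score stays integer and brute-force-checkable). Ties resolve
to the lexicographically smallest parent pair and the smallest breakpoint.
The prefix/suffix maximization is exactly equivalent to the brute-force
search over (parent A, parent B, breakpoint) triples, and the tests assert
that equivalence on small instances. The inner scan is implemented in C++
for throughput; 20,000 reads against 40 references take a few seconds.

# Determinism and numerical choices

All randomness flows from integer seeds. The gradient driver derives one
seed per stage from a master seed via a small polynomial hash reduced
modulo 2³¹ − 1 (`deriveSeed`), so any stage can be re-run independently and
a fixed master seed gives byte-identical outputs. Degenerate inputs are
rejected eagerly with named errors: all-zero count vectors, zero-count
samples in dissimilarities (named in the message), singleton ANOSIM groups,
confounded two-way designs, rank-deficient regressions, infeasible barcode
requests. When every annealing weight underflows to zero the variant choice
falls back to uniform with a warning rather than producing NaNs.

# Problem sizes used in validation

The shipped tests validate at deliberately moderate scale, chosen to
exercise the asymptotics that matter while keeping the suite quick to run:
goodness-of-fit of empirical variant frequencies at 50,000 reads (χ²,
α = 0.01); chimera detection ceilings at 20,000 reads; the
temperature-gradient experiment at its native size (2 modes × 5
temperatures × 5 replicates, ≈ 150,000 reads, rarefied to 1800); null
calibration of the ANOSIM permutation test over 200 null datasets; 1000-
replicate rarefaction means against the hypergeometric expectation.

# What passing tests do and do not show

The simulator emulates read structure, depth scaling, annealing-dependent
variant choice, chimera formation and substitution error — enough to
validate the analysis code end-to-end against ground truth and to
reproduce the qualitative DePCR signatures (negative quadratic
temperature–diversity relationship; TAS PUP Shannon within 0.05 of ln 18;
DePCR chimera rates ≤ 0.1 %). It does not model polymerase error
phylogenies, quality-score dynamics, chimeras among closely related
templates (which real detectors largely miss), taxonomic structure, or
rRNA operon copy-number effects; agreement on simulated data therefore
validates the *analysis*, not any claim about a particular real community.
Real-data community-level results (taxon tables, fecal ANOSIM values)
require the original sequencing data and are out of scope.
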