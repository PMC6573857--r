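# depcr

Primer utilization profiling for deconstructed PCR amplicon experiments.

## The problem

Amplicon surveys of microbial communities (16S rRNA gene sequencing) almost
always use *degenerate* primer pools — for example the reverse primer 806R,
`GGACTACHVGGGTWTCTAAT`, is a pool of 18 distinct oligonucleotides (H = A/C/T,
V = A/C/G, W = A/T) with predicted melting temperatures spanning roughly
54.7–61 °C. In a standard two-stage library preparation (targeted amplicon
sequencing, TAS), the locus-specific primers act through every exponential
cycle, so which pool members actually annealed to the *genomic* template is
unrecoverable, and extensive cycling also produces chimeric amplicons.

Deconstructed PCR (DePCR) separates the two roles: locus-specific primers
copy the genomic DNA for only a few linear cycles; all exponential
amplification then targets constant linker sequences (CS1/CS2). The primer
that touched the template is thereby "fossilized" inside each read, and the
per-sample count vector of which reverse-primer variants (RPV1–RPV18) appear
in the reads — the **primer utilization profile (PUP)** — becomes a direct
readout of primer–template interaction. Two diagnostic signatures follow:

* **TAS**: utilization is near-uniform regardless of annealing temperature
  (Shannon index of the 18-variant profile close to its ceiling,
  ln 18 = 2.890);
* **DePCR**: utilization narrows as annealing temperature rises, giving a
  negative quadratic relationship between annealing temperature and PUP
  Shannon index, and chimera rates orders of magnitude below TAS
  (≤ 0.1 % vs ≈ 5–6 %).

`depcr` implements the full analysis as a tested R package, together with a
synthetic read generator that emulates the DePCR vs TAS data-generating
process, so every statistic can be validated against ground truth without
external data.

## What is inside

* **Primer model** — IUPAC expansion of degenerate primers into canonical
  numbered variants; nearest-neighbor melting temperatures (unified
  parameter set, Owczarzy divalent-cation correction, free
  Mg²⁺ = max(0, Mg − dNTP)); Hamming/IUPAC mismatch counting; barcode
  design with a guaranteed minimum pairwise Hamming distance.
* **Simulator** — a template community with controlled primer–template
  mismatch structure; a logistic annealing model
  p(v) ∝ σ((Tm(v) − penalty·mm(v) − T)/softness) for DePCR-mode variant
  choice, mixed toward uniform for TAS mode; Poisson-lognormal depth
  proportional to input DNA; two-parent chimeric inserts; per-read truth
  records.
* **PUP extraction** — sliding-window quality trimming, inclusive 400–500
  base length filtering, exact substring search for variant sequences (both
  orientations), rarefaction to a fixed depth.
* **Statistics** — Shannon/richness/Pielou evenness, Bray–Curtis
  dissimilarity, classical MDS, one-way and two-way crossed ANOSIM
  (rank-based, restricted permutations), per-feature Kruskal–Wallis with
  BH/Bonferroni control, linear/quadratic least squares, robust
  multivariate-t confidence ellipses.
* **Chimera detection** — reference-based two-parent split scoring with an
  exact prefix/suffix maximization (Rcpp), Wilson intervals on rates.
* **Driver** — `runTemperatureGradient()` runs the entire
  simulate → demultiplex → filter → extract → rarefy → ordinate → test
  pipeline across a mode × temperature grid and writes TSV reports with
  full seed provenance.

## Worked example

```r
library(depcr)

pool <- expandDegenerate("GGACTACHVGGGTWTCTAAT", name = "806R")
pool
#> PrimerPool '806R': GGACTACHVGGGTWTCTAAT (18-fold degenerate)
#>   predicted Tm: 54.6-61.8 degC

community <- simulateCommunity(pool, nTaxa = 20, seed = 11)
barcodeSet <- designBarcodes(5, width = 10, minDistance = 3, seed = 12)
cfg <- simulationConfig(mode = "DePCR", annealingTempC = 55,
                        nSamples = 5, seed = 13)
sim <- simulateReads(community, pool, barcodeSet, cfg)
sim
#> SimulatedReads: 20617 reads across 5 samples (DePCR mode, 55 degC)
#>   chimeras in truth: 9

dm  <- demultiplexSimulation(sim)
pup <- buildPupExperiment(dm$readsBySample, pool)
round(shannonIndex(rarefyCounts(pup, depth = 1800, seed = 14)), 3)
#>   S01   S02   S03   S04   S05
#> 2.817 2.813 2.820 2.823 2.827

chimeraRate(detectChimeras(simReads(sim), simTemplates(sim)))$rate
#> [1] 0.0004366425
```

The five replicate PUP Shannon indices sit below the ln 18 = 2.890 ceiling
(utilization has started to narrow at 55 °C in DePCR mode), and the detected
chimera rate (0.04 %) is at the DePCR scale, far below typical standard-PCR
rates. `runTemperatureGradient(experimentConfig())` extends this across
40–60 °C in both modes and fits the temperature–diversity regression.

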