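---
title: "Methods: read-depth CNV discovery, allele typing and selection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-depth CNV discovery, allele typing and selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvwatch)
```

`cnvwatch` implements a population-cohort pipeline for discovering
amplification copy number variants (CNVs) from short-read coverage,
characterizing the distinct CNV alleles segregating at a locus, and testing
whether those alleles sit on unusually long shared haplotypes, as expected
under recent positive selection. The design follows the analysis style used
for large mosquito resequencing cohorts (hundreds to thousands of ~30x
genomes, phased SNP haplotypes, a mix of *An. gambiae*-like autosomes and a
hemizygous male X), but every stage is generic.

This vignette explains the models, the tunable parameters and the reasoning
behind the numerical choices. Everything quantitative shown here is computed
by the package's own test suite or acceptance script; nothing is quoted from
external data.

## Windowed coverage and GC normalization

Reads are counted in non-overlapping 300-bp windows; a read belongs to the
single window containing its 0-based alignment start, so each read is
counted exactly once. Counts are converted to a copy-number scale by GC
normalization: for each sample, the count in a window with GC percentage
$g$ is divided by that sample's mean count over *autosomal* windows with
the same (integer-rounded) $g$ and at least 90% accessible bases, then
multiplied by 2. Diploid regions therefore have expected normalized
coverage 2, a haploid male X about 1, and a heterozygous duplication about
3. Constants are computed per sample because GC bias is a property of each
library; restricting to accessible autosomal windows keeps repetitive and
sex-linked regions from distorting them.

Two window filters define the analysis space ("kept windows"):

* `MQ0_EXCESS`: more than 2% of the window's reads have mapping quality 0
  (ambiguous placement). The threshold is strict — exactly 2% is kept.
* `GC_RARE`: the window's GC bin is supported by fewer than 100 accessible
  autosomal windows, making its normalizing constant unreliable.

Both filters depend only on the reference tracks and the cohort-pooled MQ0
fraction, so the mask is a single genome-wide object.

## Gaussian-HMM copy-number states

Per sample and chromosome, normalized coverage over kept windows is decoded
with a hidden Markov model whose states are integer copy numbers
$k = 0, \dots, K$ (default $K = 12$). Emissions are Gaussian with mean $k$
and variance $\sigma^2_k = \sigma^2_\mathrm{base} + k\,\sigma^2_\mathrm{slope}$;
transitions between any two distinct states share one small probability
$t = 10^{-5}$. Decoding is by Viterbi (implemented in C++), with ties broken
toward the lower copy number.

Parameter choices:

* **Emission variance.** Under a Poisson-like count model the variance of
  normalized coverage grows linearly with copy number and equals the
  observed diploid variance $v_2$ at $k = 2$. We therefore estimate $v_2$
  per sample as the squared (normal-consistent) MAD of autosomal kept
  coverage — robust, so CNV windows do not inflate it — and set
  $\sigma^2_\mathrm{slope} = v_2/2$ with a small floor
  $\sigma^2_\mathrm{base} = v_2/10$ so state 0 stays non-degenerate.
* **Transition probability.** $t = 10^{-5}$ makes a state change cost about
  11.5 log-units, so an amplification must accumulate that much emission
  evidence at each boundary. This is what makes short or low-gain events
  (e.g. five windows at copy number 3 under 30x noise) only partially
  recoverable — the same regime the filters are designed around — while ten
  windows at copy number 4 are recovered essentially always.

Raw calls are maximal runs of at least five kept windows with state above
the baseline (2 on autosomes, 1 on the male X); at 300-bp windows that is
the 1500-bp minimum CNV size. Contiguity is in kept-window index space:
windows removed by the filter do not interrupt a run, because filtering
removes windows, not genome. Consequently call coordinates (and the truth
coordinates of simulated CNVs in our tests) live in kept-window space.

Each raw call is then re-scored: the likelihood of its coverage under the
Viterbi state path is compared with a null of constant baseline copy
number, in log space (mandatory — products of per-window Gaussian densities
underflow). Calls with a likelihood ratio below 1000 are dropped; a ratio
of exactly 1000 is kept.

## Cohort assembly

Samples whose autosomal kept-window coverage variance exceeds 0.2 are
removed before calling (erratic coverage produces erratic calls). Calls are
then matched across samples: two calls are the same CNV when both
breakpoints are within one window. Because that pairwise relation is not
transitive, matching is greedy and anchor-based — calls sorted by
(chromosome, start, end, sample); the first call seeds a variant and later
calls join the *earliest* anchor within one window on both ends. This makes
the partition deterministic. Variant consensus coordinates are the medians
of member starts/ends. Finally, variants are kept only if carried by at
least 5% of individuals in some population, or by at least three
individuals in populations smaller than 40.

## Permutation enrichment tests

Three Monte-Carlo nulls, all with the two-tailed convention
$p = 2\,\#\{\mathrm{null} \ge \mathrm{observed}\}/n_\mathrm{sims}$ capped at
1, and reported as an upper bound $p < 2/n_\mathrm{sims}$ when no null draw
reaches the observed count:

* **Placement null.** Every variant is re-placed uniformly among the
  admissible positions on its own chromosome that cover the same number of
  kept windows; per simulation we count variants overlapping
  heterochromatin (any overlap, one bp suffices) and variants containing at
  least one retained gene. Keeping placements on the original chromosome
  preserves the chromosome-size composition of the call set. A euchromatin
  restricted variant excludes heterochromatin-overlapping placements, for
  testing genic enrichment inside the euchromatin only.
* **Gene-identity null.** A gene is retained when at least half of its
  windows are kept, and is "copied" when all of its kept windows fall
  inside the variant. Each genic variant covering $k$ consecutive retained
  genes is reassigned a uniformly random run of $k$ consecutive genes
  (never crossing a chromosome end — gene neighborhoods are not circular),
  and we count variants containing at least one detoxification gene
  (descriptions matching P450, glutathione S-transferase or
  carboxylesterase). A variant counts once however many detox genes it
  covers.
* **Size comparison.** Heterochromatic versus euchromatic CNV lengths are
  compared with a two-sided Wilcoxon rank-sum test (normal approximation,
  as appropriate for cohort-scale group sizes). Contingency tables use
  Fisher's exact test, falling back to a simulated p-value (default
  $10^6$ replicates) when the table is too large for exact computation.

## CNV alleles from diagnostic reads

Distinct CNV alleles at a locus are recognized by their read-level
junction signatures: tandem duplications produce read pairs aligning
*facing away* from each other around the two breakpoints; tandem
inversions produce *same-orientation* pairs; deletions inside an
amplification produce properly oriented pairs with an implied insert far
beyond the library distribution (default: more than 5 SD above the mean);
pairs with mates on different chromosomes are *crossmapped*. Reads
crossing a breakpoint align partially and carry the other side of the
junction as soft-clipped bases; their clip positions pin the breakpoint to
base precision, which is why clip anchors use a ±10-bp tolerance while
discordant-pair anchors use ±1 window (300 bp).

An allele is called present in a sample when at least two diagnostic reads
support its signature. Allele-specific copy number is then estimated from
coverage: the sample's normalized coverage over the locus is modeled as
baseline plus a constant gain over each present allele's span, solved by
non-negative least squares (gains cannot be negative), and rounded half-up
to integers. Two cohort-level rules follow the field's practice: when
exactly one sample in the cohort reaches a raw estimate of 2.5 for an
allele, that lone outlier is recorded as 2 and flagged; and alleles whose
spans coincide exactly within a sample are reported non-identifiable
rather than guessed.

Genotyping retains only single-copy alleles: 0/1/2 copies map to
homozygote wild-type / heterozygote / homozygote. Any sample above 2
copies makes the allele un-genotypeable (a heterozygous triplication is
indistinguishable from a homozygous duplication) and excludes it. When
*every* carrier has exactly 2 copies the allele is interpreted as a
triplication with no duplications segregating, and carriers are genotyped
heterozygous — note this reclassification means an apparent
"heterozygote-deficit" table of pure 2-copy carriers is resolved as a
triplication rather than failing Hardy-Weinberg. Each allele is finally
tested for Hardy-Weinberg equilibrium (exact conditional test, two-sided
by probability ordering) in every population where it occurs, with
exclusion at p < 0.05 in any of them; no multiplicity correction is
applied, which makes the filter conservative in the direction of removing
doubtful alleles.

## Selection scans

Carrier and wild-type haplotypes are compared around the CNV-containing
region, using only variants outside it (coverage inside the CNV violates
the assumptions of SNP calling and phasing there):

* **EHH.** For haplotypes sharing a core label, EHH at distance $x$ is the
  fraction of unordered pairs identical at every included variant from the
  region edge out to $x$, computed independently leftward and rightward.
  We use distinct unordered pairs (without replacement) rather than allele
  counts with replacement; at cohort sizes the difference is $O(1/n)$.
* **Shared haplotype length.** For every pair, the distance from the
  region edge to the last concordant variant before the first mismatch,
  per side and summed. Medians get percentile-bootstrap 95% CIs from
  resampling pairs (1000 resamples by default); resampling haplotypes
  instead would be the main alternative and tends to give wider intervals.
* **Clustering.** Haplotype distance is the proportion of accessible
  variants that differ; hierarchical clustering is cut at height 0.001
  (i.e. clusters of essentially identical haplotypes, ~1 difference per
  1000 sites). Complete linkage guarantees the within-cluster maximum
  distance respects the cutoff; single/average linkage are available.
  Clusters are labeled by decreasing size.
* **Association.** In females, cluster-haplotype count (0-2) versus allele
  copy number by Spearman correlation, plus the least-squares slope of
  cluster count on copy number — 0.5 when every copy rides one cluster
  haplotype; in (hemizygous) males, a 2x2 Fisher exact test of cluster
  presence against allele presence.

## The synthetic cohort generator

Because the pipeline's reference datasets are consortium-scale, all
validation runs on synthetic cohorts with known truth:

* **Reference**: windows tiling small chromosomes (an `"X"` chromosome is
  hemizygous in males), integer GC per window (normal, default mean 45),
  accessibility and MQ0 tracks with realistic minor contamination,
  heterochromatin blocks at chromosome ends, ordered non-overlapping gene
  models with ~8% flagged as detox families.
* **Coverage**: negative-binomial counts (Poisson at dispersion 1) with
  mean `depth x gc_factor(gc) x CN/2`, where the GC factor is a unimodal
  quadratic peaking at 45% GC, mimicking Illumina bias. The noise law of
  real data is not knowable from published summaries; NB covers the
  variance axis the sample-QC filter operates on. Planted CNVs specify
  window runs, added copies and zygosity per carrier.
* **Breakpoint reads**: each planted mechanism emits its classifier
  category by construction, plus soft-clips carrying a per-allele
  deterministic junction sequence (so clip consensus round-trips exactly),
  plus a low rate of scattered background discordant pairs.
* **Haplotypes**: wild-type haplotypes are exchangeable draws from
  per-site frequencies; carriers copy a single core haplotype over the CNV
  region and outward to exponentially distributed per-carrier breakpoints
  (mean `core_identity_length`), with optional mutations — a reduced model
  of a partial sweep, with no explicit recombination map or coalescent
  structure.

What the generator does *not* emulate: base-level sequences and alignment
artifacts, spatially autocorrelated GC, linkage disequilibrium among
wild-type haplotypes, overlapping CNVs arising by recurrent mutation, and
population structure beyond labels. Passing tests therefore demonstrate
algorithmic correctness and calibration under the stated noise model, not
performance on any particular real cohort.

## Problem sizes and stochastic-test design

The test suite exercises the pipeline at sizes chosen to finish in minutes
while leaving Monte-Carlo margins: normalization calibration on 10 samples
x 2000 windows at 30x (mean normalized coverage within [1.95, 2.05]);
shuffle false-discovery on 50 samples x ~5300 windows with 20 genome-wide
permutations (< 0.01 calls/sample); sensitivity at 30x over 200 replicates
(10-window copy-4 gains ≥ 85% and strictly above 5-window copy-3 gains);
Viterbi against exhaustive path enumeration on 200 instances of up to 8
windows and 5 states; placement nulls against exact enumeration on toy
genomes at $10^5$ simulations within 3 Monte-Carlo SE; allele copy-number
recovery over 500 noisy samples (≥ 95% exact integers); and sweep
detection on 100 simulated cohorts (carrier EHH dominating wild type and
non-overlapping shared-length CIs in ≥ 95%).

One regime deserves a note: the minimum-span rule ("no call under five
windows") is tested as an exact property in a low-noise setting (mean
depth 100, Poisson). At 30x, a 4-window planted gain of 2 recruits one
adjacent noise window into a legitimate 5-window call in a few percent of
replicates — the same boundary noise that gives the shuffle null its small
but nonzero rate — so "never called" is an exact statement only where
per-window noise is small; at depth 100 the recruit probability is ~1e-5.
All stochastic tests run under fixed seeds.

## Known limitations

* Deletions are modeled as states 0-1 but not emitted as calls; the
  pipeline targets amplifications.
* HMM transition/emission defaults are package choices, exposed in
  `hmm_params()`; they are not fitted to any particular instrument.
* Signature discovery is declarative: the registry of diagnostic-read
  patterns is an input (here produced by the simulator's truth), not
  inferred from data.
* Phasing of CNV genotypes onto haplotypes is consumed as input; the
  generator supplies truth phase.
* The HWE filter tests each occurring population separately without
  multiplicity correction and assumes diploidy at the locus.
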