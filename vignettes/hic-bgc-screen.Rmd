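---
title: "Screening Hi-C contact maps for biosynthetic gene cluster interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening Hi-C contact maps for biosynthetic gene cluster interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicbgc)
```

## The problem

Biosynthetic gene clusters (BGCs) in plant genomes — three or more
non-homologous genes of one pathway in close genomic proximity — are
sometimes bipartite or accompanied by related genes elsewhere entirely,
such as a tandem array of near-identical paralogs on another chromosome.
One hypothesis for how such arrangements arise and operate is physical:
the dispersed loci meet in three-dimensional nuclear space. Hi-C data
collected for genome scaffolding already contains the evidence needed to
test this, as a genome-wide matrix of contact counts between binned
loci. `hicbgc` turns that matrix into a screen: given a viewpoint region
(the BGC), which bins elsewhere in the genome does it touch more often
than expected, and is a specific candidate (the array) among them?

## The interaction statistic

The screen operates on a symmetric binned contact map at one resolution
(default 50 kb). For a viewpoint $V$ (the set of bins overlapping the
viewpoint region) the profile against a target chromosome is
$x(b) = \frac{1}{|V|}\sum_{v \in V} M(v, b)$ for every bin $b$. Per
chromosome the profile is normalized by

1. removing zero-intensity bins (and, intrachromosomally, the viewpoint
   bins themselves);
2. taking $\log_2$ of the remaining intensities;
3. z-scoring across the chromosome, $z = (\log_2 x - \bar{\ell}) / s$,
   with $s$ the sample standard deviation (denominator $n-1$).

Upper-tail p-values are normal, $p = 1 - \Phi(z)$, and
Benjamini–Hochberg correction is applied **within each chromosome**,
mirroring the per-chromosome z-scoring; bins with $q < \alpha$ (default
0.05) are called. A pooled genome-wide correction would be the natural
alternative; we kept the per-chromosome family because the z-scores are
themselves per-chromosome quantities, so each chromosome's p-values are
exchangeable only with each other.

The log-normal reading of contact intensities is an approximation: the
underlying counts are (over-dispersed) Poisson, and averaging over the
viewpoint bins plus the log transform brings the kept values close
enough to normal that the tail p-values are, if anything, conservative
— the null simulations below bear this out.

The **targeted test** for a candidate region takes the mean of the
candidate bins' $\log_2$ intensities and compares it to the same
chromosome-wide mean and sample sd, with no correction. For a single-bin
candidate this reproduces the screen's $z$ and $p$ for that bin exactly.
For multi-bin candidates we deliberately do **not** scale by
$\sqrt{k}$: the bins of one region are spatially correlated, and the
unscaled comparison is the conservative generalization.

Degenerate inputs are errors, not silent results: a chromosome with
fewer than two non-zero bins, or a constant profile (zero variance),
refuses to normalize; in the genome-wide screen such chromosomes are
reported as skipped. Zero-intensity bins stay in the output table with
NA statistics so rows are positionally complete.

## Compartments

A/B compartment PC1 follows the standard construction: the expected
value at each exact bin distance (no smoothing — the maps here are small
enough that smoothing only hides structure), observed/expected, Pearson
correlation of O/E columns, leading eigenvector. Bins with zero total
intrachromosomal contact are masked. The eigenvector sign is arbitrary,
so it is oriented by gene density when a gene track is supplied (A =
gene-rich by convention), else so the first unmasked bin is
non-negative; either rule makes the output deterministic.
`region_pc1_summary()` reports mean $|PC1|$ inside versus outside a
region — the comparison behind "the cluster sits in one chromatin
state": a region whose bins have consistently small $|PC1|$ is not
partitioned by the checkerboard that dominates the rest of the
chromosome.

## Enrichment and cluster calling

TE enrichment is exact interval arithmetic: matching intervals (by label
or '/'-delimited prefix, so "LTR" covers "LTR/Gypsy/Athila") are merged
— adjacency merges too, the half-open convention making $[10,20) +
[20,30)$ contiguous, exactly as `bedtools merge` counts bases — and the
covered fraction of the region is compared with the background. The
permutation test places the same-length region uniformly at random
(weighted by the number of valid placements per chromosome) and reports
$(1 + \#\{\text{fraction} \ge \text{observed}\})/(n_{perm}+1)$.

BGC calling chains pathway-family genes whose start-to-previous-end gap
is at most `max_gap`, ignoring intervening non-pathway genes (real
clusters are interrupted by unrelated genes), and keeps chains with at
least three distinct families. Proximity is deliberately an exposed
parameter rather than a hidden rule: the motivating cluster has a member
346 kb downstream of its core, so the default of 400 kb includes it and
a 300-kb setting excludes it, and both behaviours are tested. Tandem
arrays are maximal same-family runs of two or more genes with gaps at
most 100 kb, broken by an intervening gene of a *different* pathway
family but not by filler genes.

## The synthetic generator

Every structure the pipeline is meant to detect is planted by
`synthetic_truth()` / `simulate_contact_map()` /
`simulate_genome_annotations()` and recorded in a truth object, so each
stage can be tested against known ground truth.

The contact model is Poisson with multiplicative structure — the
simplest generative model that reproduces Hi-C's marginal behaviour:

* intrachromosomal: $\lambda_{ij} = A\, d^{-\alpha}\, m_T\, m_C$ at bin
  distance $d \ge 1$, defaults $A = 100$, $\alpha = 1$ (the classic
  contact-probability decay); the diagonal uses the $d=1$ rate times a
  fixed boost of 2, avoiding the power law's singularity — diagonal
  entries are excluded from every downstream statistic anyway;
* $m_T = 2$ for bin pairs inside the same TAD block; $m_C = 3$ for bin
  pairs whose compartment labels agree;
* interchromosomal: $\lambda = \lambda_{bg} f$, default background
  $\lambda_{bg} = 5$ counts per 50-kb bin pair, $f = 6$ inside the one
  planted viewpoint–target pair and 1 elsewhere.

Compartment labels form a checkerboard of $\pm 1$ blocks (5 bins wide).
Labels take a third value, 0, over the full BGC span: neutral bins get
no compartment boost against any partner, which is what plants the
depressed-$|PC1|$ signature over the cluster that
`region_pc1_summary()` then measures. This three-valued labelling is the
one place the truth object is richer than a plain checkerboard, and it
exists precisely so that the compartment claim is testable rather than
assumed.

The default genome is three chromosomes (2, 2.5 and 3 Mb — 150 bins at
50 kb), small enough that the whole suite simulates hundreds of
replicates in minutes yet large enough that each chromosome has ~50–100
bins for the per-chromosome statistics. The gene layout rescales the
real cluster's geometry: a 600-kb core carrying two copies each of LS,
IPR and L3OH (interleaved, so that duplicated copies never form a
same-family run of their own), an ISPD gene starting exactly 346 kb
after the core's end, and a 3 × PR tandem array inside one 50-kb bin of
another chromosome — the same bin that carries the planted contact.

TE intervals (1–10 kb, uniform) are placed by rejection sampling until
each labelled region reaches its target LTR coverage — 70% over the BGC
core, 78% over the array bin, 60% genome-wide, the contrasts the screen
is meant to recover — with the final interval trimmed so the realized
coverage lands on the target rather than overshooting by up to one
interval length. The unlabelled remainder of the genome is filled at the
rate that makes the genome-wide fraction come out at its target exactly.

What the generator does **not** emulate: coverage biases and restriction
-fragment structure (no matrix balancing is needed or performed),
over-dispersion beyond Poisson, trans-contact distance structure,
nested/fragmented TEs, or genes with introns. Passing tests therefore
demonstrate that the statistics do what they claim on data with known
structure — not that real Hi-C, with its biases, would give the same
power at the same fold.

## Calibration, in numbers

The suite and `scripts/acceptance.R` recompute these from scratch; the
problem sizes are chosen so every check runs in seconds to a couple of
minutes:

* **Null behaviour**: 200 replicates with $f = 1$ (3 chromosomes × 100
  bins) — the mean false-discovery proportion among called bins at
  $\alpha = 0.05$ stays well under 0.07, and fewer than 10% of
  replicates call anything at all. The self-normalization (z-scores
  estimated from the same 100 bins they are applied to) makes the
  screen conservative relative to nominal BH.
* **Power**: the planted fold-6 contact over background 5 with a 12-bin
  viewpoint is recovered at $q < 0.05$ in ≥ 90% of 50 replicates (in
  practice all of them; the planted bin's z is ~6).
* **Compartments**: PC1 sign recovers the planted checkerboard labels
  (up to global sign) at ≥ 95% agreement across 5 replicates at 100 kb.
* **Exactness**: BH equals brute-force enumeration; tail p-values match
  an erfc-based oracle to 1e-9; coverage fractions equal a per-base
  boolean oracle bit for bit.

## Reproducibility

Every random draw flows from one integer seed (`withr::with_seed`
around each generator call), and `run_demo()` run twice with the same
seed produces byte-identical output files — this is asserted in the
tests, not just promised.

## Known limitations

* The statistic inherits the normal-tail approximation; at very sparse
  backgrounds ($\lambda_{bg} \ll 1$) the discreteness of counts would
  make the log2/z machinery unreliable, and the zero-removal step would
  discard most of the chromosome.
* The map container is resolution-fixed; cross-resolution queries mean
  re-reading the contact file at the other resolution.
* Whether input intensities are raw or balanced counts is the caller's
  choice; the statistic operates on whatever the map carries. Balanced
  values are preferable when available.
* The BGC caller takes family labels as input truth; it does not infer
  homology.
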