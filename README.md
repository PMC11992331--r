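# hicbgc

Plant biosynthetic gene clusters (BGCs) — three or more non-homologous
genes of one biosynthetic pathway in close genomic proximity — sometimes
have functionally related genes elsewhere in the genome, such as a tandem
array of near-identical copies on another chromosome. Hi-C contact data
collected for genome scaffolding can be reused to ask whether such
dispersed loci are spatially associated in the nucleus. `hicbgc`
implements that screen for R users working from binned Hi-C contact maps
and genome annotation: it finds the interchromosomal partners of a
viewpoint region, tests a specific candidate partner, characterises the
chromatin context (A/B compartment PC1, transposable-element density),
and calls the BGCs and tandem arrays themselves from family-labelled gene
models.

## The statistic

For a viewpoint region *V* (a set of bins at resolution *r*, default
50 kb) and each bin *b* of a target chromosome, the interaction intensity
is the mean contact count

&nbsp;&nbsp;&nbsp;&nbsp;x(b) = mean over v in V of M(v, b).

Per chromosome, zero-intensity bins are removed, the remainder is
log2-transformed, and z-scores are computed across the chromosome with
the sample standard deviation:

&nbsp;&nbsp;&nbsp;&nbsp;z(b) = (log2 x(b) − mean) / sd.

Upper-tail p-values come from the standard normal, p = 1 − Φ(z), and are
Benjamini–Hochberg corrected within each chromosome; bins with q < α
(default 0.05) are called significant. A targeted test for one candidate
region compares the mean of its bins' log2 intensities against the same
chromosome-wide distribution, with no multiple-test correction.

Supporting analyses: A/B compartment PC1 is the leading eigenvector of
the Pearson correlation matrix of the distance-normalised (observed /
expected) intrachromosomal map; TE enrichment is exact base-coverage
interval arithmetic of a class-labelled BED track in a region versus a
background, with an optional placement-permutation test; BGC calling
chains pathway-family genes whose gaps are at most `max_gap` (default
400 kb) and keeps chains with ≥ 3 distinct families; tandem-array calling
finds maximal same-family runs (≥ 2 members, gaps ≤ 100 kb) not broken by
another pathway gene.

A synthetic-data generator (`synthetic_truth()`,
`simulate_contact_map()`, `simulate_genome_annotations()`) plants all of
these structures — power-law distance decay, TAD blocks, checkerboard
compartments, Poisson interchromosomal background, one enriched
viewpoint↔target contact, a BGC with a member 346 kb downstream, a
three-copy tandem array, elevated LTR density — with a recorded truth
object, so the whole pipeline is testable end to end without external
data.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data (about a minute in total):

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_screen.R
Rscript analysis/03_compartments.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_clusters.R
```

Stage 2 prints:

```
screen: 1/90 interchromosomal bins significant at q < 0.05
 chrom   start     end raw_mean        z            q
  chr2 1500000 1550000    27.75 5.907135 8.702723e-08
targeted test on the array bin: z = 5.907, P = 1.74e-09 (greater than the chromosome average)
```

The one significant bin is exactly the planted target: the 50-kb bin on
chr2 holding the PR tandem array, whose contact with the BGC viewpoint
was simulated at 6-fold the interchromosomal background of 5 counts per
bin pair. The targeted test recovers the same bin with P well below the
0.05 threshold. Stage 3 reports a mean |PC1| ratio of 0.33 inside versus
outside the cluster span (the planted compartment-neutral block), stage 4
reports LTR coverage of 78% over the array bin versus 60% genome-wide
(the planted densities), and stage 5 calls exactly one BGC (families
LS/IPR/L3OH/ISPD; the ISPD member, 346 kb downstream, drops out when
`max_gap` is tightened to 300 kb) and one 3 × PR tandem array.

The same end-to-end run is available in one call as `run_demo(seed = 1,
outdir = "...")`, which writes every table plus a JSON summary and is
byte-reproducible given the seed.

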