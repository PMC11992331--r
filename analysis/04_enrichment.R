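#!/usr/bin/env Rscript
# Stage 4: LTR base-coverage enrichment of the array bin and the BGC core
# against the genome-wide background, with a permutation p-value for the
# array region. Writes results/enrichment.tsv.

suppressPackageStartupMessages(library(hicbgc))

sizes <- read_chrom_sizes("results/data/chrom.sizes")
truth <- read_truth("results/data/truth.json")
te <- read_bed("results/data/te.bed")

regions <- list(array = truth$array_region, bgc_core = truth$bgc_core)
rows <- lapply(names(regions), function(nm) {
  tab <- enrichment_table(te, regions[[nm]], sizes,
                          classes = c("LTR", "LTR/Gypsy"))
  tab$region <- nm
  tab
})
tab <- do.call(rbind, rows)
write_tsv(tab[, c("region", "class", "region_fraction",
                  "background_fraction", "ratio")],
          "results/enrichment.tsv")

for (k in seq_len(nrow(tab))) {
  cat(sprintf("%-8s %-12s %5.1f%% vs %5.1f%% genome-wide (x%.2f)\n",
              tab$region[k], tab$class[k], 100 * tab$region_fraction[k],
              100 * tab$background_fraction[k], tab$ratio[k]))
}

p <- permutation_test(te, "LTR", truth$array_region, sizes,
                      n_perm = 1000, seed = truth$seed)
cat(sprintf("permutation test, LTR coverage of the array bin: p = %.4g (1000 placements)\n",
            p))
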