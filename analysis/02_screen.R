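#!/usr/bin/env Rscript
# Stage 2: interchromosomal viewpoint screen from the BGC core, plus the
# targeted test on the planted array bin. Reads stage-1 outputs; writes
# results/screen.tsv and results/targeted_test.tsv.

suppressPackageStartupMessages(library(hicbgc))

sizes <- read_chrom_sizes("results/data/chrom.sizes")
truth <- read_truth("results/data/truth.json")
map <- read_contacts("results/data/contacts_50kb.bedpe", sizes, 50000)

viewpoint <- truth$bgc_core
sc <- screen_genome(map, viewpoint, alpha = 0.05)
write_tsv(sc$table, "results/screen.tsv")

sig <- sc$table[sc$table$significant, ]
cat(sprintf("screen: %d/%d interchromosomal bins significant at q < 0.05\n",
            nrow(sig), sum(!is.na(sc$table$q))))
if (nrow(sig)) {
  print(sig[, c("chrom", "start", "end", "raw_mean", "z", "q")],
        row.names = FALSE)
}

tt <- targeted_test(map, viewpoint, truth$array_region)
write_tsv(data.frame(chrom = truth$array_region$chrom,
                     start = truth$array_region$start,
                     end = truth$array_region$end,
                     raw_mean = tt$raw_mean, statistic = tt$statistic,
                     z = tt$z, p = tt$p),
          "results/targeted_test.tsv")
cat(sprintf("targeted test on the array bin: z = %.3f, P = %.3g %s\n",
            tt$z, tt$p,
            if (tt$p < 0.05) "(greater than the chromosome average)" else ""))
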