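#!/usr/bin/env Rscript
# Stage 3: A/B compartment PC1 on the BGC chromosome at 100 kb, and the
# in-region versus outside comparison of |PC1| over the full cluster
# span. Writes results/compartments.tsv.

suppressPackageStartupMessages(library(hicbgc))

sizes <- read_chrom_sizes("results/data/chrom.sizes")
truth <- read_truth("results/data/truth_100kb.json")
map <- read_contacts("results/data/contacts_100kb.bedpe", sizes, 100000)
genes <- read_genes_gff3("results/data/genes.gff3")

ct <- compartment_track(map, truth$bgc_chrom, genes = genes)
write_tsv(ct, "results/compartments.tsv")

span <- genomic_interval(truth$bgc_chrom, truth$bgc_core$start,
                         truth$bgc_core$end + truth$ispd_gap +
                           truth$gene_length)
s <- region_pc1_summary(ct, span)
cat(sprintf("PC1 on %s: %d bins (%d A, %d B, %d masked)\n",
            truth$bgc_chrom, nrow(ct), sum(ct$label == "A"),
            sum(ct$label == "B"), sum(ct$label == "masked")))
cat(sprintf("mean |PC1| over the cluster span %.4f vs %.4f outside (ratio %.3f)\n",
            s$inside, s$outside, s$ratio))
cat(if (s$ratio < 1)
  "the cluster span shows consistently lower |PC1| than the rest of the chromosome\n"
  else "no depressed-|PC1| signature over the cluster span\n")
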