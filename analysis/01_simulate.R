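#!/usr/bin/env Rscript
# Stage 1: simulate the study system with planted ground truth.
#
# Writes, under results/data/: a 50-kb binned contact map for the
# interaction screen, a 100-kb map for compartment analysis, gene models
# (GFF3), the LTR annotation track (BED), chromosome sizes, and the truth
# JSON recording everything that was planted.

suppressPackageStartupMessages(library(hicbgc))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2] else 1)

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

truth <- synthetic_truth(seed = seed)
sizes <- unlist(truth$chrom_sizes)

map50 <- simulate_contact_map(truth)
write_contacts(map50, file.path(outdir, "contacts_50kb.bedpe"))
truth100 <- synthetic_truth(seed = seed, resolution = 100000)
write_contacts(simulate_contact_map(truth100),
               file.path(outdir, "contacts_100kb.bedpe"))

ann <- simulate_genome_annotations(truth)
write_genes_gff3(ann$genes, file.path(outdir, "genes.gff3"))
write_bed(ann$te, file.path(outdir, "te.bed"))
writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)),
           file.path(outdir, "chrom.sizes"))
write_truth(truth, file.path(outdir, "truth.json"))
write_truth(truth100, file.path(outdir, "truth_100kb.json"))

cat(sprintf("seed %d: simulated %d chromosomes (%.1f Mb total)\n",
            seed, length(sizes), sum(sizes) / 1e6))
cat(sprintf("  planted contact: %s:%d-%d <-> %s:%d-%d, fold %g over background %g\n",
            truth$bgc_core$chrom, truth$bgc_core$start, truth$bgc_core$end,
            truth$array_region$chrom, truth$array_region$start,
            truth$array_region$end, truth$planted_contacts[[1]]$fold,
            truth$inter_background))
cat(sprintf("  genes: %d (%d pathway), TEs: %d intervals\n",
            nrow(ann$genes), sum(ann$genes$family != "other"), nrow(ann$te)))
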