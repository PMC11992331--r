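# End-to-end driver: simulate -> screen -> targeted test -> compartments
# -> TE enrichment -> cluster calls, with every output written as
# plain-text tables plus a JSON summary. All randomness flows from one
# seed, so two runs with the same seed are byte-identical.

.config_defaults <- function() {
  list(resolution = 50000, alpha = 0.05, max_gap = 400000,
       array_max_gap = 100000, seed = 1L, scope = "interchromosomal",
       viewpoint = NA_character_, candidate = NA_character_,
       contacts = NA_character_, chrom_sizes = NA_character_,
       genes = NA_character_, te_bed = NA_character_,
       outdir = NA_character_)
}

#' Read a flat key=value pipeline configuration
#'
#' One `key = value` pair per line, '#' comments allowed. Unknown keys
#' are rejected; missing keys take package defaults. Numeric fields are
#' type-checked and `alpha` must lie in (0, 1).
#'
#' @param path config file path.
#' @return named list of resolved parameters.
#' @export
read_pipeline_config <- function(path) {
  defaults <- .config_defaults()
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- defaults
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1]]
    .assert(length(kv) == 3, "malformed config line: '%s'", ln)
    key <- kv[2]; val <- trimws(kv[3])
    .assert(key %in% names(defaults), "unknown config key '%s'", key)
    if (is.numeric(defaults[[key]])) {
      num <- suppressWarnings(as.numeric(val))
      .assert(is.finite(num), "config key '%s' must be numeric", key)
      cfg[[key]] <- num
    } else {
      cfg[[key]] <- val
    }
  }
  .assert(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  .assert(cfg$resolution > 0, "resolution must be positive")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Echo a resolved configuration as key=value lines
#'
#' Unset (NA) keys are omitted; they refill from defaults on re-read, so
#' the echoed file parses back to the same resolved configuration.
#' @param cfg list from [read_pipeline_config()].
#' @param path output path.
#' @export
write_pipeline_config <- function(cfg, path) {
  set <- !vapply(cfg, function(v) length(v) == 1 && is.na(v), TRUE)
  writeLines(sprintf("%s = %s", names(cfg)[set],
                     vapply(cfg[set], function(v)
                       format(v, scientific = FALSE), "")),
             path)
  invisible(path)
}

#' Run the full synthetic demonstration pipeline
#'
#' Simulates a genome with planted truth, writes the raw inputs
#' (contacts, genes, TE track, truth), then runs every analysis stage:
#' the interchromosomal viewpoint screen from the BGC core, the targeted
#' test on the planted array bin, compartment PC1 on the BGC chromosome,
#' TE enrichment of the array region versus the genome, and BGC /
#' tandem-array calling. Writes all tables under `outdir` plus a
#' `summary.json`.
#'
#' @param seed integer seed driving every random draw.
#' @param outdir output directory (created if needed).
#' @param truth optional [synthetic_truth()]; default built from `seed`.
#' @param alpha FDR threshold for the screen.
#' @return (invisibly) the summary list: `planted_bin_recovered`,
#'   `targeted_p`, `bgc_calls`, `array_calls`, plus supporting numbers.
#' @export
run_demo <- function(seed = 1L, outdir = tempfile("hicbgc_demo"),
                     truth = synthetic_truth(seed = seed), alpha = 0.05) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sizes <- validate_chrom_sizes(unlist(truth$chrom_sizes))

  map <- simulate_contact_map(truth)
  ann <- simulate_genome_annotations(truth)
  write_contacts(map, file.path(outdir, "contacts.bedpe"))
  write_genes_gff3(ann$genes, file.path(outdir, "genes.gff3"))
  write_bed(ann$te, file.path(outdir, "te.bed"))
  write_truth(truth, file.path(outdir, "truth.json"))
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)),
             file.path(outdir, "chrom.sizes"))

  viewpoint <- truth$bgc_core
  screen <- screen_genome(map, viewpoint, alpha = alpha)
  write_tsv(screen$table, file.path(outdir, "screen.tsv"))

  target <- truth$array_region
  tt <- targeted_test(map, viewpoint, target)
  write_tsv(data.frame(chrom = target$chrom, start = target$start,
                       end = target$end, raw_mean = tt$raw_mean,
                       statistic = tt$statistic, z = tt$z, p = tt$p),
            file.path(outdir, "targeted_test.tsv"))

  comp <- compartment_track(map, truth$bgc_chrom, genes = ann$genes)
  write_tsv(comp, file.path(outdir, "compartments.tsv"))
  pc_summary <- region_pc1_summary(
    comp, genomic_interval(truth$bgc_chrom, truth$bgc_core$start,
                           truth$bgc_core$end + truth$ispd_gap +
                             truth$gene_length))

  enrich <- enrichment_table(ann$te, truth$array_region, sizes,
                             classes = c("LTR", "LTR/Gypsy"))
  write_tsv(enrich, file.path(outdir, "enrichment.tsv"))

  bgc <- annotate_calls(call_bgcs(ann$genes,
                                  c("LS", "IPR", "L3OH", "ISPD", "PR")),
                        ann$te)
  arrays <- annotate_calls(call_tandem_arrays(ann$genes), ann$te)
  write_tsv(rbind(bgc, arrays), file.path(outdir, "clusters.tsv"))

  tbins <- region_to_bins(target, map$resolution, sizes)
  hit <- screen$table$chrom == target$chrom & screen$table$bin %in% tbins
  summary <- list(
    seed = as.integer(seed),
    planted_bin_recovered = any(screen$table$significant[hit]),
    planted_bin_max_z = max(screen$table$z[hit], na.rm = TRUE),
    n_significant_bins = sum(screen$table$significant),
    targeted_p = tt$p,
    pc1_in_out_ratio = pc_summary$ratio,
    array_ltr_fraction = enrich$region_fraction[enrich$class == "LTR"],
    genome_ltr_fraction = enrich$background_fraction[enrich$class == "LTR"],
    bgc_calls = nrow(bgc),
    array_calls = sum(arrays$n_members >= 2 & arrays$n_families == 1))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
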