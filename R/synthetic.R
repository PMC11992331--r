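# Synthetic genome + Hi-C generator with planted, recorded ground truth.
#
# The generator emulates the structures the screen is designed to find:
# power-law distance decay with TAD blocks and checkerboard compartments
# within chromosomes, a flat Poisson background between chromosomes, one
# planted viewpoint<->target contact enrichment, a BGC-like gene
# arrangement (duplicated pathway genes plus one member 346 kb downstream),
# a three-copy tandem array on another chromosome, and elevated LTR
# density over both regions.

#' Default synthetic chromosome sizes
#'
#' Three chromosomes at desk scale; the BGC lives on "chr8" and the tandem
#' array on "chr2", mirroring the real genome's naming.
#' @return named numeric vector of lengths in bp.
#' @export
default_chrom_sizes <- function() {
  c(chr1 = 2e6, chr2 = 2.5e6, chr8 = 3e6)
}

#' Construct the planted ground truth for a synthetic dataset
#'
#' All downstream defaults are derived from the geometry reported for the
#' real cluster, rescaled to a small genome: a 600-kb BGC core (two copies
#' each of LS, IPR and L3OH), an ISPD gene whose start sits exactly 346 kb
#' after the core span's end, a three-copy PR tandem array on another
#' chromosome inside one 50-kb bin, and a planted interchromosomal contact
#' between the core (the viewpoint) and the array bin.
#'
#' @param seed integer seed; the same seed reproduces every output bitwise.
#' @param chrom_sizes named length vector; must contain `bgc_chrom` and
#'   `array_chrom`.
#' @param resolution bin width in bp for the simulated contact map (and the
#'   grid on which compartment labels are defined).
#' @param decay_exponent,decay_scale intrachromosomal power-law
#'   `lambda = decay_scale * d^-decay_exponent` at bin distance d >= 1; the
#'   diagonal uses the d = 1 rate times a fixed boost of 2.
#' @param inter_background Poisson mean for interchromosomal bin pairs.
#' @param planted_fold fold enrichment of the planted viewpoint-target
#'   contact over `inter_background` (1 = no planted signal).
#' @param tad_multiplier,compartment_multiplier multiplicative boosts for
#'   bin pairs inside the same TAD block / with agreeing compartment labels.
#' @param compartment_block_bins checkerboard block width, in bins.
#' @param bgc_chrom,array_chrom chromosomes carrying the BGC and the array.
#' @param core_start 0-based start of the BGC core span.
#' @param core_span width of the BGC core (the default viewpoint region).
#' @param ispd_gap distance from the core span's end to the ISPD start.
#' @param array_start 0-based start of the 50-kb array bin.
#' @param te_targets named fractions of LTR base coverage to plant: `bgc`
#'   and `array` over their regions, `genome` genome-wide.
#' @return a `synthetic_truth` list recording every planted parameter.
#' @export
synthetic_truth <- function(seed = 1L,
                            chrom_sizes = default_chrom_sizes(),
                            resolution = 50000,
                            decay_exponent = 1,
                            decay_scale = 100,
                            inter_background = 5,
                            planted_fold = 6,
                            tad_multiplier = 2,
                            compartment_multiplier = 3,
                            compartment_block_bins = 5,
                            bgc_chrom = "chr8",
                            array_chrom = "chr2",
                            core_start = 1000000,
                            core_span = 600000,
                            ispd_gap = 346000,
                            array_start = 1500000,
                            te_targets = c(bgc = 0.70, array = 0.78, genome = 0.60)) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  .assert(all(c(bgc_chrom, array_chrom) %in% names(chrom_sizes)),
          "bgc/array chromosome missing from chrom_sizes")
  .assert(decay_exponent > 0 && decay_scale > 0 && inter_background > 0,
          "decay and background parameters must be positive")
  .assert(planted_fold >= 1 && tad_multiplier >= 1 && compartment_multiplier >= 1,
          "multipliers must be >= 1")
  .assert(all(te_targets >= 0 & te_targets <= 1) &&
            all(c("bgc", "array", "genome") %in% names(te_targets)),
          "te_targets must name bgc, array, genome fractions in [0,1]")

  gene_len <- 4000
  core_end <- core_start + core_span
  ispd_start <- core_end + ispd_gap
  .assert(ispd_start + gene_len <= chrom_sizes[[bgc_chrom]],
          "BGC geometry exceeds %s", bgc_chrom)
  array_region <- list(chrom = array_chrom, start = array_start,
                       end = array_start + resolution)
  .assert(array_region$end <= chrom_sizes[[array_chrom]],
          "array region exceeds %s", array_chrom)
  bgc_core <- list(chrom = bgc_chrom, start = core_start, end = core_end)

  tad_blocks <- list(
    list(chrom = names(chrom_sizes)[1], start = 400000, end = 800000,
         multiplier = tad_multiplier),
    list(chrom = array_chrom, start = 500000, end = 900000,
         multiplier = tad_multiplier),
    list(chrom = bgc_chrom, start = core_start + 200000, end = core_end,
         multiplier = tad_multiplier))
  tad_blocks <- Filter(function(b) b$end <= chrom_sizes[[b$chrom]], tad_blocks)

  # checkerboard +1/-1 in fixed-width blocks; bins over the full BGC span
  # (core through ISPD) are compartment-neutral (label 0) so the region
  # shows the planted low-|PC1| signature
  labels <- lapply(names(chrom_sizes), function(cn) {
    nb <- as.integer(ceiling(chrom_sizes[[cn]] / resolution))
    lab <- ifelse((seq_len(nb) - 1) %/% compartment_block_bins %% 2 == 0, 1L, -1L)
    if (cn == bgc_chrom) {
      neutral <- region_to_bins(list(chrom = cn, start = core_start,
                                     end = ispd_start + gene_len), resolution)
      lab[neutral + 1L] <- 0L
    }
    lab
  })
  names(labels) <- names(chrom_sizes)

  truth <- list(
    seed = as.integer(seed),
    chrom_sizes = as.list(chrom_sizes),
    resolution = resolution,
    decay_exponent = decay_exponent,
    decay_scale = decay_scale,
    inter_background = inter_background,
    tad_blocks = tad_blocks,
    compartment_multiplier = compartment_multiplier,
    compartment_labels = labels,
    planted_contacts = list(list(viewpoint = bgc_core, target = array_region,
                                 fold = planted_fold)),
    bgc_chrom = bgc_chrom,
    array_chrom = array_chrom,
    bgc_core = bgc_core,
    ispd_gap = ispd_gap,
    gene_length = gene_len,
    array_region = array_region,
    te_targets = as.list(te_targets))
  class(truth) <- "synthetic_truth"
  truth
}

#' Simulate a binned Hi-C contact map from planted truth
#'
#' Entry (i, j) is Poisson with rate `A * d^-alpha * m_T * m_C` within a
#' chromosome (bin distance d >= 1; the diagonal uses the d = 1 rate times
#' 2) and `lambda_bg * f` between chromosomes, where f is the planted fold
#' inside a planted viewpoint-target pair and 1 elsewhere. Deterministic
#' given `truth$seed`.
#'
#' @param truth a [synthetic_truth()].
#' @param chrom_sizes,resolution usually taken from `truth`.
#' @return a [contact_map()].
#' @export
simulate_contact_map <- function(truth,
                                 chrom_sizes = unlist(truth$chrom_sizes),
                                 resolution = truth$resolution) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  .assert(resolution <= min(chrom_sizes),
          "resolution larger than smallest chromosome")
  chroms <- names(chrom_sizes)
  nb <- vapply(chroms, function(cn) n_bins(chrom_sizes, cn, resolution), 1L)
  labels <- truth$compartment_labels
  .assert(all(vapply(chroms, function(cn)
    length(labels[[cn]]) == nb[[cn]], TRUE)),
    "compartment labels do not match the binning grid")

  planted <- lapply(truth$planted_contacts, function(pc) {
    list(vc = pc$viewpoint$chrom,
         vb = region_to_bins(pc$viewpoint, resolution, chrom_sizes),
         tc = pc$target$chrom,
         tb = region_to_bins(pc$target, resolution, chrom_sizes),
         fold = pc$fold)
  })

  withr::with_seed(truth$seed, {
    parts <- list()
    for (ci in seq_along(chroms)) {
      cn <- chroms[ci]
      n <- nb[[cn]]
      idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
      i <- idx[, 1] - 1L; j <- idx[, 2] - 1L
      d <- j - i
      lam <- truth$decay_scale * pmax(d, 1)^(-truth$decay_exponent)
      lam[d == 0] <- 2 * truth$decay_scale
      for (b in truth$tad_blocks) {
        if (b$chrom != cn) next
        tb <- region_to_bins(b, resolution, chrom_sizes)
        inb <- i %in% tb & j %in% tb
        lam[inb] <- lam[inb] * b$multiplier
      }
      lab <- labels[[cn]]
      agree <- lab[i + 1L] == lab[j + 1L] & lab[i + 1L] != 0L
      lam[agree] <- lam[agree] * truth$compartment_multiplier
      v <- rpois(length(lam), lam)
      keep <- v > 0
      parts[[length(parts) + 1L]] <-
        data.frame(chrom1 = cn, bin1 = i[keep], chrom2 = cn, bin2 = j[keep],
                   value = as.numeric(v[keep]))
      for (cj in seq_along(chroms)) {
        if (cj <= ci) next
        cm <- chroms[cj]
        m <- nb[[cm]]
        gi <- rep(seq_len(n) - 1L, times = m)
        gj <- rep(seq_len(m) - 1L, each = n)
        lam2 <- rep(truth$inter_background, n * m)
        for (pc in planted) {
          hit <- if (pc$vc == cn && pc$tc == cm) {
            gi %in% pc$vb & gj %in% pc$tb
          } else if (pc$vc == cm && pc$tc == cn) {
            gj %in% pc$vb & gi %in% pc$tb
          } else logical(n * m)
          lam2[hit] <- lam2[hit] * pc$fold
        }
        v2 <- rpois(length(lam2), lam2)
        keep2 <- v2 > 0
        parts[[length(parts) + 1L]] <-
          data.frame(chrom1 = cn, bin1 = gi[keep2], chrom2 = cm,
                     bin2 = gj[keep2], value = as.numeric(v2[keep2]))
      }
    }
    contact_map(chrom_sizes, resolution, do.call(rbind, parts))
  })
}

# Fill `region` with sampled intervals until covered bases reach
# target_fraction * width; the last interval is trimmed so the realized
# coverage lands on the target (within 1 bp).
.fill_region_with_tes <- function(region, target_fraction, classes) {
  width <- region$end - region$start
  target <- round(target_fraction * width)
  if (target <= 0 || width < 2) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      class = character()))
  }
  starts <- numeric(); ends <- numeric()
  covered <- 0
  guard <- 0L
  while (covered < target && guard < 100000L) {
    guard <- guard + 1L
    len <- round(runif(1, 1000, 10000))
    len <- min(len, width)
    s <- region$start + floor(runif(1, 0, width - len + 1))
    e <- s + len
    starts <- c(starts, s); ends <- c(ends, e)
    covered <- .covered_bases(starts, ends)
    while (covered > target && ends[length(ends)] - starts[length(starts)] > 1) {
      ends[length(ends)] <- max(starts[length(starts)] + 1,
                                ends[length(ends)] - (covered - target))
      covered <- .covered_bases(starts, ends)
    }
  }
  data.frame(chrom = region$chrom, start = starts, end = ends,
             class = rep_len(classes, length(starts)))
}

.covered_bases <- function(starts, ends) {
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1, end = ends))
  sum(IRanges::width(ir))
}

#' Simulate gene models and a TE annotation track from planted truth
#'
#' Emits the BGC core (LS x2, IPR x2, L3OH x2 spread over the core span),
#' an ISPD gene starting exactly `truth$ispd_gap` bp after the core span's
#' end, a three-member PR tandem array inside the planted target bin,
#' filler genes of family "other", and LTR intervals whose realized base
#' coverage matches the planted targets: `bgc` over the core, `array` over
#' the array bin, and `genome` genome-wide (the unlabelled remainder is
#' filled at the rate that makes the genome-wide fraction come out at its
#' target).
#'
#' @param truth a [synthetic_truth()].
#' @return `list(genes = <gene records>, te = <annotation track>)`.
#' @export
simulate_genome_annotations <- function(truth) {
  sizes <- validate_chrom_sizes(unlist(truth$chrom_sizes))
  core <- truth$bgc_core
  gl <- truth$gene_length
  span <- core$end - core$start
  .assert(span >= 6 * gl, "BGC core span too small for six genes")
  # duplicated families interleaved (LS/IPR/L3OH twice over) so no two
  # copies of one family form a same-family run of their own
  offs <- round(span * c(0, 0.05, 0.35, 0.55, 0.60, 1)) # last gene ends at span end
  starts <- core$start + c(offs[1:5], offs[6] - gl)
  fam <- c("LS", "IPR", "L3OH", "LS", "IPR", "L3OH")
  ids <- c("LS1", "IPRv1", "L3OHv1", "LS2", "IPRv2", "L3OHv2")
  strands <- c("+", "-", "+", "-", "+", "+")
  genes <- data.frame(id = ids, chrom = core$chrom, start = starts,
                      end = starts + gl, strand = strands, family = fam)
  ispd_start <- core$end + truth$ispd_gap
  genes <- rbind(genes, data.frame(
    id = "ISPD", chrom = core$chrom, start = ispd_start,
    end = ispd_start + gl, strand = "+", family = "ISPD"))

  ar <- truth$array_region
  pr_len <- 2000
  pr_starts <- ar$start + c(0, 20000, 40000)
  .assert(max(pr_starts) + pr_len <= ar$end, "array bin too small for PR genes")
  genes <- rbind(genes, data.frame(
    id = c("PR1", "PR2", "PR3"), chrom = ar$chrom, start = pr_starts,
    end = pr_starts + pr_len, strand = "+", family = "PR"))

  # deterministic filler genes every 200 kb, skipping pathway-gene overlap
  for (cn in names(sizes)) {
    fs <- seq(100000, sizes[[cn]] - 2000, by = 200000)
    keep <- vapply(fs, function(s) {
      g <- genes[genes$chrom == cn, , drop = FALSE]
      !any(s < g$end & s + 2000 > g$start)
    }, TRUE)
    fs <- fs[keep]
    if (length(fs)) {
      genes <- rbind(genes, data.frame(
        id = sprintf("%s_f%02d", cn, seq_along(fs)), chrom = cn, start = fs,
        end = fs + 2000, strand = ".", family = "other"))
    }
  }
  genes <- genes[order(match(genes$chrom, names(sizes)), genes$start), ]
  rownames(genes) <- NULL

  tt <- truth$te_targets
  labelled <- list(
    bgc = list(region = core, target = tt$bgc,
               classes = c("LTR/Gypsy/Athila", "LTR/Gypsy", "LTR/Copia")),
    array = list(region = truth$array_region, target = tt$array,
                 classes = c("LTR/Gypsy", "LTR/Gypsy/Athila")))
  lab_w <- sum(vapply(labelled, function(x) x$region$end - x$region$start, 1))
  lab_cov <- sum(vapply(labelled, function(x)
    (x$region$end - x$region$start) * x$target, 1))
  total_w <- sum(sizes)
  bg_target <- (tt$genome * total_w - lab_cov) / (total_w - lab_w)
  .assert(bg_target >= 0 && bg_target <= 1,
          "genome-wide TE target unreachable given region targets")

  te <- withr::with_seed(truth$seed, {
    parts <- lapply(labelled, function(x)
      .fill_region_with_tes(x$region, x$target, x$classes))
    bg_classes <- c("LTR/Copia/SIRE", "LTR/Gypsy", "LTR/Copia")
    for (cn in names(sizes)) {
      bounds <- sort(unlist(lapply(labelled, function(x)
        if (x$region$chrom == cn) c(x$region$start, x$region$end))))
      cuts <- c(0, bounds, sizes[[cn]])
      for (k in seq(1, length(cuts) - 1, by = 2)) {
        seg <- list(chrom = cn, start = cuts[k], end = cuts[k + 1])
        if (seg$end > seg$start) {
          parts[[length(parts) + 1L]] <-
            .fill_region_with_tes(seg, bg_target, bg_classes)
        }
      }
    }
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
  })
  te <- te[order(match(te$chrom, names(sizes)), te$start), ]
  rownames(te) <- NULL
  list(genes = genes, te = te)
}

.truth_fields <- c(
  "seed", "chrom_sizes", "resolution", "decay_exponent", "decay_scale",
  "inter_background", "tad_blocks", "compartment_multiplier",
  "compartment_labels", "planted_contacts", "bgc_chrom", "array_chrom",
  "bgc_core", "ispd_gap", "gene_length", "array_region", "te_targets")

#' Write planted truth as JSON
#' @param truth a [synthetic_truth()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read planted truth back from JSON
#'
#' Unknown fields are rejected; the round trip through [write_truth()] is
#' lossless.
#' @param path JSON path.
#' @return a `synthetic_truth`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  extra <- setdiff(names(x), .truth_fields)
  .assert(length(extra) == 0, "unknown truth field: %s",
          paste(extra, collapse = ", "))
  missing <- setdiff(.truth_fields, names(x))
  .assert(length(missing) == 0, "missing truth field: %s",
          paste(missing, collapse = ", "))
  x <- x[.truth_fields]
  x$seed <- as.integer(x$seed)
  x$compartment_labels <- lapply(x$compartment_labels, as.integer)
  class(x) <- "synthetic_truth"
  x
}
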