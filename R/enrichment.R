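# Base-coverage enrichment of annotation classes in a region versus a
# background, with exact interval arithmetic and an optional permutation
# significance test.

.to_iranges <- function(starts, ends) {
  IRanges::IRanges(start = starts + 1, end = ends)
}

#' Merge intervals into a disjoint sorted union
#'
#' Overlapping and adjacent intervals merge (half-open convention:
#' \[10,20) + \[20,30) are contiguous); covered bases are preserved.
#'
#' @param starts,ends parallel vectors of 0-based half-open bounds on one
#'   chromosome.
#' @return data frame `start, end`, disjoint and sorted.
#' @export
merge_intervals <- function(starts, ends) {
  .assert(length(starts) == length(ends), "starts/ends length mismatch")
  if (length(starts) == 0) return(data.frame(start = numeric(), end = numeric()))
  .assert(all(ends > starts) && all(starts >= 0), "invalid interval")
  ir <- IRanges::reduce(.to_iranges(starts, ends))
  data.frame(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
}

.class_matches <- function(labels, class_prefix) {
  labels == class_prefix | startsWith(labels, paste0(class_prefix, "/"))
}

#' Fraction of a region's bases covered by an annotation class
#'
#' Class matching is by exact label or '/'-delimited hierarchical prefix:
#' "LTR" matches "LTR/Gypsy/Athila" but not "LTRX". The matching
#' intervals are merged before counting, so overlaps are not
#' double-counted.
#'
#' @param track annotation track (`chrom, start, end, class`).
#' @param class_prefix class label or prefix.
#' @param region genomic interval (or "chrom:start-end").
#' @return covered bases / region length, in \[0, 1\].
#' @export
coverage_fraction <- function(track, class_prefix, region) {
  region <- .as_interval(region)
  .assert(region$end > region$start, "zero-length region")
  sel <- track$chrom == region$chrom & .class_matches(track$class, class_prefix)
  if (!any(sel)) return(0)
  merged <- .to_iranges(track$start[sel], track$end[sel])
  hit <- IRanges::intersect(IRanges::reduce(merged),
                            .to_iranges(region$start, region$end))
  sum(IRanges::width(hit)) / (region$end - region$start)
}

.background_fraction <- function(track, class_prefix, background) {
  covered <- 0; total <- 0
  for (bg in background) {
    covered <- covered + coverage_fraction(track, class_prefix, bg) *
      (bg$end - bg$start)
    total <- total + (bg$end - bg$start)
  }
  covered / total
}

#' Region-versus-background enrichment table
#'
#' One row per class: the fraction of region bases covered by the class,
#' the same fraction over the background, and their ratio (NaN when the
#' background fraction is 0).
#'
#' @param track annotation track.
#' @param region genomic interval (or string).
#' @param background either a named chromosome-sizes vector (whole-genome
#'   background) or a list of genomic intervals.
#' @param classes class labels/prefixes to report; default: every
#'   top-level class present in the track plus every full label.
#' @return data frame of enrichment rows: `class, region_fraction,
#'   background_fraction, ratio`.
#' @export
enrichment_table <- function(track, region, background, classes = NULL) {
  region <- .as_interval(region)
  if (!is.null(names(background)) && is.numeric(background)) {
    background <- lapply(names(background), function(cn)
      genomic_interval(cn, 0, background[[cn]]))
  }
  .assert(length(background) > 0, "empty background")
  background <- lapply(background, .as_interval)
  if (is.null(classes)) {
    top <- unique(vapply(strsplit(track$class, "/"), `[[`, "", 1L))
    classes <- unique(c(sort(top), sort(unique(track$class))))
  }
  rows <- lapply(classes, function(cl) {
    rf <- coverage_fraction(track, cl, region)
    bf <- .background_fraction(track, cl, background)
    data.frame(class = cl, region_fraction = rf, background_fraction = bf,
               ratio = if (bf > 0) rf / bf else NaN)
  })
  do.call(rbind, rows)
}

#' Permutation test for region enrichment
#'
#' Places `n_perm` random regions of the same length uniformly over the
#' supplied chromosomes (start positions weighted by the number of valid
#' placements per chromosome) and reports
#' `p = (1 + #{placements with fraction >= observed}) / (n_perm + 1)`.
#' Deterministic given `seed`.
#'
#' @param track annotation track.
#' @param class_prefix class label or prefix.
#' @param region observed genomic interval (or string).
#' @param chrom_sizes named lengths of the chromosomes to permute over.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return permutation p-value.
#' @export
permutation_test <- function(track, class_prefix, region, chrom_sizes,
                             n_perm = 1000, seed = 1) {
  region <- .as_interval(region)
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  .assert(n_perm >= 100, "n_perm must be >= 100")
  len <- region$end - region$start
  slots <- pmax(chrom_sizes - len + 1, 0)
  .assert(any(slots > 0), "region longer than any chromosome")
  observed <- coverage_fraction(track, class_prefix, region)
  withr::with_seed(as.integer(seed), {
    cn <- sample(names(chrom_sizes), n_perm, replace = TRUE,
                 prob = slots / sum(slots))
    hits <- vapply(seq_len(n_perm), function(k) {
      s <- floor(runif(1, 0, slots[[cn[k]]]))
      coverage_fraction(track, class_prefix,
                        genomic_interval(cn[k], s, s + len)) >= observed
    }, TRUE)
    (1 + sum(hits)) / (n_perm + 1)
  })
}
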