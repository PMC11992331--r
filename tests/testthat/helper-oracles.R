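# Independent oracles and small fixture builders used across the suite.

# O(m^2) Benjamini-Hochberg by direct enumeration of the step-up
# definition: q at sorted rank i is min over j >= i of p_(j) * m / j,
# capped at 1, mapped back to input order.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o[i:m]] * m / seq(i, m)))
  }
  q
}

# Upper-tail standard normal probability via the complementary error
# function (independent of pnorm).
normal_tail_oracle <- function(z) {
  0.5 * pracma::erfc(z / sqrt(2))
}

# Per-base boolean-array coverage: fraction of region bases covered by
# any of the (0-based half-open) intervals.
coverage_brute_force <- function(starts, ends, region_start, region_end) {
  covered <- logical(region_end - region_start)
  for (k in seq_along(starts)) {
    lo <- max(starts[k], region_start)
    hi <- min(ends[k], region_end)
    if (hi > lo) covered[(lo - region_start + 1):(hi - region_start)] <- TRUE
  }
  mean(covered)
}

# Contact map from explicit rows (chrom1, bin1, chrom2, bin2, value).
make_map <- function(chrom_sizes, resolution, ...) {
  rows <- list(...)
  entries <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom1 = r[[1]], bin1 = as.integer(r[[2]]),
               chrom2 = r[[3]], bin2 = as.integer(r[[4]]),
               value = as.numeric(r[[5]]))))
  contact_map(chrom_sizes, resolution, entries)
}

# Viewpoint profile object built directly from raw per-bin values.
make_profile <- function(values, in_viewpoint = rep(FALSE, length(values))) {
  structure(list(viewpoint = genomic_interval("chrV", 0, 1),
                 target_chrom = "chrT", resolution = 50000,
                 values = values, in_viewpoint = in_viewpoint),
            class = "viewpoint_profile")
}

# Annotation track data frame from vectors.
make_track <- function(chrom, starts, ends, classes) {
  data.frame(chrom = chrom, start = starts, end = ends, class = classes)
}

# Gene-record row.
gene_row <- function(id, chrom, start, end, family, strand = "+") {
  data.frame(id = id, chrom = chrom, start = start, end = end,
             strand = strand, family = family)
}
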