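# A/B compartment PC1: distance-stratified expected, observed/expected,
# Pearson correlation of O/E columns, leading eigenvector, A/B labels by
# sign.

#' Distance-stratified expected contact value
#'
#' `E(d)` is the mean of all intrachromosomal entries at bin distance d,
#' including implicit zeros. Distances at which every observation is zero
#' get `E = NaN` and are masked downstream.
#'
#' @param map a [contact_map()].
#' @param chrom chromosome name.
#' @return numeric vector of length n (index k = distance k - 1).
#' @export
expected_by_distance <- function(map, chrom) {
  M <- contact_matrix(map, chrom)
  n <- nrow(M)
  .assert(n >= 3, "chromosome '%s' has fewer than 3 bins", chrom)
  vapply(0:(n - 1), function(d) {
    v <- M[cbind(seq_len(n - d), seq_len(n - d) + d)]
    if (all(v == 0)) NaN else mean(v)
  }, 1.0)
}

#' Observed/expected correlation matrix
#'
#' Divides each entry by the expected value at its distance, masks bins
#' with zero total intrachromosomal contact, and returns the Pearson
#' correlation matrix of the O/E columns over unmasked bins.
#'
#' @param map a [contact_map()].
#' @param chrom chromosome name.
#' @return list with `corr` (k x k correlation matrix over unmasked bins)
#'   and `unmasked` (0-based indices of retained bins).
#' @export
oe_correlation <- function(map, chrom) {
  M <- contact_matrix(map, chrom)
  n <- nrow(M)
  E <- expected_by_distance(map, chrom)
  unmasked <- which(rowSums(M) > 0)
  .assert(length(unmasked) >= 4, "too few unmasked bins on '%s'", chrom)
  D <- abs(outer(seq_len(n), seq_len(n), `-`))
  OE <- M / matrix(E[D + 1L], n, n)
  OE <- OE[unmasked, unmasked, drop = FALSE]
  sds <- apply(OE, 2, function(col) sd(col[is.finite(col)]))
  .assert(all(is.finite(sds)) && all(sds > 0),
          "degenerate O/E matrix on '%s' (zero-variance column)", chrom)
  C <- suppressWarnings(cor(OE, use = "pairwise.complete.obs"))
  .assert(all(is.finite(C)), "degenerate O/E correlation on '%s'", chrom)
  list(corr = (C + t(C)) / 2, unmasked = unmasked - 1L)
}

#' Leading eigenvector (PC1) with A/B labels
#'
#' The eigenvector of the largest eigenvalue, unit Euclidean norm. Sign
#' orientation: when per-bin gene counts are supplied, flipped so that the
#' positive-PC1 bins carry the higher gene density (A = gene-rich by
#' convention); otherwise so the first bin's value is non-negative.
#' Labels: A where PC1 > 0, else B.
#'
#' @param correlation square symmetric correlation matrix.
#' @param gene_counts optional per-bin gene counts (same length/order as
#'   the correlation's bins) used to orient the sign.
#' @return list with `pc1` and `label` ("A"/"B").
#' @export
pc1 <- function(correlation, gene_counts = NULL) {
  .assert(is.matrix(correlation) && nrow(correlation) == ncol(correlation),
          "correlation must be a square matrix")
  eg <- eigen(correlation, symmetric = TRUE)
  v <- eg$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  if (!is.null(gene_counts)) {
    .assert(length(gene_counts) == length(v),
            "gene_counts length must match the matrix dimension")
    pos <- v > 0
    dens_pos <- if (any(pos)) mean(gene_counts[pos]) else -Inf
    dens_neg <- if (any(!pos)) mean(gene_counts[!pos]) else -Inf
    if (dens_neg > dens_pos) v <- -v
  } else if (v[1] < 0) {
    v <- -v
  }
  list(pc1 = v, label = ifelse(v > 0, "A", "B"))
}

#' Compute the A/B compartment track for one chromosome
#'
#' Full pipeline: distance expected, observed/expected, correlation,
#' leading eigenvector. Masked bins (zero total contact) carry NA PC1 and
#' label "masked".
#'
#' @param map a [contact_map()].
#' @param chrom chromosome name.
#' @param genes optional gene-record data frame used to orient the PC1
#'   sign by gene density.
#' @return a `compartment_track` data frame: chrom, start, end, pc1,
#'   label.
#' @export
compartment_track <- function(map, chrom, genes = NULL) {
  oc <- oe_correlation(map, chrom)
  gc <- NULL
  if (!is.null(genes)) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    cnt <- tabulate(floor((g$start + g$end) / 2 / map$resolution) + 1L,
                    nbins = n_bins(map, chrom))
    gc <- cnt[oc$unmasked + 1L]
  }
  comp <- pc1(oc$corr, gc)
  nb <- n_bins(map, chrom)
  r <- map$resolution
  pc <- rep(NA_real_, nb); lab <- rep("masked", nb)
  pc[oc$unmasked + 1L] <- comp$pc1
  lab[oc$unmasked + 1L] <- comp$label
  out <- data.frame(chrom = chrom,
                    start = (seq_len(nb) - 1L) * r,
                    end = pmin(seq_len(nb) * r, map$chrom_sizes[[chrom]]),
                    pc1 = pc, label = lab)
  class(out) <- c("compartment_track", class(out))
  out
}

#' Mean |PC1| inside versus outside a region
#'
#' The comparison behind the claim that a region sits in a single
#' chromatin state: a low in/out ratio means the region's PC1 magnitude
#' is consistently smaller than the rest of the chromosome's.
#'
#' @param track a [compartment_track()].
#' @param region genomic interval on the track's chromosome (or string).
#' @return list with `inside`, `outside` (mean |PC1| over unmasked bins)
#'   and `ratio = inside / outside`.
#' @export
region_pc1_summary <- function(track, region) {
  region <- .as_interval(region)
  .assert(all(track$chrom == region$chrom),
          "region chromosome does not match the track")
  inside <- track$start < region$end & track$end > region$start
  ok <- !is.na(track$pc1)
  .assert(any(inside & ok), "region contains no unmasked bin")
  .assert(any(!inside & ok), "no unmasked bins outside the region")
  m_in <- mean(abs(track$pc1[inside & ok]))
  m_out <- mean(abs(track$pc1[!inside & ok]))
  list(inside = m_in, outside = m_out, ratio = m_in / m_out)
}
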