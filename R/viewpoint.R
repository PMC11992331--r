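# Virtual-4C viewpoint screen: per-target-bin mean intensity, then the
# per-chromosome normalization (drop zeros, log2, z-score with sample sd),
# upper-tail normal p-values and Benjamini-Hochberg correction within each
# chromosome, plus the targeted candidate-region test.

#' Extract a viewpoint interaction profile
#'
#' For every bin b of the target chromosome, the profile value is the
#' arithmetic mean of map(v, b) over the viewpoint bins v. When the target
#' chromosome is the viewpoint's own, bins inside the viewpoint are still
#' reported but flagged, and are excluded from all downstream statistics.
#'
#' @param map a [contact_map()].
#' @param viewpoint genomic interval (or "chrom:start-end").
#' @param target_chrom chromosome to profile against.
#' @return a `viewpoint_profile`: list with `values` (one per target bin),
#'   `in_viewpoint` flags, and coordinates.
#' @export
extract_viewpoint_profile <- function(map, viewpoint, target_chrom) {
  viewpoint <- .as_interval(viewpoint, map$chrom_sizes)
  .assert(target_chrom %in% names(map$chrom_sizes),
          "unknown chromosome '%s'", target_chrom)
  vbins <- region_to_bins(viewpoint, map$resolution, map$chrom_sizes)
  .assert(length(vbins) > 0, "viewpoint empty after binning")
  M <- contact_submatrix(map, viewpoint$chrom, vbins, target_chrom)
  values <- colMeans(M)
  nb <- n_bins(map, target_chrom)
  flag <- rep(FALSE, nb)
  if (identical(target_chrom, viewpoint$chrom)) flag[vbins + 1L] <- TRUE
  structure(list(viewpoint = viewpoint, target_chrom = target_chrom,
                 resolution = map$resolution, values = values,
                 in_viewpoint = flag),
            class = "viewpoint_profile")
}

#' Normalize a viewpoint profile
#'
#' The screen's normalization: remove zero-intensity bins (and viewpoint
#' bins), take log2 of what remains, and z-score across the chromosome
#' using the sample standard deviation (denominator n - 1).
#'
#' @param profile a `viewpoint_profile`.
#' @return list with `log2` and `z` (full-length, NA outside kept bins)
#'   and the logical `kept` mask.
#' @export
normalize_profile <- function(profile) {
  x <- profile$values
  kept <- x > 0 & !profile$in_viewpoint
  .assert(sum(kept) >= 2, "degenerate chromosome profile (<2 non-zero bins)")
  lx <- rep(NA_real_, length(x))
  lx[kept] <- log2(x[kept])
  s <- sd(lx[kept])
  .assert(s > 0, "zero variance in chromosome profile")
  z <- (lx - mean(lx[kept])) / s
  list(log2 = lx, z = z, kept = kept)
}

#' Upper-tail normal p-value for a z-score
#'
#' The proportion of a standard normal expected above z: `1 - Phi(z)`.
#' @param z finite numeric vector of z-scores.
#' @return p-values in (0, 1), strictly decreasing in z.
#' @export
tail_pvalue <- function(z) {
  .assert(all(is.finite(z)), "non-finite z-score")
  pnorm(z, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment: q at sorted rank i is
#' `min_{j >= i}(p_(j) * m / j)` capped at 1, mapped back to input order.
#' @param pvalues numeric vector, all in (0, 1].
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  .assert(length(pvalues) >= 1, "empty p-value vector")
  .assert(all(is.finite(pvalues)) && all(pvalues > 0 & pvalues <= 1),
          "p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

.screen_one_chrom <- function(map, viewpoint, chrom, alpha) {
  prof <- extract_viewpoint_profile(map, viewpoint, chrom)
  norm <- normalize_profile(prof)
  r <- map$resolution
  nb <- length(prof$values)
  p <- q <- rep(NA_real_, nb)
  p[norm$kept] <- tail_pvalue(norm$z[norm$kept])
  q[norm$kept] <- bh_adjust(p[norm$kept])
  data.frame(chrom = chrom,
             bin = seq_len(nb) - 1L,
             start = (seq_len(nb) - 1L) * r,
             end = pmin(seq_len(nb) * r, map$chrom_sizes[[chrom]]),
             raw_mean = prof$values,
             log2 = norm$log2,
             z = ifelse(norm$kept, norm$z, NA_real_),
             p = p, q = q,
             in_viewpoint = prof$in_viewpoint,
             significant = !is.na(q) & q < alpha,
             row.names = NULL)
}

#' Genome-wide viewpoint interaction screen
#'
#' Runs the full statistic per chromosome — extract, normalize, upper-tail
#' p — with BH correction applied within each chromosome separately, and
#' calls bins significant at `q < alpha`. Zero-intensity (and viewpoint)
#' bins are reported with NA statistics and `significant = FALSE`.
#' Chromosomes whose profile cannot be normalized (fewer than two non-zero
#' bins, or zero variance) are recorded as skipped, not fatal.
#'
#' @param map a [contact_map()].
#' @param viewpoint genomic interval (or "chrom:start-end").
#' @param alpha FDR threshold (default 0.05).
#' @param scope `"interchromosomal"` (all chromosomes except the
#'   viewpoint's; default) or one chromosome name.
#' @return a `screen_result`: list with `table` (one row per target bin:
#'   chrom, bin, start, end, raw_mean, log2, z, p, q, in_viewpoint,
#'   significant), `alpha`, and `skipped` chromosome names.
#' @export
screen_genome <- function(map, viewpoint, alpha = 0.05,
                          scope = "interchromosomal") {
  viewpoint <- .as_interval(viewpoint, map$chrom_sizes)
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  chroms <- if (identical(scope, "interchromosomal")) {
    setdiff(names(map$chrom_sizes), viewpoint$chrom)
  } else {
    .assert(scope %in% names(map$chrom_sizes),
            "scope must be 'interchromosomal' or a chromosome name")
    scope
  }
  rows <- list(); skipped <- character()
  for (cn in chroms) {
    tab <- tryCatch(.screen_one_chrom(map, viewpoint, cn, alpha),
                    error = function(e) NULL)
    if (is.null(tab)) skipped <- c(skipped, cn) else
      rows[[length(rows) + 1L]] <- tab
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), bin = integer(), start = numeric(),
               end = numeric(), raw_mean = numeric(), log2 = numeric(),
               z = numeric(), p = numeric(), q = numeric(),
               in_viewpoint = logical(), significant = logical())
  structure(list(table = table, alpha = alpha, skipped = skipped,
                 viewpoint = viewpoint),
            class = "screen_result")
}

#' Targeted candidate-region interaction test
#'
#' Tests whether the viewpoint's interaction with a candidate region is
#' greater than the chromosome average: the statistic is the mean of the
#' candidate bins' log2 intensities, z-scored against the mean and sample
#' sd of all kept log2 values on that chromosome, with an upper-tail
#' normal p-value and no multiple-test correction. A single-bin candidate
#' reproduces that bin's screen-level z and p exactly.
#'
#' @param map a [contact_map()].
#' @param viewpoint genomic interval (or "chrom:start-end").
#' @param candidate genomic interval on a single chromosome.
#' @return list with `raw_mean`, `statistic` (mean log2), `z`, `p`, and
#'   `n_bins` used.
#' @export
targeted_test <- function(map, viewpoint, candidate) {
  viewpoint <- .as_interval(viewpoint, map$chrom_sizes)
  candidate <- .as_interval(candidate, map$chrom_sizes)
  prof <- extract_viewpoint_profile(map, viewpoint, candidate$chrom)
  norm <- normalize_profile(prof)
  cbins <- region_to_bins(candidate, map$resolution, map$chrom_sizes)
  ckept <- intersect(cbins, which(norm$kept) - 1L)
  .assert(length(ckept) > 0, "candidate removed by zero filter")
  lx <- norm$log2[norm$kept]
  stat <- mean(norm$log2[ckept + 1L])
  z <- (stat - mean(lx)) / sd(lx)
  list(raw_mean = mean(prof$values[cbins + 1L]),
       statistic = stat, z = z, p = tail_pvalue(z),
       n_bins = length(ckept))
}

#' @export
print.screen_result <- function(x, ...) {
  ns <- sum(x$table$significant)
  cat(sprintf("viewpoint screen: %d target bins on %d chromosomes, %d significant at q < %g\n",
              nrow(x$table), length(unique(x$table$chrom)), ns, x$alpha))
  if (length(x$skipped))
    cat("skipped (degenerate):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
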