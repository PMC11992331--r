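# Binned contact map: sparse symmetric binned Hi-C counts at one resolution.
# Entries are stored once, in canonical orientation (chrom order, then bin),
# so symmetry is structural rather than duplicated.

#' Construct a binned contact map
#'
#' @param chrom_sizes named numeric vector (name = chromosome, value = length
#'   in bp); iteration order is the chromosome order used everywhere.
#' @param resolution bin width in bp.
#' @param entries data frame with columns `chrom1, bin1, chrom2, bin2, value`
#'   (bin index = floor(position / resolution)). Duplicate and mirrored
#'   entries are summed into canonical orientation.
#' @return object of class `contact_map`.
#' @export
contact_map <- function(chrom_sizes, resolution, entries = NULL) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  .assert(is.numeric(resolution) && resolution >= 1, "resolution must be >= 1")
  if (is.null(entries) || nrow(entries) == 0L) {
    entries <- data.frame(chrom1 = character(), bin1 = integer(),
                          chrom2 = character(), bin2 = integer(),
                          value = numeric())
  } else {
    entries <- canonicalize_entries(entries, chrom_sizes, resolution)
  }
  structure(list(chrom_sizes = chrom_sizes, resolution = resolution,
                 entries = entries),
            class = "contact_map")
}

validate_chrom_sizes <- function(chrom_sizes) {
  .assert(length(chrom_sizes) >= 1, "empty chromosome sizes")
  .assert(!is.null(names(chrom_sizes)) && all(nzchar(names(chrom_sizes))),
          "chromosome sizes must be named")
  .assert(!anyDuplicated(names(chrom_sizes)), "duplicate chromosome name")
  .assert(all(is.finite(chrom_sizes)) && all(chrom_sizes >= 1) &&
            all(chrom_sizes == floor(chrom_sizes)),
          "non-positive or non-integer chromosome length")
  stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
}

#' Number of bins on a chromosome at the map's resolution
#' @param chrom_sizes named length vector, or a `contact_map`.
#' @param chrom chromosome name.
#' @param resolution bin width (ignored when a map is passed).
#' @export
n_bins <- function(chrom_sizes, chrom, resolution = NULL) {
  if (inherits(chrom_sizes, "contact_map")) {
    resolution <- chrom_sizes$resolution
    chrom_sizes <- chrom_sizes$chrom_sizes
  }
  .assert(chrom %in% names(chrom_sizes), "unknown chromosome '%s'", chrom)
  as.integer(ceiling(chrom_sizes[[chrom]] / resolution))
}

# Put every entry into canonical orientation ((chrom order, bin) of side 1
# <= side 2), then sum duplicates.
canonicalize_entries <- function(entries, chrom_sizes, resolution) {
  need <- c("chrom1", "bin1", "chrom2", "bin2", "value")
  .assert(all(need %in% names(entries)), "entries missing required columns")
  entries <- entries[, need]
  ord <- names(chrom_sizes)
  i1 <- match(entries$chrom1, ord)
  i2 <- match(entries$chrom2, ord)
  .assert(!anyNA(i1) && !anyNA(i2), "unknown chromosome in contact entries")
  .assert(all(entries$value >= 0), "negative contact value")
  nb <- ceiling(chrom_sizes / resolution)
  .assert(all(entries$bin1 >= 0 & entries$bin1 < nb[i1]) &&
            all(entries$bin2 >= 0 & entries$bin2 < nb[i2]),
          "bin index outside chromosome")
  swap <- i1 > i2 | (i1 == i2 & entries$bin1 > entries$bin2)
  if (any(swap)) {
    tmp_c <- entries$chrom1[swap]; tmp_b <- entries$bin1[swap]
    entries$chrom1[swap] <- entries$chrom2[swap]
    entries$bin1[swap] <- entries$bin2[swap]
    entries$chrom2[swap] <- tmp_c
    entries$bin2[swap] <- tmp_b
    i <- i1[swap]; i1[swap] <- i2[swap]; i2[swap] <- i
  }
  key <- paste(entries$chrom1, entries$bin1, entries$chrom2, entries$bin2,
               sep = "\r")
  v <- rowsum(entries$value, key)
  first <- !duplicated(key)
  out <- entries[first, c("chrom1", "bin1", "chrom2", "bin2")]
  out$value <- as.numeric(v[match(key[first], rownames(v)), 1])
  out <- out[out$value != 0, , drop = FALSE]
  o <- order(match(out$chrom1, ord), out$bin1, match(out$chrom2, ord), out$bin2)
  out <- out[o, , drop = FALSE]
  out$bin1 <- as.integer(out$bin1); out$bin2 <- as.integer(out$bin2)
  rownames(out) <- NULL
  out
}

#' Query a single contact value
#'
#' Symmetric: `contact_query(m, a, i, b, j) == contact_query(m, b, j, a, i)`.
#' Absent entries are zero.
#' @param map a `contact_map`.
#' @param chrom1,bin1,chrom2,bin2 bin coordinates.
#' @export
contact_query <- function(map, chrom1, bin1, chrom2, bin2) {
  e <- contact_pair_entries(map, chrom1, chrom2)
  hit <- e$bin_a == bin1 & e$bin_b == bin2
  if (any(hit)) sum(e$value[hit]) else 0
}

# All entries between chromosome pair (ca, cb), oriented as (bin on ca,
# bin on cb); for ca == cb both (i,j) and (j,i) off-diagonal rows appear.
contact_pair_entries <- function(map, ca, cb) {
  ord <- names(map$chrom_sizes)
  .assert(ca %in% ord && cb %in% ord, "unknown chromosome")
  e <- map$entries
  if (ca == cb) {
    sel <- e$chrom1 == ca & e$chrom2 == ca
    e <- e[sel, , drop = FALSE]
    off <- e$bin1 != e$bin2
    data.frame(bin_a = c(e$bin1, e$bin2[off]),
               bin_b = c(e$bin2, e$bin1[off]),
               value = c(e$value, e$value[off]))
  } else {
    fwd <- e[e$chrom1 == ca & e$chrom2 == cb, , drop = FALSE]
    rev <- e[e$chrom1 == cb & e$chrom2 == ca, , drop = FALSE]
    data.frame(bin_a = c(fwd$bin1, rev$bin2),
               bin_b = c(fwd$bin2, rev$bin1),
               value = c(fwd$value, rev$value))
  }
}

#' Dense symmetric intrachromosomal matrix for one chromosome
#' @param map a `contact_map`.
#' @param chrom chromosome name.
#' @return n x n numeric matrix (absent entries are 0).
#' @export
contact_matrix <- function(map, chrom) {
  n <- n_bins(map, chrom)
  M <- matrix(0, n, n)
  e <- contact_pair_entries(map, chrom, chrom)
  if (nrow(e)) M[cbind(e$bin_a + 1L, e$bin_b + 1L)] <- e$value
  M
}

# Dense matrix of contacts between a bin set on chrom_a and all bins of
# chrom_b (rows = bins_a in given order, cols = all bins of chrom_b).
contact_submatrix <- function(map, chrom_a, bins_a, chrom_b) {
  nb <- n_bins(map, chrom_b)
  M <- matrix(0, length(bins_a), nb)
  e <- contact_pair_entries(map, chrom_a, chrom_b)
  e <- e[e$bin_a %in% bins_a, , drop = FALSE]
  if (nrow(e)) M[cbind(match(e$bin_a, bins_a), e$bin_b + 1L)] <- e$value
  M
}

#' Bin indices overlapping an interval
#'
#' Returns every bin overlapping the interval by at least one base, i.e.
#' `floor(start/r) .. floor((end-1)/r)`.
#'
#' @param interval a genomic interval (or "chrom:start-end" string).
#' @param resolution bin width in bp.
#' @param chrom_sizes optional; when given, the interval is bounds-checked.
#' @return integer vector of 0-based bin indices (contiguous).
#' @export
region_to_bins <- function(interval, resolution, chrom_sizes = NULL) {
  interval <- .as_interval(interval, chrom_sizes)
  as.integer(seq.int(floor(interval$start / resolution),
                     floor((interval$end - 1) / resolution)))
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d chromosomes, resolution %d bp, %d stored entries\n",
              length(x$chrom_sizes), as.integer(x$resolution), nrow(x$entries)))
  invisible(x)
}
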