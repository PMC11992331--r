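#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm p.adjust rpois runif sd cor aggregate
#' @importFrom utils read.table write.table
NULL

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

#' Parse a "chrom:start-end" region string
#'
#' Coordinates are 0-based half-open, matching the package-wide convention.
#'
#' @param x character scalar like `"chr8:29100000-29700000"`.
#' @return A genomic interval: `list(chrom, start, end)`.
#' @export
parse_region <- function(x) {
  .assert(is.character(x) && length(x) == 1L, "region must be a single string")
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  .assert(length(m) == 4L, "malformed region '%s' (expected chrom:start-end)", x)
  genomic_interval(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

#' Construct a genomic interval
#'
#' Intervals are 0-based half-open throughout the package (BED-native);
#' GFF3 coordinates are converted on read.
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @param chrom_sizes optional named vector of chromosome lengths; when
#'   supplied the interval is checked against it.
#' @return `list(chrom, start, end)` with class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, chrom_sizes = NULL) {
  .assert(is.character(chrom) && nzchar(chrom), "chrom must be a non-empty string")
  .assert(is.numeric(start) && is.numeric(end), "start/end must be numeric")
  .assert(start >= 0 && start < end, "invalid interval [%s, %s)", start, end)
  if (!is.null(chrom_sizes)) {
    .assert(chrom %in% names(chrom_sizes), "unknown chromosome '%s'", chrom)
    .assert(end <= chrom_sizes[[chrom]],
            "interval end %s exceeds %s length %s", end, chrom, chrom_sizes[[chrom]])
  }
  structure(list(chrom = chrom, start = as.numeric(start), end = as.numeric(end)),
            class = "genomic_interval")
}

.as_interval <- function(x, chrom_sizes = NULL) {
  if (is.character(x)) x <- parse_region(x)
  .assert(is.list(x) && all(c("chrom", "start", "end") %in% names(x)),
          "not a genomic interval")
  genomic_interval(x$chrom, x$start, x$end, chrom_sizes)
}
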