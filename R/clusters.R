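# Proximity-based calling of biosynthetic gene clusters (>= 3 distinct
# pathway families chained within a gap threshold) and same-family tandem
# arrays from family-labelled gene models.

.chain_genes <- function(genes, max_gap, break_on_family_change = FALSE) {
  # genes sorted by start on one chromosome; returns a grouping vector.
  grp <- integer(nrow(genes))
  g <- 1L
  grp[1] <- g
  run_end <- genes$end[1]
  for (k in seq_len(nrow(genes))[-1]) {
    new_chain <- genes$start[k] - run_end > max_gap ||
      (break_on_family_change && genes$family[k] != genes$family[k - 1])
    if (new_chain) g <- g + 1L
    grp[k] <- g
    run_end <- if (new_chain) genes$end[k] else max(run_end, genes$end[k])
  }
  grp
}

.empty_calls <- function() {
  data.frame(kind = character(), chrom = character(), start = numeric(),
             end = numeric(), n_members = integer(), n_families = integer(),
             families = character(), member_ids = character())
}

.call_from_groups <- function(genes, grp, kind) {
  if (nrow(genes) == 0) return(.empty_calls())
  out <- lapply(split(seq_len(nrow(genes)), grp), function(ix) {
    m <- genes[ix, , drop = FALSE]
    data.frame(kind = kind, chrom = m$chrom[1], start = min(m$start),
               end = max(m$end), n_members = nrow(m),
               n_families = length(unique(m$family)),
               families = paste(sort(unique(m$family)), collapse = ","),
               member_ids = paste(m$id, collapse = ","))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call biosynthetic gene clusters
#'
#' Chains consecutive pathway-family genes on a chromosome whenever the
#' gap from the previous chain's end to the next gene's start is at most
#' `max_gap`, ignoring intervening non-pathway genes, and emits chains
#' with at least three distinct families as BGC calls. A BGC here is
#' three or more non-homologous genes of one biosynthetic pathway in
#' close genomic proximity; "close" is the exposed `max_gap`, whose
#' default of 400 kb admits a member sitting 346 kb downstream of the
#' core.
#'
#' @param genes gene-record data frame (`id, chrom, start, end, strand,
#'   family`).
#' @param pathway_families character vector of family labels that belong
#'   to the pathway; labels absent from `genes` only trigger a warning.
#' @param max_gap maximum start-to-previous-end gap in bp (default
#'   400000).
#' @return cluster-call data frame (`kind, chrom, start, end, n_members,
#'   n_families, families, member_ids`), possibly empty.
#' @export
call_bgcs <- function(genes, pathway_families, max_gap = 400000) {
  .assert(length(pathway_families) > 0, "pathway_families must be non-empty")
  .assert(max_gap > 0, "max_gap must be positive")
  unknown <- setdiff(pathway_families, genes$family)
  if (length(unknown))
    warning("pathway families not present in gene set: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  g <- genes[genes$family %in% pathway_families, , drop = FALSE]
  empty <- .empty_calls()
  if (nrow(g) == 0) return(empty)
  calls <- lapply(split(g, g$chrom), function(gc) {
    gc <- gc[order(gc$start), , drop = FALSE]
    .call_from_groups(gc, .chain_genes(gc, max_gap), "BGC")
  })
  calls <- do.call(rbind, c(unname(calls), list(make.row.names = FALSE)))
  calls <- calls[calls$n_families >= 3, , drop = FALSE]
  calls <- calls[order(match(calls$chrom, unique(genes$chrom)), calls$start), ]
  rownames(calls) <- NULL
  calls
}

#' Call tandem gene arrays
#'
#' Maximal runs of two or more same-family genes with inter-gene gaps at
#' most `max_gap` and no intervening gene of a different pathway family
#' (genes of family "other", and any family listed in `ignore_families`,
#' are transparent and never break a run).
#'
#' @param genes gene-record data frame.
#' @param max_gap maximum inter-gene gap in bp (default 100000).
#' @param ignore_families families treated as non-pathway filler
#'   (default "other").
#' @return cluster-call data frame with `kind = "tandem_array"`.
#' @export
call_tandem_arrays <- function(genes, max_gap = 100000,
                               ignore_families = "other") {
  .assert(max_gap > 0, "max_gap must be positive")
  g <- genes[!(genes$family %in% ignore_families), , drop = FALSE]
  empty <- .empty_calls()
  if (nrow(g) == 0) return(empty)
  calls <- lapply(split(g, g$chrom), function(gc) {
    gc <- gc[order(gc$start), , drop = FALSE]
    .call_from_groups(gc, .chain_genes(gc, max_gap,
                                       break_on_family_change = TRUE),
                      "tandem_array")
  })
  calls <- do.call(rbind, c(unname(calls), list(make.row.names = FALSE)))
  calls <- calls[calls$n_members >= 2, , drop = FALSE]
  calls <- calls[order(match(calls$chrom, unique(genes$chrom)), calls$start), ]
  rownames(calls) <- NULL
  calls
}

#' Annotate cluster calls with LTR base coverage
#'
#' Adds the fraction of each call's span covered by intervals matching
#' `class_prefix` (default "LTR"), via [coverage_fraction()].
#'
#' @param calls cluster-call data frame.
#' @param te_track annotation track.
#' @param class_prefix class label or prefix.
#' @return `calls` with an added `ltr_fraction` column.
#' @export
annotate_calls <- function(calls, te_track, class_prefix = "LTR") {
  if (nrow(calls) == 0) {
    calls$ltr_fraction <- numeric()
    return(calls)
  }
  calls$ltr_fraction <- vapply(seq_len(nrow(calls)), function(k)
    coverage_fraction(te_track, class_prefix,
                      genomic_interval(calls$chrom[k], calls$start[k],
                                       calls$end[k])), 1.0)
  calls
}
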