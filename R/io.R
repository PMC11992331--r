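# Readers/writers for the plain-text formats the pipeline touches:
# UCSC chrom.sizes, BEDPE-style contact triplets, BED4, GFF3.

#' Read a UCSC-style chrom.sizes file
#'
#' Whitespace-separated two-column text: chromosome name, length in bp.
#' Row order defines the chromosome order used throughout.
#'
#' @param path file path.
#' @return named numeric vector of lengths, in file order.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  .assert(length(lines) > 0, "empty chrom.sizes file '%s'", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  .assert(all(lengths(parts) >= 2), "malformed chrom.sizes row in '%s'", path)
  nm <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  .assert(!anyNA(len) && all(len == floor(len)), "non-integer length in '%s'", path)
  .assert(all(len >= 1), "non-positive length in '%s'", path)
  .assert(!anyDuplicated(nm), "duplicate chromosome name in '%s'", path)
  stats::setNames(len, nm)
}

#' Read BEDPE-style binned contacts
#'
#' Seven tab-separated columns: chrom1 start1 end1 chrom2 start2 end2 value.
#' Start/end must be aligned to the resolution grid. Duplicate (i,j)/(j,i)
#' rows are summed. Lines starting with '#' are ignored.
#'
#' @param path file path.
#' @param chrom_sizes named length vector (see [read_chrom_sizes()]).
#' @param resolution bin width in bp.
#' @return a [contact_map()].
#' @export
read_contacts <- function(path, chrom_sizes, resolution) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  df <- tryCatch(
    read.table(path, sep = "\t", comment.char = "#",
               col.names = c("chrom1", "start1", "end1",
                             "chrom2", "start2", "end2", "value"),
               colClasses = c("character", "numeric", "numeric",
                              "character", "numeric", "numeric", "numeric")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else
        stop(sprintf("malformed contact file '%s': %s", path,
                     conditionMessage(e)), call. = FALSE)
    })
  if (is.null(df)) return(contact_map(chrom_sizes, resolution))
  .assert(all(df$chrom1 %in% names(chrom_sizes)) &&
            all(df$chrom2 %in% names(chrom_sizes)),
          "unknown chromosome in '%s'", path)
  aligned <- df$start1 %% resolution == 0 & df$start2 %% resolution == 0 &
    df$end1 - df$start1 <= resolution & df$end2 - df$start2 <= resolution &
    df$end1 > df$start1 & df$end2 > df$start2
  .assert(all(aligned), "unaligned bin in '%s' (resolution %d)",
          path, as.integer(resolution))
  .assert(all(df$value >= 0), "negative value in '%s'", path)
  entries <- data.frame(chrom1 = df$chrom1, bin1 = df$start1 %/% resolution,
                        chrom2 = df$chrom2, bin2 = df$start2 %/% resolution,
                        value = df$value)
  contact_map(chrom_sizes, resolution, entries)
}

#' Write a contact map as BEDPE-style triplets
#'
#' Upper-triangle rows only (canonical orientation), sorted by chromosome
#' order then bin; values written at full precision so the file round-trips
#' exactly through [read_contacts()].
#'
#' @param map a [contact_map()].
#' @param path output path.
#' @export
write_contacts <- function(map, path) {
  r <- map$resolution
  sizes <- map$chrom_sizes
  e <- map$entries
  lines <- if (nrow(e)) {
    end1 <- pmin((e$bin1 + 1) * r, sizes[e$chrom1])
    end2 <- pmin((e$bin2 + 1) * r, sizes[e$chrom2])
    sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s",
            e$chrom1, as.integer(e$bin1 * r), as.integer(end1),
            e$chrom2, as.integer(e$bin2 * r), as.integer(end2),
            sprintf("%.17g", e$value))
  } else character()
  writeLines(c("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tvalue", lines),
             path)
  invisible(path)
}

#' Read a BED4 file as an annotation track
#'
#' Columns: chrom, start, end, name; the name column carries the class
#' label (hierarchical, '/'-delimited, e.g. "LTR/Gypsy/Athila").
#' Coordinates stay 0-based half-open (BED-native).
#'
#' @param path file path.
#' @return data frame with columns `chrom, start, end, class` (an
#'   annotation track).
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop(sprintf("malformed BED '%s': %s", path,
                                conditionMessage(e)), call. = FALSE))
  cls <- if ("name" %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)$name)
  } else {
    rep(NA_character_, length(gr))
  }
  .assert(!anyNA(cls) && all(nzchar(cls)), "BED row without class label in '%s'", path)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    class = cls)
  .assert(all(out$end > out$start), "empty interval in '%s'", path)
  out
}

#' Write an annotation track as BED4
#' @param track data frame `chrom, start, end, class` (0-based half-open).
#' @param path output path.
#' @export
write_bed <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                     as.integer(track$end), track$class), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps features of type "gene". The pathway family is taken from the
#' `family` attribute, falling back to `Name`; a gene with neither is an
#' error. GFF3 1-based inclusive coordinates are converted to 0-based
#' half-open.
#'
#' @param path file path.
#' @return data frame of gene records: `id, chrom, start, end, strand,
#'   family`.
#' @export
read_genes_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "GFF3"),
                 error = function(e)
                   stop(sprintf("malformed GFF3 '%s': %s", path,
                                conditionMessage(e)), call. = FALSE))
  gr <- gr[as.character(S4Vectors::mcols(gr)$type) == "gene"]
  mc <- S4Vectors::mcols(gr)
  fam <- if ("family" %in% names(mc)) as.character(mc$family) else
    rep(NA_character_, length(gr))
  nm <- if ("Name" %in% names(mc)) as.character(mc$Name) else
    rep(NA_character_, length(gr))
  fam <- ifelse(is.na(fam) | !nzchar(fam), nm, fam)
  .assert(!anyNA(fam) && all(nzchar(fam)), "unlabelled gene in '%s'", path)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    sprintf("gene%04d", seq_along(gr))
  .assert(!anyDuplicated(id), "duplicate gene id in '%s'", path)
  out <- data.frame(id = id,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    family = fam)
  out$strand[out$strand == "*"] <- "."
  .assert(all(out$end > out$start), "empty gene interval in '%s'", path)
  out
}

#' Write gene records as GFF3
#' @param genes gene-record data frame (0-based half-open; converted back
#'   to 1-based inclusive on write).
#' @param path output path.
#' @export
write_genes_gff3 <- function(genes, path) {
  strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, ".")
  lines <- sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;family=%s",
                   genes$chrom, as.integer(genes$start + 1),
                   as.integer(genes$end), strand, genes$id, genes$id,
                   genes$family)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write a results table as TSV
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
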