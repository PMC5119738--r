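# Readers and writers for the BED-family text formats the pipeline touches.
# All files are 0-based half-open on disk; in memory everything is a GRanges
# (1-based closed).  The conversion happens here and nowhere else.

# parse tab-separated lines into a character matrix with >= ncol fields,
# reporting the first offending line by its number in the original file
split_fields <- function(lines, ncol, path, line_numbers = seq_along(lines)) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol)
  if (length(bad)) {
    stop(sprintf("malformed record at line %d of '%s': expected at least %d tab-separated fields, found %d",
                 line_numbers[bad[1L]], path, ncol, nf[bad[1L]]))
  }
  m <- vapply(seq_len(ncol), function(j) {
    vapply(fields, `[[`, character(1L), j)
  }, character(length(fields)))
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  m
}

parse_numeric_column <- function(x, what, lines, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop(sprintf("malformed %s at line %d of '%s': '%s'",
                 what, lines[bad[1L]], path, x[bad[1L]]))
  }
  v
}

#' Read aligned tags from a BED6 or tagAlign file
#'
#' Both dialects carry `chrom start end name/sequence score strand`; the score
#' column is taken as the mapping quality.  Coordinates are 0-based half-open
#' on disk and converted to 1-based closed `GRanges` in memory.  Records on
#' chromosomes absent from `genome` are dropped (mirroring alignment to a
#' partial reference); the number dropped is stored in
#' `S4Vectors::metadata(x)$n_dropped` and reported as a message.
#'
#' @param path Path to the tag file.
#' @param format `"bed6"` or `"tagalign"` (parsed identically; the fourth
#'   column is a name or the read sequence respectively).
#' @param genome [genome_layout()] of the species the tags belong to.
#' @return A `GRanges` with a `mapq` metadata column and the layout's seqinfo.
#'   Malformed lines (too few fields, non-numeric coordinates, `start >= end`,
#'   coordinates beyond the chromosome, unknown strand) raise an error naming
#'   the line.  An empty file yields an empty `GRanges`.
#' @export
read_tags <- function(path, format = c("bed6", "tagalign"), genome) {
  format <- match.arg(format)
  stopifnot(inherits(genome, "genome_layout"))
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep_lines <- which(nzchar(lines))
  empty <- GenomicRanges::GRanges(seqinfo = as_seqinfo(genome))
  S4Vectors::mcols(empty)$mapq <- integer(0)
  if (length(keep_lines) == 0L) {
    S4Vectors::metadata(empty)$n_dropped <- 0L
    return(empty)
  }
  m <- split_fields(lines[keep_lines], 6L, path, keep_lines)
  chrom <- m[, 1L]
  start0 <- parse_numeric_column(m[, 2L], "start coordinate", keep_lines, path)
  end0 <- parse_numeric_column(m[, 3L], "end coordinate", keep_lines, path)
  mapq <- parse_numeric_column(m[, 5L], "mapping quality", keep_lines, path)
  strand <- m[, 6L]

  bad <- which(!(strand %in% c("+", "-")))
  if (length(bad)) {
    stop(sprintf("invalid strand '%s' at line %d of '%s'",
                 strand[bad[1L]], keep_lines[bad[1L]], path))
  }
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad)) {
    stop(sprintf("invalid interval [%s, %s) at line %d of '%s'",
                 m[bad[1L], 2L], m[bad[1L], 3L], keep_lines[bad[1L]], path))
  }

  known <- chrom %in% genome$chrom
  n_dropped <- sum(!known)
  if (n_dropped > 0) {
    message(sprintf("read_tags: dropped %d record(s) on chromosome(s) absent from layout '%s'",
                    n_dropped, genome$species))
  }
  idx <- which(known)
  bad <- idx[end0[idx] > genome$lengths[chrom[idx]]]
  if (length(bad)) {
    stop(sprintf("interval end %s exceeds length of %s at line %d of '%s'",
                 m[bad[1L], 3L], chrom[bad[1L]], keep_lines[bad[1L]], path))
  }

  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom[idx], levels = genome$chrom),
    ranges = IRanges::IRanges(start = start0[idx] + 1, end = end0[idx]),
    strand = strand[idx],
    mapq = as.integer(mapq[idx]),
    seqinfo = as_seqinfo(genome)
  )
  S4Vectors::metadata(gr)$n_dropped <- n_dropped
  gr
}

#' Write tags as BED6
#'
#' The score column carries the mapping quality; names are `t1, t2, ...`.
#'
#' @param tags A `GRanges` with a `mapq` metadata column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  mapq <- S4Vectors::mcols(tags)$mapq %||% rep(0L, length(tags))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(tags)) {
    writeLines(sprintf("%s\t%d\t%d\tt%d\t%d\t%s",
                       as.character(GenomicRanges::seqnames(tags)),
                       GenomicRanges::start(tags) - 1L,
                       GenomicRanges::end(tags),
                       seq_along(tags),
                       as.integer(mapq),
                       as.character(GenomicRanges::strand(tags))),
               con)
  }
  invisible(path)
}

#' Read a BED3+ region file into a normalized region set
#'
#' Regions are sorted and overlapping or bookended intervals are merged, so the
#' result is a sorted, disjoint `GRanges`.  Normalization is idempotent.
#'
#' @param path Path to a BED file (first three columns used).
#' @return A sorted, disjoint `GRanges`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep_lines <- which(nzchar(lines))
  if (length(keep_lines) == 0L) return(GenomicRanges::GRanges())
  m <- split_fields(lines[keep_lines], 3L, path, keep_lines)
  start0 <- parse_numeric_column(m[, 2L], "start coordinate", keep_lines, path)
  end0 <- parse_numeric_column(m[, 3L], "end coordinate", keep_lines, path)
  bad <- which(start0 >= end0)
  if (length(bad)) {
    stop(sprintf("empty or inverted interval [%s, %s) at line %d of '%s'",
                 m[bad[1L], 2L], m[bad[1L], 3L], keep_lines[bad[1L]], path))
  }
  gr <- GenomicRanges::GRanges(m[, 1L], IRanges::IRanges(start0 + 1, end0))
  normalize_regions(gr)
}

#' Normalize a region set
#'
#' Sorts seqlevels alphabetically, sorts intervals, and merges overlapping or
#' bookended intervals.
#'
#' @param regions A `GRanges`.
#' @return A sorted, disjoint, unstranded `GRanges`.
#' @export
normalize_regions <- function(regions) {
  regions <- GenomicRanges::granges(regions)
  GenomicRanges::strand(regions) <- "*"
  GenomeInfoDb::seqlevels(regions) <- sort(GenomeInfoDb::seqlevels(regions))
  GenomicRanges::reduce(sort(regions))
}

#' Write a region set as BED3
#'
#' @param regions A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(regions)) {
    writeLines(sprintf("%s\t%d\t%d",
                       as.character(GenomicRanges::seqnames(regions)),
                       GenomicRanges::start(regions) - 1L,
                       GenomicRanges::end(regions)),
               con)
  }
  invisible(path)
}
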