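# Binned coverage tracks: fixed-width bins along a genome, one value per bin.
# The value of a bin is (fragment bp overlapping the bin) / bin_width, so a
# fragment contributes total mass length/bin_width and the conservation
# identity sum(values) * bin_width == sum(fragment lengths) is exact.

#' Construct a binned coverage track
#'
#' @param genome A [genome_layout()].
#' @param bin_width Bin width in bp (> 0).
#' @param values Named list (one element per chromosome of the layout) of
#'   non-negative numeric vectors of length `ceiling(length / bin_width)`.
#'   Missing chromosomes get all-zero bins.
#' @return An object of class `bin_track`.
#' @export
bin_track <- function(genome, bin_width, values = NULL) {
  stopifnot(inherits(genome, "genome_layout"))
  if (!is_count(bin_width) || bin_width <= 0) stop("bin_width must be a positive integer")
  n_bins <- ceiling(genome$lengths / bin_width)
  if (is.null(values)) {
    values <- lapply(n_bins, numeric)
  } else {
    stopifnot(is.list(values), all(names(values) %in% genome$chrom))
    values <- values[intersect(genome$chrom, names(values))]
    full <- lapply(genome$chrom, function(ch) {
      v <- values[[ch]]
      if (is.null(v)) return(numeric(n_bins[[ch]]))
      if (length(v) != n_bins[[ch]]) {
        stop(sprintf("chromosome %s: expected %d bins, got %d",
                     ch, n_bins[[ch]], length(v)))
      }
      if (any(v < 0)) stop("bin values must be non-negative")
      as.numeric(v)
    })
    values <- stats::setNames(full, genome$chrom)
  }
  structure(list(genome = genome, bin_width = as.integer(bin_width),
                 values = values),
            class = "bin_track")
}

#' @export
print.bin_track <- function(x, ...) {
  cat(sprintf("bin_track: %s, %d-bp bins, %d bins, total mass %.4g\n",
              x$genome$species, x$bin_width,
              sum(vapply(x$values, length, 1L)),
              sum(vapply(x$values, sum, 1)) * x$bin_width))
  invisible(x)
}

#' Total fragment bp represented by a track
#'
#' @param track A [bin_track()].
#' @return `sum(values) * bin_width`, the total fragment bp assigned.
#' @export
track_mass <- function(track) {
  stopifnot(inherits(track, "bin_track"))
  sum(vapply(track$values, sum, 1)) * track$bin_width
}

format_bedgraph_value <- function(v) {
  v <- signif(v, 4L)
  ifelse(v == floor(v) & abs(v) < 1e15,
         sprintf("%.1f", v),
         sprintf("%.10g", v))
}

#' Write a binned track as bedGraph
#'
#' Emits records in genome order, merging runs of bins with equal value and
#' omitting zero-valued runs.  Values are written with 4 significant digits so
#' files are reproducible; re-reading reproduces the non-zero bins of
#' `signif(values, 4)` exactly.
#'
#' @param track A [bin_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "bin_track"))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  w <- track$bin_width
  for (ch in track$genome$chrom) {
    v <- signif(track$values[[ch]], 4L)
    if (!length(v)) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    s0 <- starts_bin[keep] * w
    e0 <- pmin(ends_bin[keep] * w, unname(track$genome$lengths[[ch]]))
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, s0, e0,
                       format_bedgraph_value(r$values[keep])),
               con)
  }
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()] back into a track
#'
#' Record boundaries must align with the bin grid (as produced by the writer).
#'
#' @param path Path to the bedGraph file.
#' @param genome A [genome_layout()].
#' @param bin_width Bin width in bp the file was written with.
#' @return A [bin_track()].
#' @export
read_bedgraph <- function(path, genome, bin_width) {
  track <- bin_track(genome, bin_width)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep_lines <- which(nzchar(lines) & !startsWith(lines, "track"))
  if (!length(keep_lines)) return(track)
  m <- split_fields(lines[keep_lines], 4L, path, keep_lines)
  chrom <- m[, 1L]
  s0 <- parse_numeric_column(m[, 2L], "start coordinate", keep_lines, path)
  e0 <- parse_numeric_column(m[, 3L], "end coordinate", keep_lines, path)
  val <- parse_numeric_column(m[, 4L], "value", keep_lines, path)
  unknown <- which(!(chrom %in% genome$chrom))
  if (length(unknown)) {
    stop(sprintf("unknown chromosome '%s' at line %d of '%s'",
                 chrom[unknown[1L]], keep_lines[unknown[1L]], path))
  }
  if (any(s0 %% bin_width != 0)) {
    stop("bedGraph record not aligned to the bin grid in '", path, "'")
  }
  for (i in seq_along(chrom)) {
    ch <- chrom[i]
    first <- s0[i] %/% bin_width + 1L
    last <- ceiling(e0[i] / bin_width)
    track$values[[ch]][first:last] <- val[i]
  }
  track
}
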