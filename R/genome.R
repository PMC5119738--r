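#' Genome layout for one species
#'
#' A genome layout names the chromosomes of one species, their lengths, and the
#' species label used to keep the two genomes of a spike-in experiment apart.
#' It is the coordinate space against which tags are validated.
#'
#' @param species Short species label, e.g. `"human"` or `"fly"`.
#' @param chrom Character vector of chromosome names (unique).
#' @param lengths Numeric vector of chromosome lengths in bp (> 0), parallel to
#'   `chrom`.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout("fly", c("chr2L", "chr2R"), c(23011544, 21146708))
#' @export
genome_layout <- function(species, chrom, lengths) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  chrom <- as.character(chrom)
  lengths <- as.numeric(lengths)
  if (length(chrom) == 0L) {
    stop("a genome layout needs at least one chromosome")
  }
  if (length(chrom) != length(lengths)) {
    stop("'chrom' and 'lengths' must have the same length")
  }
  if (anyDuplicated(chrom)) {
    stop("duplicated chromosome names: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != floor(lengths))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(
    list(species = species, chrom = chrom,
         lengths = stats::setNames(lengths, chrom)),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout '%s': %d chromosome(s), %s bp total\n",
              x$species, length(x$chrom),
              format(total_length(x), big.mark = ",")))
  invisible(x)
}

#' Total genome length of a layout
#'
#' @param layout A [genome_layout()].
#' @return Total length in bp.
#' @export
total_length <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$lengths)
}

#' Convert a genome layout to a Seqinfo
#'
#' @param layout A [genome_layout()].
#' @return A [GenomeInfoDb::Seqinfo] whose `genome` field carries the species
#'   label.
#' @export
as_seqinfo <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  GenomeInfoDb::Seqinfo(seqnames = layout$chrom,
                        seqlengths = as.integer(layout$lengths),
                        genome = layout$species)
}

#' Read a UCSC chrom.sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path Path to the chrom.sizes file.
#' @param species Species label to attach to the layout.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path, species) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(species, df$chrom, df$length)
}

#' Write a UCSC chrom.sizes file
#'
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  writeLines(sprintf("%s\t%d", layout$chrom, as.integer(layout$lengths)), path)
  invisible(path)
}
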