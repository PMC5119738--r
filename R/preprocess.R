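# Tag-level filters and the tags -> binned coverage transformation.
# Order of application is fixed: mapping-quality filter, then duplicate
# removal, so duplicates of low-quality alignments cannot shield a
# high-quality tag at the same position.

#' Preprocessing parameters
#'
#' @param min_mapq Strict mapping-quality cutoff; tags with `mapq > min_mapq`
#'   are kept (default 25, a uniqueness proxy for BWA alignments).
#' @param extension Fragment length in bp tags are extended to at their
#'   3'-ends (default 200, the average genomic fragment length of a sonicated
#'   library).
#' @param bin_width Coverage bin width in bp (default 32).
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(min_mapq = 25L, extension = 200L,
                              bin_width = 32L) {
  stopifnot(is_count(min_mapq), is_count(extension), extension > 0,
            is_count(bin_width), bin_width > 0)
  structure(list(min_mapq = as.integer(min_mapq),
                 extension = as.integer(extension),
                 bin_width = as.integer(bin_width)),
            class = "preprocess_params")
}

#' Keep tags with mapping quality strictly above a cutoff
#'
#' The cutoff is exclusive: `mapq > min_mapq`.  Input order is preserved and
#' the operation is idempotent.
#'
#' @param tags `GRanges` with a `mapq` metadata column.
#' @param min_mapq Exclusive cutoff (default 25).
#' @return Filtered `GRanges`.
#' @export
filter_mapq <- function(tags, min_mapq = 25L) {
  mapq <- S4Vectors::mcols(tags)$mapq
  if (is.null(mapq)) stop("tags carry no 'mapq' metadata column")
  tags[mapq > min_mapq]
}

# 5' alignment position of each tag: start for +, end for -
five_prime_pos <- function(tags) {
  ifelse(as.character(GenomicRanges::strand(tags)) == "-",
         GenomicRanges::end(tags),
         GenomicRanges::start(tags))
}

#' Remove duplicate tags
#'
#' PCR duplicates share the 5' alignment position, so the duplicate key is
#' (chromosome, 5' position, strand): start for `+` tags, end for `-` tags.
#' The first occurrence is kept; order is preserved; idempotent.
#'
#' @param tags `GRanges` of tags.
#' @return Deduplicated `GRanges`.
#' @export
deduplicate <- function(tags) {
  if (!length(tags)) return(tags)
  key <- paste(as.character(GenomicRanges::seqnames(tags)),
               five_prime_pos(tags),
               as.character(GenomicRanges::strand(tags)))
  tags[!duplicated(key)]
}

#' Extend tags at their 3'-ends to the fragment length
#'
#' A `+` tag keeps its start and grows to `extension` bp; a `-` tag keeps its
#' end and grows upstream.  Fragments are clipped at chromosome boundaries, so
#' every fragment is at most `extension` bp and contains the tag's 5' base.
#' One fragment per tag.
#'
#' @param tags `GRanges` of tags with seqlengths set (as produced by
#'   [read_tags()] or [sample_library()]).
#' @param extension Fragment length in bp (default 200).
#' @return `GRanges` of fragments; strand records the source tag's strand.
#' @export
extend_tags <- function(tags, extension = 200L) {
  if (any(is.na(GenomeInfoDb::seqlengths(tags)))) {
    stop("tags must carry seqlengths for boundary clipping")
  }
  # resize may momentarily run past chromosome ends; trim() clips them
  fr <- suppressWarnings(GenomicRanges::resize(tags, width = extension,
                                               fix = "start"))
  fr <- GenomicRanges::trim(fr)
  S4Vectors::mcols(fr) <- NULL
  fr
}

#' Bin fragment coverage along the genome
#'
#' Each bin's value is the total fragment bp overlapping the bin divided by
#' the bin width (fractional occupancy).  A fragment therefore contributes
#' total mass `length / bin_width`, and the conservation identity
#' `track_mass(track) == sum(width(fragments))` is exact.
#'
#' @param fragments `GRanges` of fragments (validated against the genome).
#' @param genome A [genome_layout()].
#' @param bin_width Bin width in bp (default 32).
#' @return A [bin_track()].
#' @export
bin_coverage <- function(fragments, genome, bin_width = 32L) {
  stopifnot(inherits(genome, "genome_layout"))
  track <- bin_track(genome, bin_width)
  if (!length(fragments)) return(track)
  GenomeInfoDb::seqlevels(fragments) <- genome$chrom
  GenomeInfoDb::seqinfo(fragments) <- as_seqinfo(genome)
  cov <- GenomicRanges::coverage(fragments)
  for (ch in genome$chrom) {
    len <- unname(genome$lengths[[ch]])
    n <- ceiling(len / bin_width)
    starts <- (seq_len(n) - 1L) * bin_width + 1L
    ends <- pmin(seq_len(n) * bin_width, len)
    v <- IRanges::Views(cov[[ch]], start = starts, end = ends)
    track$values[[ch]] <- as.numeric(IRanges::viewSums(v)) / bin_width
  }
  track
}

#' Preprocess a sample library
#'
#' Applies the mapping-quality filter and then duplicate removal, identically
#' to every species bucket, and extends the surviving tags to fragments.
#'
#' @param lib A [sample_library()].
#' @param params A [preprocess_params()].
#' @return A list with elements `library` (the filtered [sample_library()]),
#'   `fragments` (named list, species -> `GRanges` of extended fragments) and
#'   `stats` (data frame of input/kept counts per species and filter stage).
#' @export
preprocess_library <- function(lib, params = preprocess_params()) {
  stopifnot(inherits(lib, "sample_library"),
            inherits(params, "preprocess_params"))
  stats_rows <- list()
  filtered <- lapply(stats::setNames(names(lib$tags), names(lib$tags)),
                     function(sp) {
    raw <- lib$tags[[sp]]
    hi <- filter_mapq(raw, params$min_mapq)
    uniq <- deduplicate(hi)
    stats_rows[[sp]] <<- data.frame(
      sample_id = lib$sample_id, species = sp,
      n_input = length(raw), n_mapq = length(hi), n_unique = length(uniq))
    uniq
  })
  out <- sample_library(lib$sample_id, lib$treatment, lib$mark,
                        filtered, lib$layouts)
  fragments <- lapply(stats::setNames(names(out$tags), names(out$tags)),
                      function(sp) extend_tags(out$tags[[sp]],
                                               params$extension))
  list(library = out, fragments = fragments,
       stats = do.call(rbind, unname(stats_rows)))
}
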