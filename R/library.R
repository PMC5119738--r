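#' One sample's tags, partitioned by species
#'
#' A sample library holds every aligned tag of one ChIP reaction, split into
#' one bucket per species, together with sample metadata.  A spike-in
#' experiment has two buckets: the experimental species and the reference
#' (spike-in) species.
#'
#' @param sample_id Sample identifier.
#' @param treatment Treatment label, e.g. `"control"` or `"treated"`.
#' @param mark Antibody target label, e.g. `"H3K27me3"`.
#' @param tags Named list, species label -> `GRanges` of tags.
#' @param layouts Named list, species label -> [genome_layout()]; must cover
#'   every species in `tags`, and every tag's chromosome must exist in its
#'   species' layout.
#' @return An object of class `sample_library`.
#' @export
sample_library <- function(sample_id, treatment = NA_character_,
                           mark = NA_character_, tags, layouts) {
  stopifnot(is.list(tags), is.list(layouts),
            !is.null(names(tags)), !is.null(names(layouts)))
  missing_layout <- setdiff(names(tags), names(layouts))
  if (length(missing_layout)) {
    stop("no layout registered for species: ",
         paste(missing_layout, collapse = ", "))
  }
  tags <- lapply(stats::setNames(names(tags), names(tags)), function(sp) {
    gr <- tags[[sp]]
    layout <- layouts[[sp]]
    bad <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                   layout$chrom)
    if (length(bad)) {
      stop(sprintf("sample '%s', species '%s': tags on chromosome(s) absent from layout: %s",
                   sample_id, sp, paste(bad, collapse = ", ")))
    }
    GenomeInfoDb::seqlevels(gr) <- layout$chrom
    GenomeInfoDb::seqinfo(gr) <- as_seqinfo(layout)
    gr
  })
  structure(list(sample_id = as.character(sample_id),
                 treatment = as.character(treatment),
                 mark = as.character(mark),
                 tags = tags,
                 layouts = layouts[names(tags)]),
            class = "sample_library")
}

#' @export
print.sample_library <- function(x, ...) {
  cat(sprintf("sample_library '%s' (treatment=%s, mark=%s)\n",
              x$sample_id, x$treatment, x$mark))
  for (sp in names(x$tags)) {
    cat(sprintf("  %s: %d tags\n", sp, length(x$tags[[sp]])))
  }
  invisible(x)
}

#' Number of tags per species in a library
#'
#' @param lib A [sample_library()].
#' @return Named integer vector, species -> tag count.
#' @export
tag_counts <- function(lib) {
  stopifnot(inherits(lib, "sample_library"))
  vapply(lib$tags, length, integer(1L))
}

#' Assign tags of a combined two-species alignment to species buckets
#'
#' Two conventions are supported.  With `mode = "prefixed_chroms"` all tags sit
#' in one `GRanges` whose chromosome names carry the species label as a prefix
#' followed by `"_"` (e.g. `human_chr1`, `fly_chr2R`); the prefix is stripped.
#' With `mode = "separate_files"` chromosome names are unprefixed and each tag
#' is assigned to the unique layout that contains its chromosome (the
#' two-alignment workflow, one aligned file per species, concatenated or not).
#' Every tag is assigned to exactly one species; the total count is conserved.
#'
#' @param tags A `GRanges` of tags (with a `mapq` metadata column).
#' @param layouts Named list, species label -> [genome_layout()].
#' @param mode `"separate_files"` or `"prefixed_chroms"`.
#' @param sample_id,treatment,mark Metadata for the resulting library.
#' @return A [sample_library()] with one bucket per layout (empty buckets
#'   included).
#' @export
partition_species <- function(tags, layouts,
                              mode = c("separate_files", "prefixed_chroms"),
                              sample_id = "sample", treatment = NA, mark = NA) {
  mode <- match.arg(mode)
  stopifnot(is.list(layouts), !is.null(names(layouts)))
  chrom <- as.character(GenomicRanges::seqnames(tags))

  if (mode == "prefixed_chroms") {
    species <- sub("_.*$", "", chrom)
    plain <- sub("^[^_]*_", "", chrom)
    bad <- !(species %in% names(layouts)) | !startsWith(chrom, paste0(species, "_"))
    if (any(bad)) {
      stop("unresolvable species prefix for chromosome(s): ",
           paste(unique(chrom[bad]), collapse = ", "))
    }
  } else {
    lookup <- unlist(lapply(names(layouts), function(sp) {
      stats::setNames(rep(sp, length(layouts[[sp]]$chrom)), layouts[[sp]]$chrom)
    }))
    if (anyDuplicated(names(lookup))) {
      dup <- unique(names(lookup)[duplicated(names(lookup))])
      stop("chromosome name(s) present in more than one layout (use prefixed_chroms): ",
           paste(dup, collapse = ", "))
    }
    species <- unname(lookup[chrom])
    if (anyNA(species)) {
      stop("chromosome(s) not found in any layout: ",
           paste(unique(chrom[is.na(species)]), collapse = ", "))
    }
    plain <- chrom
  }

  buckets <- lapply(stats::setNames(names(layouts), names(layouts)), function(sp) {
    idx <- which(species == sp)
    layout <- layouts[[sp]]
    unknown <- setdiff(unique(plain[idx]), layout$chrom)
    if (length(unknown)) {
      stop(sprintf("species '%s': chromosome(s) absent from its layout: %s",
                   sp, paste(unknown, collapse = ", ")))
    }
    gr <- GenomicRanges::GRanges(
      seqnames = factor(plain[idx], levels = layout$chrom),
      ranges = IRanges::ranges(tags)[idx],
      strand = GenomicRanges::strand(tags)[idx],
      seqinfo = as_seqinfo(layout)
    )
    S4Vectors::mcols(gr) <- S4Vectors::mcols(tags)[idx, , drop = FALSE]
    gr
  })
  sample_library(sample_id, treatment, mark, buckets, layouts)
}
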