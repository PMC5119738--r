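# The core of the method: count reference-species tags per sample, turn the
# counts into correction factors relative to a designated reference sample
# (conventionally the vehicle/DMSO control), and apply the factors to the
# experimental-species tags by seeded random removal.  Only removal is
# possible, so factors are rescaled to make the largest exactly 1.

#' Count reference-species tags in a sample library
#'
#' Two counting strategies mirror the two mapping strategies for spike-in
#' tags.  `whole_genome` counts every reference-species tag.  `restricted`
#' counts only tags whose 5' position falls inside a pre-defined region set
#' (the reference-antibody-bound regions), which excludes reference chromatin
#' pulled down by a cross-reacting experimental antibody and is therefore the
#' primary strategy.
#'
#' @param lib A [sample_library()], already preprocessed (the same filters
#'   must have been applied to every sample being compared).
#' @param reference_species Species label of the spike-in bucket.
#' @param mode `"restricted"` or `"whole_genome"`.
#' @param regions `GRanges` of reference regions; required (non-empty) in
#'   restricted mode.
#' @return Integer tag count.
#' @export
count_reference_tags <- function(lib, reference_species,
                                 mode = c("restricted", "whole_genome"),
                                 regions = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(lib, "sample_library"))
  if (!reference_species %in% names(lib$tags)) {
    stop(sprintf("sample '%s' has no tags for reference species '%s'",
                 lib$sample_id, reference_species))
  }
  tags <- lib$tags[[reference_species]]
  if (mode == "whole_genome") return(length(tags))
  if (is.null(regions) || !length(regions)) {
    stop("restricted counting requires a non-empty region set")
  }
  if (!length(tags)) return(0L)
  p5 <- GenomicRanges::GRanges(GenomicRanges::seqnames(tags),
                               IRanges::IRanges(five_prime_pos(tags),
                                                width = 1L))
  sum(IRanges::overlapsAny(p5, regions, ignore.strand = TRUE))
}

#' Correction factors from reference-tag counts
#'
#' The raw factor of sample *i* is `count[reference] / count[i]` (the
#' reference sample's own raw factor is 1).  Because factors are applied by
#' random tag removal only, all factors are then divided by their maximum, so
#' the largest applied factor is exactly 1 and ratios between samples are
#' preserved.  Scale-invariant: multiplying all counts by a constant leaves
#' the factors unchanged.
#'
#' @param counts Named numeric vector, sample id -> reference tag count; all
#'   counts must be positive (a zero count means the spike-in yielded too few
#'   tags for normalization -- add more spike-in material).
#' @param reference_sample Sample id the factors are computed against.
#' @param counting_mode Optional label recorded in the table.
#' @return A `correction_table` data frame with columns `sample_id`,
#'   `reference_tag_count`, `raw_factor`, `applied_factor`, `counting_mode`.
#' @export
compute_correction_factors <- function(counts, reference_sample,
                                       counting_mode = NA_character_) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("'counts' must be named by sample id")
  }
  if (!reference_sample %in% names(counts)) {
    stop("reference sample '", reference_sample, "' not among the counts")
  }
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    bad <- names(counts)[!is.finite(counts) | counts <= 0]
    stop("non-positive reference tag count for sample(s) ",
         paste(bad, collapse = ", "),
         ": too few spike-in tags for normalization; ",
         "increase the amount of spike-in chromatin")
  }
  raw <- unname(counts[reference_sample]) / counts
  applied <- raw / max(raw)
  out <- data.frame(sample_id = names(counts),
                    reference_tag_count = unname(counts),
                    raw_factor = unname(raw),
                    applied_factor = unname(applied),
                    counting_mode = counting_mode,
                    row.names = NULL)
  attr(out, "reference_sample") <- reference_sample
  class(out) <- c("correction_table", "data.frame")
  out
}

#' Write a correction table as TSV
#'
#' @param table A `correction_table` from [compute_correction_factors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correction_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Randomly remove tags to a fixed fraction
#'
#' Keeps `round(factor * n)` tags (round-half-to-even), sampled uniformly
#' without replacement; the survivors keep their input order.  Deterministic
#' given `seed`.
#'
#' @param tags `GRanges` of tags.
#' @param factor Retention fraction in (0, 1].
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @return Downsampled `GRanges`.
#' @export
downsample_tags <- function(tags, factor, seed = NULL) {
  if (!(is.numeric(factor) && length(factor) == 1L && factor > 0 &&
        factor <= 1)) {
    stop("factor must be in (0, 1]")
  }
  n <- length(tags)
  size <- round(factor * n)
  if (size >= n) return(tags)
  keep <- with_seed(seed, sort(sample.int(n, size)))
  tags[keep]
}

#' Standard sequencing-depth normalization
#'
#' Downsamples every sample's experimental-species tags to the count of the
#' sample with the fewest, the conventional equal-depth normalization that a
#' spike-in is designed to replace.  The smallest sample is unchanged.
#'
#' @param samples List of [sample_library()] objects (>= 2).
#' @param species Experimental species label.
#' @param seed Integer seed.
#' @return List of libraries with equalized experimental tag counts.
#' @export
standard_normalize <- function(samples, species, seed = 1L) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  counts <- vapply(samples, function(s) length(s$tags[[species]]), integer(1L))
  target <- min(counts)
  seeds <- derive_seeds(seed, length(samples))
  lapply(seq_along(samples), function(i) {
    lib <- samples[[i]]
    if (counts[i] > target) {
      lib$tags[[species]] <- downsample_tags(lib$tags[[species]],
                                             target / counts[i], seeds[i])
    }
    lib
  })
}

#' Apply spike-in correction factors
#'
#' Downsamples each sample's experimental-species tags by its applied factor
#' from the correction table; reference-species tags are left untouched.
#'
#' @param samples List of [sample_library()] objects.
#' @param table A `correction_table` covering every sample id.
#' @param species Experimental species label.
#' @param seed Integer seed.
#' @return List of normalized libraries, in input order.
#' @export
spike_normalize <- function(samples, table, species, seed = 1L) {
  stopifnot(is.list(samples), inherits(table, "correction_table"))
  ids <- vapply(samples, function(s) s$sample_id, character(1L))
  missing <- setdiff(ids, table$sample_id)
  if (length(missing)) {
    stop("no correction factor for sample(s): ",
         paste(missing, collapse = ", "))
  }
  seeds <- derive_seeds(seed, length(samples))
  lapply(seq_along(samples), function(i) {
    lib <- samples[[i]]
    f <- table$applied_factor[match(ids[i], table$sample_id)]
    if (f < 1) {
      lib$tags[[species]] <- downsample_tags(lib$tags[[species]], f, seeds[i])
    }
    lib
  })
}
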