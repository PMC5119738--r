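# Union peak regions across conditions and per-region average signal, the
# quantities behind the scatter and box summaries used to compare control and
# treated occupancy.

#' Union of island sets across samples
#'
#' Merges the islands of all samples into one sorted, disjoint region set, so
#' per-region signal can be compared across conditions on common intervals.
#' Commutative and associative in the input sets.
#'
#' @param ... `GRanges` island sets (or a single list of them).
#' @return A sorted, disjoint `GRanges`.
#' @export
union_regions <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !methods::is(sets[[1L]], "GRanges")) {
    sets <- sets[[1L]]
  }
  if (!length(sets)) stop("at least one island set is required")
  sets <- lapply(sets, GenomicRanges::granges)
  normalize_regions(suppressWarnings(do.call(c, unname(sets))))
}

#' Average signal per region
#'
#' The signal of a region is the total fragment bp overlapping it divided by
#' its length, in fragments-per-bp: length-normalized, additive over disjoint
#' fragment subsets, and zero where nothing overlaps.
#'
#' @param regions Normalized `GRanges` (see [normalize_regions()]).
#' @param fragments `GRanges` of extended fragments for one sample.
#' @return Numeric vector, one value per region.
#' @export
region_signal <- function(regions, fragments) {
  sig <- numeric(length(regions))
  if (!length(regions) || !length(fragments)) return(sig)
  ov <- GenomicRanges::findOverlaps(regions, fragments, ignore.strand = TRUE)
  if (!length(ov)) return(sig)
  inter <- GenomicRanges::pintersect(
    regions[S4Vectors::queryHits(ov)],
    GenomicRanges::granges(fragments)[S4Vectors::subjectHits(ov)],
    ignore.strand = TRUE)
  bp <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(ov), sum)
  sig[as.integer(names(bp))] <- as.numeric(bp)
  sig / GenomicRanges::width(regions)
}

#' Per-region signal matrix across samples
#'
#' One row per region, one column per sample, values in fragments-per-bp
#' ([region_signal()]); raw overlapping-fragment counts are kept alongside for
#' transparency.  Each sample's genome-wide mean signal (total fragment bp
#' over genome bp) is recorded and later used for the fold-change pseudocount.
#'
#' @param regions Normalized `GRanges`.
#' @param fragments Named list, sample id -> `GRanges` of fragments.
#' @param genome A [genome_layout()] (for the genome-wide means).
#' @return An object of class `region_signal_matrix` with elements `regions`,
#'   `signal` (matrix), `counts` (matrix of overlapping-fragment counts) and
#'   `depth` (named vector of genome-wide mean signals).
#' @export
region_signal_matrix <- function(regions, fragments, genome) {
  stopifnot(is.list(fragments), !is.null(names(fragments)),
            inherits(genome, "genome_layout"))
  regions <- normalize_regions(regions)
  signal <- do.call(cbind, lapply(fragments, function(fr) {
    region_signal(regions, fr)
  }))
  counts <- do.call(cbind, lapply(fragments, function(fr) {
    GenomicRanges::countOverlaps(regions, fr, ignore.strand = TRUE)
  }))
  depth <- vapply(fragments, function(fr) {
    sum(as.numeric(GenomicRanges::width(fr))) / total_length(genome)
  }, numeric(1L))
  structure(list(regions = regions, signal = signal, counts = counts,
                 depth = depth),
            class = "region_signal_matrix")
}

#' @export
print.region_signal_matrix <- function(x, ...) {
  cat(sprintf("region_signal_matrix: %d regions x %d samples\n",
              nrow(x$signal), ncol(x$signal)))
  invisible(x)
}

#' Fold-change summary between two samples
#'
#' Per-region ratios `(signal_a + eps) / (signal_b + eps)` with a pseudocount
#' `eps` for stability at weak regions; by convention sample *a* is the
#' control and sample *b* the treated sample.  Reports the median ratio,
#' quartiles, and per-region log2 ratios for scatter/box export.
#'
#' @param mat A [region_signal_matrix()].
#' @param sample_a,sample_b Column names (control, treated).
#' @param pseudocount Pseudocount; defaults to 0.1 times the mean of the two
#'   samples' genome-wide mean signals.
#' @return An object of class `fold_change_summary`: `median_ratio`, `q1`,
#'   `q3`, `ratios`, `log2_ratios`, `pseudocount`, `n_regions`.
#' @export
fold_change_summary <- function(mat, sample_a, sample_b, pseudocount = NULL) {
  stopifnot(inherits(mat, "region_signal_matrix"))
  for (s in c(sample_a, sample_b)) {
    if (!s %in% colnames(mat$signal)) stop("no such sample: ", s)
  }
  eps <- pseudocount %||% (0.1 * mean(mat$depth[c(sample_a, sample_b)]))
  if (!(is.numeric(eps) && length(eps) == 1L && eps >= 0)) {
    stop("pseudocount must be a non-negative number")
  }
  a <- mat$signal[, sample_a]
  b <- mat$signal[, sample_b]
  ratios <- (a + eps) / (b + eps)
  q <- stats::quantile(ratios, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(sample_a = sample_a, sample_b = sample_b,
                 median_ratio = q[2L], q1 = q[1L], q3 = q[3L],
                 ratios = ratios, log2_ratios = log2(ratios),
                 pseudocount = eps, n_regions = length(ratios)),
            class = "fold_change_summary")
}

#' @export
print.fold_change_summary <- function(x, ...) {
  cat(sprintf("fold change %s / %s over %d regions\n", x$sample_a, x$sample_b,
              x$n_regions))
  cat(sprintf("  median ratio %.3f  [Q1 %.3f, Q3 %.3f]  (pseudocount %.4g)\n",
              x$median_ratio, x$q1, x$q3, x$pseudocount))
  invisible(x)
}

#' Export per-region signals of two samples as TSV
#'
#' One row per region with both samples' signals, the data behind a scatter
#' plot; plottable by any tool.
#'
#' @param mat A [region_signal_matrix()].
#' @param sample_a,sample_b Column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_scatter_data <- function(mat, sample_a, sample_b, path) {
  stopifnot(inherits(mat, "region_signal_matrix"))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(mat$regions)),
    start = GenomicRanges::start(mat$regions) - 1L,
    end = GenomicRanges::end(mat$regions),
    a = mat$signal[, sample_a],
    b = mat$signal[, sample_b])
  names(df)[4:5] <- c(sample_a, sample_b)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Box-plot summary per sample
#'
#' Tukey five-number summary of each sample's per-region signals: quartiles
#' and whiskers at the most extreme values within 1.5 IQR of the box.
#'
#' @param mat A [region_signal_matrix()].
#' @return Data frame with columns `sample`, `lower_whisker`, `q1`, `median`,
#'   `q3`, `upper_whisker`.
#' @export
box_summary <- function(mat) {
  stopifnot(inherits(mat, "region_signal_matrix"))
  rows <- lapply(colnames(mat$signal), function(s) {
    v <- mat$signal[, s]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    lw <- min(v[v >= q[1L] - 1.5 * iqr])
    uw <- max(v[v <= q[3L] + 1.5 * iqr])
    data.frame(sample = s, lower_whisker = lw, q1 = q[1L], median = q[2L],
               q3 = q[3L], upper_whisker = uw)
  })
  do.call(rbind, rows)
}

#' Write a region signal matrix as TSV
#'
#' Columns: `chrom`, `start`, `end`, then one signal column per sample.
#'
#' @param mat A [region_signal_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "region_signal_matrix"))
  df <- cbind(
    data.frame(chrom = as.character(GenomicRanges::seqnames(mat$regions)),
               start = GenomicRanges::start(mat$regions) - 1L,
               end = GenomicRanges::end(mat$regions)),
    as.data.frame(mat$signal))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
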