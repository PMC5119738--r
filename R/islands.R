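# Broad-domain island calling against a random (Poisson) background, in the
# style of clustered-window callers for diffuse histone marks: fixed-width
# windows, an eligibility count cutoff, bounded gaps between eligible
# windows, summed -log Poisson window scores, and a score threshold chosen so
# the expected number of passing islands under the background alone equals a
# requested E-value.

#' Island-calling parameters
#'
#' @param window Window width in bp (default 200).
#' @param gap Maximum gap in bp between eligible windows within one island;
#'   must be a multiple of `window`.  Conventionally 600 for the broad marks
#'   H3K27me3/H3K9me3 and 200 for H3K4me3.
#' @param e_value Expected number of islands at or above the score threshold
#'   under the random background (default 1).
#' @param effective_genome_fraction Fraction of the genome alignable tags can
#'   land on, in (0, 1]; scales the background rate (default 0.74, a common
#'   value for the human genome; use 1 for synthetic genomes).
#' @param p0 Poisson upper-tail probability defining window eligibility
#'   (default 0.2).
#' @param mc_draws Number of Monte-Carlo background genomes used to set the
#'   score threshold (default 10000).
#' @param seed Seed for the threshold Monte Carlo (default 1).
#' @return An object of class `island_params`.
#' @export
island_params <- function(window = 200L, gap = 600L, e_value = 1,
                          effective_genome_fraction = 0.74, p0 = 0.2,
                          mc_draws = 10000L, seed = 1L) {
  stopifnot(is_count(window), window > 0, is_count(gap),
            is.numeric(e_value), length(e_value) == 1L, e_value > 0,
            is.numeric(effective_genome_fraction),
            effective_genome_fraction > 0, effective_genome_fraction <= 1,
            is.numeric(p0), p0 > 0, p0 < 1,
            is_count(mc_draws), mc_draws >= 100)
  if (gap %% window != 0) {
    stop("gap must be an integer multiple of the window width")
  }
  structure(list(window = as.integer(window), gap = as.integer(gap),
                 e_value = e_value,
                 effective_genome_fraction = effective_genome_fraction,
                 p0 = p0, mc_draws = as.integer(mc_draws),
                 seed = as.integer(seed)),
            class = "island_params")
}

# number of windows per chromosome
n_windows <- function(genome, window) {
  stats::setNames(as.integer(ceiling(genome$lengths / window)), genome$chrom)
}

#' Per-window tag counts
#'
#' Each element (tag or fragment) is counted once, in the window containing
#' its midpoint, so window counts sum to the input size.
#'
#' @param x `GRanges` of tags or fragments.
#' @param genome A [genome_layout()].
#' @param window Window width in bp.
#' @return Named list, chromosome -> integer vector of window counts
#'   (length `ceiling(length / window)`).
#' @export
window_counts <- function(x, genome, window = 200L) {
  stopifnot(inherits(genome, "genome_layout"))
  nw <- n_windows(genome, window)
  counts <- lapply(nw, integer)
  if (!length(x)) return(counts)
  chrom <- as.character(GenomicRanges::seqnames(x))
  bad <- setdiff(unique(chrom), genome$chrom)
  if (length(bad)) {
    stop("elements on chromosome(s) absent from layout: ",
         paste(bad, collapse = ", "))
  }
  # midpoint of the 0-based half-open interval, left-rounded
  mid0 <- (GenomicRanges::start(x) - 1 + GenomicRanges::end(x)) %/% 2
  win <- mid0 %/% window + 1L
  for (ch in unique(chrom)) {
    idx <- chrom == ch
    counts[[ch]] <- tabulate(win[idx], nbins = nw[[ch]])
  }
  counts
}

#' Smallest eligible window count for a background rate
#'
#' Returns the smallest integer `k >= 1` whose Poisson upper-tail probability
#' `P(X >= k)` falls below `p0`, i.e. the least count that is "surprising"
#' under the background.
#'
#' @param lambda Background tag rate per window (> 0).
#' @param p0 Tail probability cutoff (default 0.2).
#' @return Integer eligibility threshold.
#' @export
eligibility_threshold <- function(lambda, p0 = 0.2) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > 0,
            is.numeric(p0), p0 > 0, p0 < 1)
  k <- 1L
  # P(X >= k) = ppois(k - 1, lower.tail = FALSE)
  while (ppois(k - 1, lambda, lower.tail = FALSE) >= p0) {
    k <- k + 1L
  }
  k
}

#' Score of one window
#'
#' The score of an eligible window (count at or above `min_count`) is the
#' negative log of the Poisson probability mass at the observed count;
#' ineligible windows score 0.  Monotonically increasing in the count above
#' the background rate.
#'
#' @param count Integer tag count(s); vectorized.
#' @param lambda Background rate per window (> 0).
#' @param min_count Eligibility threshold (see [eligibility_threshold()]).
#' @return Numeric score(s) `>= 0`.
#' @export
window_score <- function(count, lambda, min_count = 1L) {
  if (!(is.numeric(lambda) && length(lambda) == 1L && lambda > 0)) {
    stop("lambda must be a positive number")
  }
  ifelse(count >= min_count, -dpois(count, lambda, log = TRUE), 0)
}

#' Cluster eligible windows into candidate islands
#'
#' Maximal runs of eligible windows in which consecutive eligible windows are
#' separated by at most `gap_windows` ineligible windows.  An island spans
#' from the start of its first eligible window to the end of its last; its
#' score is the sum of its eligible windows' scores; its tag count sums every
#' window in the span.  Islands are disjoint and every eligible window belongs
#' to exactly one island.
#'
#' @param counts Named list of per-window counts (see [window_counts()]).
#' @param scores Named list of per-window scores, parallel to `counts`.
#' @param min_count Eligibility threshold.
#' @param gap_windows Maximum number of ineligible windows bridged.
#' @param genome A [genome_layout()].
#' @param window Window width in bp.
#' @return `GRanges` of candidate islands with metadata columns `score` and
#'   `tag_count`, window-aligned (the last window may be clipped at the
#'   chromosome end).
#' @export
assemble_islands <- function(counts, scores, min_count, gap_windows,
                             genome, window) {
  out <- list()
  for (ch in genome$chrom) {
    cnt <- counts[[ch]]
    idx <- which(cnt >= min_count)
    if (!length(idx)) next
    cluster <- cumsum(c(TRUE, diff(idx) > gap_windows + 1L))
    first <- idx[!duplicated(cluster)]
    last <- idx[!duplicated(cluster, fromLast = TRUE)]
    sc <- as.numeric(tapply(scores[[ch]][idx], cluster, sum))
    csum <- cumsum(c(0L, cnt))
    tag_count <- csum[last + 1L] - csum[first]
    len <- unname(genome$lengths[[ch]])
    out[[ch]] <- GenomicRanges::GRanges(
      seqnames = ch,
      ranges = IRanges::IRanges(start = (first - 1L) * window + 1L,
                                end = pmin(last * window, len)),
      score = sc, tag_count = as.integer(tag_count),
      seqinfo = as_seqinfo(genome)
    )
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges(seqinfo = as_seqinfo(genome))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(score = numeric(0),
                                                 tag_count = integer(0))
    return(gr)
  }
  do.call(c, unname(out))
}

#' Island-score threshold for an E-value by Monte Carlo
#'
#' Simulates `mc_draws` background genomes in which every window receives an
#' independent Poisson(`lambda`) count -- the large-sample limit of placing
#' `n_tags` uniformly on the effective genome -- assembles islands under the
#' same eligibility and gap rules as the caller, and returns the smallest
#' score cutoff at which the expected number of passing islands per genome is
#' at most `e_value`.  Deterministic given `params$seed`; decreasing the
#' E-value can only raise the threshold.
#'
#' @param genome A [genome_layout()].
#' @param n_tags Number of tags the sample places on the genome (> 0).
#' @param params An [island_params()].
#' @return Score threshold (numeric), with attributes `lambda` and
#'   `min_count`.
#' @export
score_threshold_mc <- function(genome, n_tags, params = island_params()) {
  stopifnot(inherits(genome, "genome_layout"), is_count(n_tags), n_tags > 0)
  lambda <- n_tags * params$window /
    (params$effective_genome_fraction * total_length(genome))
  min_count <- eligibility_threshold(lambda, params$p0)
  gap_windows <- params$gap %/% params$window
  thr <- if (is.infinite(params$e_value)) {
    0
  } else {
    with_seed(params$seed,
              .null_score_threshold_cpp(params$mc_draws,
                                        unname(n_windows(genome, params$window)),
                                        lambda, min_count, gap_windows,
                                        params$e_value))
  }
  structure(thr, lambda = lambda, min_count = min_count)
}

#' Call enriched islands in one sample
#'
#' The background rate is `lambda = n * window / (egf * G)` for `n` input
#' fragments on a genome of `G` bp with effective fraction `egf`.  Fragments
#' are counted by midpoint into windows, eligible windows are clustered across
#' gaps of at most `params$gap` bp, and candidate islands are kept when their
#' summed score reaches the E-value threshold (computed by
#' [score_threshold_mc()] unless supplied).
#'
#' @param fragments `GRanges` of preprocessed fragments (one sample, one
#'   species).
#' @param genome A [genome_layout()].
#' @param params An [island_params()].
#' @param threshold Optional precomputed score threshold; when `NULL` it is
#'   estimated by Monte Carlo under `params`.
#' @return `GRanges` of islands, sorted, with metadata columns `score` and
#'   `tag_count`; `S4Vectors::metadata()` records `lambda`, `min_count`,
#'   `threshold` and `n_tags`.  Zero fragments yield an empty result with a
#'   warning.
#' @export
call_islands <- function(fragments, genome, params = island_params(),
                         threshold = NULL) {
  stopifnot(inherits(genome, "genome_layout"),
            inherits(params, "island_params"))
  empty <- GenomicRanges::GRanges(seqinfo = as_seqinfo(genome))
  S4Vectors::mcols(empty) <- S4Vectors::DataFrame(score = numeric(0),
                                                  tag_count = integer(0))
  if (!length(fragments)) {
    warning("no fragments supplied; no islands called")
    return(empty)
  }
  n <- length(fragments)
  if (is.null(threshold)) {
    threshold <- score_threshold_mc(genome, n, params)
  }
  lambda <- attr(threshold, "lambda") %||%
    (n * params$window /
       (params$effective_genome_fraction * total_length(genome)))
  min_count <- attr(threshold, "min_count") %||%
    eligibility_threshold(lambda, params$p0)
  counts <- window_counts(fragments, genome, params$window)
  scores <- lapply(counts, window_score, lambda = lambda,
                   min_count = min_count)
  islands <- assemble_islands(counts, scores, min_count,
                              params$gap %/% params$window, genome,
                              params$window)
  islands <- sort(islands[S4Vectors::mcols(islands)$score >= as.numeric(threshold)])
  S4Vectors::metadata(islands) <- list(lambda = lambda, min_count = min_count,
                                       threshold = as.numeric(threshold),
                                       n_tags = n)
  islands
}

#' Write islands as BED5 and a full-precision TSV
#'
#' The BED score column rescales island scores to 0--1000; the TSV keeps full
#' precision and tag counts.
#'
#' @param islands `GRanges` from [call_islands()].
#' @param bed_path,tsv_path Output paths (`NULL` to skip one of them).
#' @return Invisibly, a character vector of the files written.
#' @export
write_islands <- function(islands, bed_path = NULL, tsv_path = NULL) {
  sc <- S4Vectors::mcols(islands)$score
  written <- character(0)
  if (!is.null(bed_path)) {
    scaled <- if (length(sc) && max(sc) > 0) {
      as.integer(round(1000 * sc / max(sc)))
    } else {
      integer(length(sc))
    }
    con <- file(bed_path, open = "wt")
    if (length(islands)) {
      writeLines(sprintf("%s\t%d\t%d\tisland_%d\t%d",
                         as.character(GenomicRanges::seqnames(islands)),
                         GenomicRanges::start(islands) - 1L,
                         GenomicRanges::end(islands),
                         seq_along(islands), scaled),
                 con)
    }
    close(con)
    written <- c(written, bed_path)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(islands)),
      start = GenomicRanges::start(islands) - 1L,
      end = GenomicRanges::end(islands),
      name = if (length(islands)) sprintf("island_%d", seq_along(islands)) else character(0),
      score = sc,
      tag_count = S4Vectors::mcols(islands)$tag_count
    )
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}
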