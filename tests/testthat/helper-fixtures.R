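# Shared fixtures and independent oracles, built in code at test time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

tiny_layout <- function(species = "human", chrom = c("chrA", "chrB"),
                        lengths = c(10000, 8000)) {
  genome_layout(species, chrom, lengths)
}

# random tags on a layout, drawn under a local seed
random_tags <- function(n, layout, seed = 1, tag_len = 50,
                        mapq = rep(60L, n)) {
  spikechip:::with_seed(seed, {
    chrom <- sample(layout$chrom, n, replace = TRUE, prob = layout$lengths)
    len <- unname(layout$lengths[chrom])
    start <- floor(runif(n, 1, len - tag_len))
    GRanges(factor(chrom, levels = layout$chrom),
            IRanges(start, width = tag_len),
            strand = sample(c("+", "-"), n, TRUE),
            mapq = as.integer(mapq),
            seqinfo = as_seqinfo(layout))
  })
}

write_bed6 <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

# brute-force per-bp coverage of one chromosome (independent of bin_coverage)
brute_coverage_vector <- function(fragments, chrom, len) {
  v <- numeric(len)
  fr <- fragments[as.character(seqnames(fragments)) == chrom]
  for (i in seq_along(fr)) {
    v[start(fr)[i]:end(fr)[i]] <- v[start(fr)[i]:end(fr)[i]] + 1
  }
  v
}

# independent island enumeration: linear scan over windows applying the
# eligibility / gap / score rules directly
oracle_islands <- function(fragments, genome, window, gap, lambda, min_count,
                           threshold) {
  rows <- list()
  for (ch in genome$chrom) {
    len <- unname(genome$lengths[[ch]])
    nw <- ceiling(len / window)
    cnt <- integer(nw)
    fr <- fragments[as.character(seqnames(fragments)) == ch]
    for (i in seq_along(fr)) {
      mid0 <- (start(fr)[i] - 1 + end(fr)[i]) %/% 2
      w <- mid0 %/% window + 1L
      cnt[w] <- cnt[w] + 1L
    }
    elig <- which(cnt >= min_count)
    if (!length(elig)) next
    gwin <- gap %/% window
    run_start <- elig[1]; prev <- elig[1]
    members <- list(); cur <- c(elig[1])
    flush <- function(first, last, members_idx) {
      sc <- sum(-dpois(cnt[members_idx], lambda, log = TRUE))
      if (sc >= threshold) {
        rows[[length(rows) + 1L]] <<- data.frame(
          chrom = ch, start = (first - 1L) * window + 1L,
          end = min(last * window, len), score = sc,
          tag_count = sum(cnt[first:last]))
      }
    }
    if (length(elig) > 1) {
      for (e in elig[-1]) {
        if (e - prev > gwin + 1L) {
          flush(run_start, prev, cur)
          run_start <- e; cur <- c(e)
        } else {
          cur <- c(cur, e)
        }
        prev <- e
      }
    }
    flush(run_start, prev, cur)
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      tag_count = integer(0)))
  }
  df <- do.call(rbind, rows)
  df[order(match(df$chrom, genome$chrom), df$start), , drop = FALSE]
}

islands_to_df <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr), score = mcols(gr)$score,
             tag_count = mcols(gr)$tag_count)
}

# uniform background fragments, the pure-noise input for calibration tests
uniform_fragments <- function(n, layout, seed, width = 200) {
  spikechip:::with_seed(seed, {
    chrom <- sample(layout$chrom, n, replace = TRUE, prob = layout$lengths)
    len <- unname(layout$lengths[chrom])
    start <- floor(runif(n, 1, len - width))
    GRanges(factor(chrom, levels = layout$chrom), IRanges(start, width = width),
            seqinfo = as_seqinfo(layout))
  })
}

# closed-form expected restricted reference count after duplicate removal:
# n tags land uniformly in the spike-in regions (B bp of 5' keys per strand);
# plus-strand 5' ends always fall inside, minus-strand ends only on the first
# width - (tag_length - 1) positions of each region
expected_restricted_count <- function(n, region_widths, tag_length) {
  B <- sum(region_widths)
  Bp <- sum(pmax(region_widths - (tag_length - 1), 0))
  (B + Bp) * (1 - (1 - 1 / B)^(n / 2))
}

# spike-derived correction factor truth, saturation-corrected
corrected_truth_factor <- function(expt) {
  N <- expt$config$depth
  w <- width(expt$regions$h2av)
  e_count <- function(cond) {
    tw <- expt$truth[[cond]]
    n <- N * tw$weight_by_compartment$h2av / tw$total_weight
    expected_restricted_count(n, w, expt$config$tag_length)
  }
  e_count("control") / e_count("treated")
}

# shared quantification path used by the acceptance tests: preprocess both
# conditions, normalize by the requested method, call islands, quantify, and
# return the control/treated median region ratio
experiment_median_ratio <- function(expt, method, seed) {
  cfg <- expt$config
  pre_c <- preprocess_library(expt$control)
  pre_t <- preprocess_library(expt$treated)
  libs <- list(pre_c$library, pre_t$library)
  sp <- cfg$exp_layout$species
  ref_sp <- cfg$ref_layout$species
  if (method == "standard") {
    norm <- standard_normalize(libs, sp, seed)
  } else {
    cnt <- c(control = count_reference_tags(libs[[1]], ref_sp, "restricted",
                                            expt$regions$h2av),
             treated = count_reference_tags(libs[[2]], ref_sp, "restricted",
                                            expt$regions$h2av))
    tab <- compute_correction_factors(cnt, "control", "restricted")
    norm <- spike_normalize(libs, tab, sp, seed)
  }
  frags <- lapply(norm, function(l) extend_tags(l$tags[[sp]], 200))
  names(frags) <- c("control", "treated")
  ip <- island_params(window = 200, gap = 600, e_value = 1,
                      effective_genome_fraction = 1, seed = seed)
  isl <- lapply(frags, call_islands, genome = cfg$exp_layout, params = ip)
  regions <- union_regions(isl)
  mat <- region_signal_matrix(regions, frags, cfg$exp_layout)
  fold_change_summary(mat, "control", "treated")$median_ratio
}
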