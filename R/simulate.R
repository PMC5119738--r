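# Two-species library simulator.  It reproduces the statistical structure the
# spike-in method assumes: broad enriched domains on the experimental genome,
# a uniform multiplicative global signal change between conditions, a constant
# spike-in compartment recovered from reference regions, an optional
# cross-reactive reference compartment that grows as the experimental target
# is depleted, and -- crucially -- a final fixed-depth sequencing step that
# equalizes library sizes and thereby erases the global change from raw
# counts.

#' Simulation configuration
#'
#' Pre-sequencing pull-down is modeled as weighted compartments; sequencing
#' draws exactly `depth` tags from the compartment weights (multinomial), with
#' positions uniform within compartments.  In the treated condition the whole
#' experimental-species pull-down (domains and diffuse background alike) is
#' scaled by `1 / fold_change` -- a uniform global loss of the target mark --
#' while the reference compartment recovered by the spike-in antibody keeps
#' its absolute weight.  With `cross_reactivity > 0` an extra reference
#' compartment, disjoint from the spike-in regions, receives weight
#' `cross_reactivity * (1 - 1/fold_change)` times the spike-in weight,
#' mimicking pull-down of reference chromatin by freed experimental antibody.
#'
#' @param exp_layout Experimental-species [genome_layout()] (default four 1-Mb
#'   chromosomes labeled species `"human"`).
#' @param ref_layout Reference-species [genome_layout()] (default two 100-kb
#'   chromosomes labeled species `"fly"`).
#' @param n_domains,domain_width Number and width range (bp) of enriched
#'   domains on the experimental genome (default 60 domains of 2--20 kb).
#' @param n_h2av,h2av_width Number and width range of reference-antibody-bound
#'   regions (default 40 of 1--3 kb).
#' @param n_cross,cross_width Number and width range of cross-reactive
#'   reference regions, disjoint from the spike-in regions (default 20 of
#'   1--3 kb).
#' @param enrichment Fold tag density inside domains over background
#'   (default 20).
#' @param fold_change Global fold change F >= 1; treated signal is control/F
#'   everywhere on the experimental genome (default 4).
#' @param spike_fraction Expected fraction of the control pull-down that is
#'   reference spike-in material (default 0.02, the one-in-fifty design
#'   target).
#' @param cross_reactivity Cross-reactive pull-down per unit of freed
#'   experimental antibody, relative to the spike-in weight (default 0).
#' @param depth Sequenced tags per sample (default 2e5).
#' @param tag_length Tag length in bp (default 50).
#' @param mapq Mapping quality assigned to simulated tags (default 60).
#' @param dup_fraction Optional fraction of tags replaced by duplicates of
#'   other tags, for exercising duplicate removal (default 0).
#' @param low_mapq_fraction Optional fraction of tags assigned mapping quality
#'   0--25, for exercising the quality filter (default 0).
#' @param seed Master seed; region placement and both conditions' tag draws
#'   derive from it (default 1).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(exp_layout = genome_layout("human",
                                                         paste0("chrE", 1:4),
                                                         rep(1e6, 4)),
                              ref_layout = genome_layout("fly",
                                                         paste0("chrR", 1:2),
                                                         rep(1e5, 2)),
                              n_domains = 60L, domain_width = c(2000, 20000),
                              n_h2av = 40L, h2av_width = c(1000, 3000),
                              n_cross = 20L, cross_width = c(1000, 3000),
                              enrichment = 20, fold_change = 4,
                              spike_fraction = 0.02, cross_reactivity = 0,
                              depth = 2e5, tag_length = 50L, mapq = 60L,
                              dup_fraction = 0, low_mapq_fraction = 0,
                              seed = 1L) {
  stopifnot(inherits(exp_layout, "genome_layout"),
            inherits(ref_layout, "genome_layout"),
            is_count(n_domains), n_domains > 0,
            is_count(n_h2av), n_h2av > 0, is_count(n_cross),
            length(domain_width) == 2L, all(domain_width > 0),
            length(h2av_width) == 2L, length(cross_width) == 2L,
            is.numeric(enrichment), enrichment >= 1,
            is.numeric(fold_change), fold_change >= 1,
            is.numeric(spike_fraction), spike_fraction > 0,
            spike_fraction < 1,
            is.numeric(cross_reactivity), cross_reactivity >= 0,
            is_count(depth), depth > 0, is_count(tag_length), tag_length > 0,
            dup_fraction >= 0, dup_fraction < 1,
            low_mapq_fraction >= 0, low_mapq_fraction < 1)
  if (exp_layout$species == ref_layout$species) {
    stop("experimental and reference species labels must differ")
  }
  structure(list(exp_layout = exp_layout, ref_layout = ref_layout,
                 n_domains = as.integer(n_domains),
                 domain_width = sort(domain_width),
                 n_h2av = as.integer(n_h2av), h2av_width = sort(h2av_width),
                 n_cross = as.integer(n_cross),
                 cross_width = sort(cross_width),
                 enrichment = enrichment, fold_change = fold_change,
                 spike_fraction = spike_fraction,
                 cross_reactivity = cross_reactivity,
                 depth = as.integer(depth),
                 tag_length = as.integer(tag_length), mapq = as.integer(mapq),
                 dup_fraction = dup_fraction,
                 low_mapq_fraction = low_mapq_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# place non-overlapping intervals of the given widths on a layout:
# chromosomes drawn proportional to length, positions by stick-breaking of
# the free space; draws from the current RNG state
place_intervals <- function(layout, widths) {
  n <- length(widths)
  if (!n) return(GenomicRanges::GRanges(seqinfo = as_seqinfo(layout)))
  for (attempt in 1:100) {
    chrom_idx <- sample.int(length(layout$chrom), n, replace = TRUE,
                            prob = layout$lengths)
    ok <- TRUE
    for (ci in unique(chrom_idx)) {
      if (sum(widths[chrom_idx == ci]) >= layout$lengths[ci]) ok <- FALSE
    }
    if (ok) break
    if (attempt == 100) stop("cannot place intervals: widths exceed genome")
  }
  parts <- lapply(seq_along(layout$chrom), function(ci) {
    idx <- which(chrom_idx == ci)
    if (!length(idx)) return(NULL)
    w <- widths[idx]
    len <- unname(layout$lengths[ci])
    free <- len - sum(w)
    cuts <- sort(runif(length(w)))
    gaps <- floor(diff(c(0, cuts)) * free)
    starts <- cumsum(gaps) + cumsum(c(0, w[-length(w)])) + 1
    data.frame(chrom = layout$chrom[ci], start = starts,
               end = starts + w - 1, slot = idx)
  })
  df <- do.call(rbind, parts)
  df <- df[order(df$slot), ]
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = layout$chrom),
    ranges = IRanges::IRanges(df$start, df$end),
    seqinfo = as_seqinfo(layout))
  sort(gr)
}

# compartment table: one row per interval with its species, coordinates,
# pre-sequencing weight and compartment label
compartment_table <- function(config, regions, condition) {
  s <- if (condition == "treated") 1 / config$fold_change else 1
  f_cond <- if (condition == "treated") config$fold_change else 1

  dom <- regions$domains
  bg <- GenomicRanges::gaps(dom)
  bg <- bg[GenomicRanges::strand(bg) == "*"]
  dom_df <- data.frame(
    species = config$exp_layout$species,
    chrom = as.character(GenomicRanges::seqnames(dom)),
    start = GenomicRanges::start(dom), end = GenomicRanges::end(dom),
    compartment = "domain",
    weight = GenomicRanges::width(dom) * config$enrichment * s)
  bg_df <- data.frame(
    species = config$exp_layout$species,
    chrom = as.character(GenomicRanges::seqnames(bg)),
    start = GenomicRanges::start(bg), end = GenomicRanges::end(bg),
    compartment = "background",
    weight = GenomicRanges::width(bg) * 1 * s)

  w_exp_control <- sum(GenomicRanges::width(dom)) * config$enrichment +
    sum(GenomicRanges::width(bg))
  w_h2av_total <- config$spike_fraction / (1 - config$spike_fraction) *
    w_exp_control
  h2av <- regions$h2av
  h2av_df <- data.frame(
    species = config$ref_layout$species,
    chrom = as.character(GenomicRanges::seqnames(h2av)),
    start = GenomicRanges::start(h2av), end = GenomicRanges::end(h2av),
    compartment = "h2av",
    weight = w_h2av_total * GenomicRanges::width(h2av) /
      sum(GenomicRanges::width(h2av)))

  cross <- regions$cross
  w_cross_total <- config$cross_reactivity * (1 - 1 / f_cond) * w_h2av_total
  cross_df <- if (length(cross) && w_cross_total > 0) {
    data.frame(
      species = config$ref_layout$species,
      chrom = as.character(GenomicRanges::seqnames(cross)),
      start = GenomicRanges::start(cross), end = GenomicRanges::end(cross),
      compartment = "crossreact",
      weight = w_cross_total * GenomicRanges::width(cross) /
        sum(GenomicRanges::width(cross)))
  }
  tab <- rbind(dom_df, bg_df, h2av_df, cross_df)
  tab <- tab[tab$weight > 0, ]
  rownames(tab) <- NULL
  tab
}

#' Simulate one sample of a spike-in ChIP-seq experiment
#'
#' Draws exactly `config$depth` tags multinomially from the compartment
#' weights of the given condition (the fixed-depth sequencing step), with
#' positions uniform within compartments, strands uniform, and constant
#' mapping quality.  Region sets must be shared between conditions; pass the
#' `regions` element produced by [simulate_experiment()] (or leave `NULL` to
#' draw them from `config$seed`).
#'
#' @param config A [simulation_config()].
#' @param condition `"control"` or `"treated"`.
#' @param seed Seed for the tag draw.
#' @param regions List with elements `domains`, `h2av`, `cross` (shared
#'   between conditions), or `NULL`.
#' @return A list: `library` (a [sample_library()]) and `truth` (compartment
#'   weights, expected and realized tag proportions).
#' @export
simulate_sample <- function(config, condition = c("control", "treated"),
                            seed = config$seed, regions = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(regions)) {
    regions <- with_seed(config$seed, draw_region_sets(config))
  }
  tab <- compartment_table(config, regions, condition)
  if (!nrow(tab) || sum(tab$weight) <= 0) {
    stop("infeasible configuration: all compartment weights are zero")
  }
  layouts <- stats::setNames(list(config$exp_layout, config$ref_layout),
                             c(config$exp_layout$species,
                               config$ref_layout$species))
  chrom_len <- c(config$exp_layout$lengths, config$ref_layout$lengths)

  drawn <- with_seed(seed, {
    idx <- sample.int(nrow(tab), config$depth, replace = TRUE,
                      prob = tab$weight)
    iw <- tab$end[idx] - tab$start[idx] + 1
    start <- tab$start[idx] + floor(runif(config$depth) * iw)
    strand <- sample(c("+", "-"), config$depth, replace = TRUE)
    mapq <- rep(config$mapq, config$depth)
    if (config$dup_fraction > 0) {
      n_dup <- round(config$dup_fraction * config$depth)
      if (n_dup > 0) {
        to <- sample.int(config$depth, n_dup)
        from <- sample.int(config$depth, n_dup, replace = TRUE)
        idx[to] <- idx[from]
        start[to] <- start[from]
        strand[to] <- strand[from]
      }
    }
    if (config$low_mapq_fraction > 0) {
      n_low <- round(config$low_mapq_fraction * config$depth)
      if (n_low > 0) {
        lo <- sample.int(config$depth, n_low)
        mapq[lo] <- sample(0:25, n_low, replace = TRUE)
      }
    }
    list(idx = idx, start = start, strand = strand, mapq = mapq)
  })

  chrom <- tab$chrom[drawn$idx]
  end <- pmin(drawn$start + config$tag_length - 1, unname(chrom_len[chrom]))
  species <- tab$species[drawn$idx]

  buckets <- lapply(layouts, function(layout) {
    sel <- which(species == layout$species)
    GenomicRanges::GRanges(
      seqnames = factor(chrom[sel], levels = layout$chrom),
      ranges = IRanges::IRanges(drawn$start[sel], end[sel]),
      strand = drawn$strand[sel],
      mapq = as.integer(drawn$mapq[sel]),
      seqinfo = as_seqinfo(layout))
  })

  lib <- sample_library(condition, treatment = condition, mark = "H3K27me3",
                        tags = buckets, layouts = layouts)
  w_by_class <- tapply(tab$weight, tab$compartment, sum)
  expected <- w_by_class / sum(tab$weight)
  realized <- table(factor(tab$compartment[drawn$idx],
                           levels = names(w_by_class))) / config$depth
  truth <- list(condition = condition,
                total_weight = sum(tab$weight),
                weight_by_compartment = as.list(w_by_class),
                expected_proportions = as.list(expected),
                realized_proportions = as.list(as.numeric(realized) |>
                                                 stats::setNames(names(w_by_class))))
  list(library = lib, truth = truth)
}

# draw all three region sets under the current RNG state, keeping the
# spike-in and cross-reactive reference sets disjoint
draw_region_sets <- function(config) {
  dom_w <- round(runif(config$n_domains, config$domain_width[1L],
                       config$domain_width[2L]))
  domains <- place_intervals(config$exp_layout, dom_w)
  h2av_w <- round(runif(config$n_h2av, config$h2av_width[1L],
                        config$h2av_width[2L]))
  cross_w <- if (config$n_cross > 0) {
    round(runif(config$n_cross, config$cross_width[1L],
                config$cross_width[2L]))
  } else {
    numeric(0)
  }
  ref <- place_intervals(config$ref_layout, c(h2av_w, cross_w))
  # the two reference sets are placed jointly (guaranteeing disjointness) and
  # split by a random draw of which intervals carry the spike-in signal
  pick <- sample.int(length(ref), config$n_h2av)
  list(domains = domains,
       h2av = sort(ref[pick]),
       cross = sort(ref[setdiff(seq_along(ref), pick)]))
}

#' Simulate a paired control/treated spike-in experiment
#'
#' Draws the shared region sets and both conditions' libraries from
#' `config$seed` (condition seeds are derived, so the whole experiment is
#' reproducible from the one seed), and assembles the ground-truth record.
#'
#' @param config A [simulation_config()].
#' @return A list of class `spike_experiment`: `control` and `treated`
#'   ([sample_library()] objects), `regions` (domains, h2av, cross), `truth`
#'   (fold change, per-condition compartment bookkeeping, the expected
#'   spike-derived correction factor `expected_factor`, and the realized
#'   domain coverage fraction) and `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  setup <- with_seed(config$seed, {
    regions <- draw_region_sets(config)
    seeds <- sample.int(.Machine$integer.max - 1L, 2L)
    list(regions = regions, seeds = seeds)
  })
  regions <- setup$regions
  control <- simulate_sample(config, "control", setup$seeds[1L], regions)
  treated <- simulate_sample(config, "treated", setup$seeds[2L], regions)
  truth <- list(
    fold_change = config$fold_change,
    expected_factor = treated$truth$total_weight /
      control$truth$total_weight,
    domain_coverage = sum(GenomicRanges::width(regions$domains)) /
      total_length(config$exp_layout),
    control = control$truth,
    treated = treated$truth)
  structure(list(control = control$library, treated = treated$library,
                 regions = regions, truth = truth, config = config),
            class = "spike_experiment")
}

#' @export
print.spike_experiment <- function(x, ...) {
  cat(sprintf("spike_experiment: F=%g, depth=%d tags/sample, %d domains (%.1f%% of genome)\n",
              x$truth$fold_change, x$config$depth,
              length(x$regions$domains), 100 * x$truth$domain_coverage))
  cat(sprintf("  expected spike correction factor (treated vs control): %.4f\n",
              x$truth$expected_factor))
  invisible(x)
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Write a simulated experiment as a self-contained fixture directory
#'
#' Emits BED tag files per condition and species, chrom.sizes per species,
#' the spike-in region BED, a ground-truth JSON, and a ready-to-run pipeline
#' configuration (`config.yml`), so the directory is a complete pipeline
#' input.  Regenerating with the same config yields byte-identical files.
#'
#' @param experiment A `spike_experiment` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of files written.
#' @export
write_fixture <- function(experiment, dir) {
  stopifnot(inherits(experiment, "spike_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- experiment$config
  exp_sp <- cfg$exp_layout$species
  ref_sp <- cfg$ref_layout$species
  files <- c()
  for (cond in c("control", "treated")) {
    lib <- experiment[[cond]]
    for (sp in c(exp_sp, ref_sp)) {
      f <- file.path(dir, sprintf("%s_%s.bed", cond, sp))
      write_tags(lib$tags[[sp]], f)
      files[sprintf("tags_%s_%s", cond, sp)] <- f
    }
  }
  f <- file.path(dir, paste0(exp_sp, ".chrom.sizes"))
  write_chrom_sizes(cfg$exp_layout, f)
  files["chrom_sizes_exp"] <- f
  f <- file.path(dir, paste0(ref_sp, ".chrom.sizes"))
  write_chrom_sizes(cfg$ref_layout, f)
  files["chrom_sizes_ref"] <- f
  f <- file.path(dir, "h2av_regions.bed")
  write_regions(experiment$regions$h2av, f)
  files["h2av_regions"] <- f

  truth <- experiment$truth
  truth$domains <- granges_to_df(experiment$regions$domains)
  truth$h2av_regions <- granges_to_df(experiment$regions$h2av)
  truth$cross_regions <- granges_to_df(experiment$regions$cross)
  truth$schema_version <- 1L
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files["truth"] <- f

  run_cfg <- list(
    samples = list(
      list(id = "control", treatment = "control", mark = lib_mark(experiment$control),
           tags = stats::setNames(list(basename(files[[sprintf("tags_control_%s", exp_sp)]]),
                                       basename(files[[sprintf("tags_control_%s", ref_sp)]])),
                                  c(exp_sp, ref_sp))),
      list(id = "treated", treatment = "treated", mark = lib_mark(experiment$treated),
           tags = stats::setNames(list(basename(files[[sprintf("tags_treated_%s", exp_sp)]]),
                                       basename(files[[sprintf("tags_treated_%s", ref_sp)]])),
                                  c(exp_sp, ref_sp)))),
    genomes = stats::setNames(list(basename(files[["chrom_sizes_exp"]]),
                                   basename(files[["chrom_sizes_ref"]])),
                              c(exp_sp, ref_sp)),
    experimental_species = exp_sp,
    reference_species = ref_sp,
    reference_sample = "control",
    counting_mode = "restricted",
    regions = basename(files[["h2av_regions"]]),
    gaps = list(H3K27me3 = 600L, H3K9me3 = 600L, H3K4me3 = 200L),
    island = list(window = 200L, e_value = 1,
                  effective_genome_fraction = 1.0, p0 = 0.2,
                  mc_draws = 10000L),
    preprocess = list(min_mapq = 25L, extension = 200L, bin_width = 32L),
    seed = cfg$seed,
    output_dir = "out")
  f <- file.path(dir, "config.yml")
  yaml::write_yaml(run_cfg, f)
  files["config"] <- f
  invisible(files)
}

lib_mark <- function(lib) {
  if (is.na(lib$mark)) "H3K27me3" else lib$mark
}
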