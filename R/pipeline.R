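# Run-level configuration and the stage commands the CLI dispatches to.
# One declarative YAML file names the samples, genomes, reference sample,
# counting mode and per-mark island parameters; every stage is a function of
# the validated config so runs are reproducible from config + seed alone.

#' Read and validate a pipeline run configuration
#'
#' The YAML file names the samples (id, treatment, mark, per-species tag
#' files), the genome layouts, the experimental and reference species, the
#' reference sample the correction factors are computed against, the counting
#' mode (plus region BED when restricted), a mark -> gap map and the island
#' and preprocessing parameters.  Relative paths are resolved against the
#' config file's directory.  Validation failures raise a
#' `spikechip_config_error` before any computation.
#'
#' @param path Path to the YAML configuration.
#' @return A validated run configuration of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error(paste0("no such config file: ", path))
  cfg <- yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  cfg$.path <- normalizePath(path)
  validate_run_config(cfg)
}

resolve_path <- function(cfg, p) {
  if (startsWith(p, "/")) p else file.path(cfg$.dir, p)
}

validate_run_config <- function(cfg) {
  need <- c("samples", "genomes", "experimental_species",
            "reference_species", "reference_sample")
  missing <- need[!need %in% names(cfg)]
  if (length(missing)) {
    config_error(paste0("config is missing required field(s): ",
                        paste(missing, collapse = ", ")))
  }
  ids <- vapply(cfg$samples, function(s) s$id %||% NA_character_,
                character(1L))
  if (anyNA(ids) || anyDuplicated(ids)) {
    config_error("every sample needs a unique 'id'")
  }
  if (sum(ids == cfg$reference_sample) != 1L) {
    config_error(paste0("reference_sample '", cfg$reference_sample,
                        "' must match exactly one sample id"))
  }
  for (sp in c(cfg$experimental_species, cfg$reference_species)) {
    if (is.null(cfg$genomes[[sp]])) {
      config_error(paste0("no genome (chrom.sizes) declared for species '",
                          sp, "'"))
    }
  }
  marks <- unique(vapply(cfg$samples, function(s) s$mark %||% NA_character_,
                         character(1L)))
  marks <- marks[!is.na(marks)]
  no_gap <- marks[!marks %in% names(cfg$gaps %||% list())]
  if (length(no_gap)) {
    config_error(paste0("no gap size configured for mark(s): ",
                        paste(no_gap, collapse = ", ")))
  }
  cfg$counting_mode <- cfg$counting_mode %||% "restricted"
  if (!cfg$counting_mode %in% c("restricted", "whole_genome")) {
    config_error("counting_mode must be 'restricted' or 'whole_genome'")
  }
  if (cfg$counting_mode == "restricted" && is.null(cfg$regions)) {
    config_error("restricted counting requires a 'regions' BED file")
  }
  for (s in cfg$samples) {
    for (sp in names(s$tags)) {
      f <- resolve_path(cfg, s$tags[[sp]])
      if (!file.exists(f)) {
        config_error(paste0("sample '", s$id, "': missing tag file ", f))
      }
    }
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$output_dir <- cfg$output_dir %||% "out"
  class(cfg) <- "run_config"
  cfg
}

config_layouts <- function(cfg) {
  lapply(stats::setNames(names(cfg$genomes), names(cfg$genomes)),
         function(sp) read_chrom_sizes(resolve_path(cfg, cfg$genomes[[sp]]),
                                       sp))
}

config_preprocess_params <- function(cfg) {
  p <- cfg$preprocess %||% list()
  preprocess_params(min_mapq = p$min_mapq %||% 25L,
                    extension = p$extension %||% 200L,
                    bin_width = p$bin_width %||% 32L)
}

config_island_params <- function(cfg, mark) {
  p <- cfg$island %||% list()
  gap <- cfg$gaps[[mark]] %||% 600L
  island_params(window = p$window %||% 200L, gap = gap,
                e_value = p$e_value %||% 1,
                effective_genome_fraction =
                  p$effective_genome_fraction %||% 0.74,
                p0 = p$p0 %||% 0.2,
                mc_draws = p$mc_draws %||% 10000L,
                seed = cfg$seed)
}

#' Load every sample of a run configuration
#'
#' @param cfg A `run_config`.
#' @return Named list of [sample_library()] objects, in config order.
#' @export
load_samples <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  layouts <- config_layouts(cfg)
  libs <- lapply(cfg$samples, function(s) {
    tags <- lapply(stats::setNames(names(s$tags), names(s$tags)),
                   function(sp) {
      read_tags(resolve_path(cfg, s$tags[[sp]]), "bed6", layouts[[sp]])
    })
    sample_library(s$id, s$treatment %||% NA, s$mark %||% NA, tags,
                   layouts[names(tags)])
  })
  stats::setNames(libs, vapply(libs, `[[`, "", "sample_id"))
}

out_dir <- function(cfg) {
  d <- resolve_path(cfg, cfg$output_dir)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_provenance <- function(cfg, step, outdir, extra = list()) {
  rec <- c(list(step = step,
                config = basename(cfg$.path),
                config_md5 = unname(tools::md5sum(cfg$.path)),
                seed = cfg$seed,
                package = "spikechip",
                version = as.character(utils::packageVersion("spikechip"))),
           extra)
  jsonlite::write_json(rec, file.path(outdir, paste0(step, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Stage: simulate a fixture data set
#'
#' @param dir Output directory.
#' @param config A [simulation_config()].
#' @return The files written, invisibly.
#' @export
run_simulate <- function(dir, config = simulation_config()) {
  write_fixture(simulate_experiment(config), dir)
}

#' Stage: preprocess all samples
#'
#' Applies the mapping-quality and duplicate filters to every species bucket
#' of every sample, writes filtered tag BEDs and a per-sample counts report.
#'
#' @param cfg A `run_config` (see [read_run_config()]).
#' @return Invisibly, the list of preprocessed samples (as returned by
#'   [preprocess_library()]).
#' @export
run_preprocess <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  libs <- load_samples(cfg)
  params <- config_preprocess_params(cfg)
  outdir <- out_dir(cfg)
  pre <- lapply(libs, preprocess_library, params = params)
  for (p in pre) {
    for (sp in names(p$library$tags)) {
      write_tags(p$library$tags[[sp]],
                 file.path(outdir, sprintf("filtered_%s_%s.bed",
                                           p$library$sample_id, sp)))
    }
  }
  stats <- do.call(rbind, lapply(pre, `[[`, "stats"))
  utils::write.table(stats, file.path(outdir, "preprocess_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(cfg, "preprocess", outdir)
  invisible(pre)
}

#' Stage: call islands in every sample
#'
#' Preprocesses, then calls islands on each sample's experimental-species
#' fragments with the mark-specific gap size, writing BED5 and TSV per
#' sample.
#'
#' @param cfg A `run_config`.
#' @param samples Optional preprocessed samples from [run_preprocess()] to
#'   reuse.
#' @return Invisibly, a named list of island `GRanges`.
#' @export
run_callpeaks <- function(cfg, samples = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  pre <- samples %||% run_preprocess(cfg)
  outdir <- out_dir(cfg)
  layouts <- config_layouts(cfg)
  sp <- cfg$experimental_species
  islands <- lapply(pre, function(p) {
    ip <- config_island_params(cfg, lib_mark(p$library))
    isl <- call_islands(p$fragments[[sp]], layouts[[sp]], ip)
    write_islands(isl,
                  bed_path = file.path(outdir, sprintf("islands_%s.bed",
                                                       p$library$sample_id)),
                  tsv_path = file.path(outdir, sprintf("islands_%s.tsv",
                                                       p$library$sample_id)))
    isl
  })
  write_provenance(cfg, "callpeaks", outdir)
  invisible(islands)
}

#' Stage: normalize all samples
#'
#' `method = "spikein"` counts reference-species tags per the configured
#' counting mode, computes correction factors against the reference sample,
#' and downsamples experimental-species tags accordingly;
#' `method = "standard"` equalizes experimental-species depth instead.
#' Writes scaled tag BEDs and (for spike-in) the correction table TSV.
#'
#' @param cfg A `run_config`.
#' @param method `"spikein"` or `"standard"`.
#' @param samples Optional preprocessed samples to reuse.
#' @return Invisibly, a list with the normalized libraries and, for spike-in,
#'   the correction table.
#' @export
run_normalize <- function(cfg, method = c("spikein", "standard"),
                          samples = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(cfg, "run_config"))
  pre <- samples %||% run_preprocess(cfg)
  outdir <- out_dir(cfg)
  libs <- lapply(pre, `[[`, "library")
  table <- NULL
  if (method == "spikein") {
    regions <- if (cfg$counting_mode == "restricted") {
      read_regions(resolve_path(cfg, cfg$regions))
    }
    counts <- vapply(libs, count_reference_tags, numeric(1L),
                     reference_species = cfg$reference_species,
                     mode = cfg$counting_mode, regions = regions)
    table <- compute_correction_factors(counts, cfg$reference_sample,
                                        cfg$counting_mode)
    write_correction_table(table,
                           file.path(outdir, "correction_factors.tsv"))
    norm <- spike_normalize(libs, table, cfg$experimental_species,
                            seed = cfg$seed)
  } else {
    norm <- standard_normalize(libs, cfg$experimental_species,
                               seed = cfg$seed)
  }
  for (lib in norm) {
    write_tags(lib$tags[[cfg$experimental_species]],
               file.path(outdir, sprintf("normalized_%s_%s_%s.bed", method,
                                         lib$sample_id,
                                         cfg$experimental_species)))
  }
  write_provenance(cfg, paste0("normalize_", method), outdir)
  invisible(list(samples = norm, table = table))
}

#' Stage: quantify per-region signal across samples
#'
#' Runs the full chain: preprocess, normalize (spike-in by default), call
#' islands on the normalized samples, union the islands into common regions,
#' and compute per-region signal.  Writes the region signal matrix,
#' scatter-plot TSVs for every non-reference sample against the reference
#' sample, the box summary, and per-sample bedGraph coverage tracks.
#'
#' @param cfg A `run_config`.
#' @param method Normalization applied before quantification (`"spikein"`,
#'   `"standard"` or `"none"`).
#' @return Invisibly, a list with the [region_signal_matrix()], the island
#'   sets and the fold-change summaries.
#' @export
run_quantify <- function(cfg, method = c("spikein", "standard", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(cfg, "run_config"))
  pre <- run_preprocess(cfg)
  params <- config_preprocess_params(cfg)
  outdir <- out_dir(cfg)
  layouts <- config_layouts(cfg)
  sp <- cfg$experimental_species

  libs <- if (method == "none") {
    lapply(pre, `[[`, "library")
  } else {
    run_normalize(cfg, method, samples = pre)$samples
  }
  fragments <- lapply(libs, function(lib) {
    extend_tags(lib$tags[[sp]], params$extension)
  })
  names(fragments) <- vapply(libs, `[[`, "", "sample_id")

  islands <- lapply(seq_along(libs), function(i) {
    ip <- config_island_params(cfg, lib_mark(libs[[i]]))
    call_islands(fragments[[i]], layouts[[sp]], ip)
  })
  regions <- union_regions(islands)
  mat <- region_signal_matrix(regions, fragments, layouts[[sp]])
  write_signal_matrix(mat, file.path(outdir,
                                     sprintf("region_signal_%s.tsv", method)))
  utils::write.table(box_summary(mat),
                     file.path(outdir, sprintf("box_summary_%s.tsv", method)),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ref_id <- cfg$reference_sample
  summaries <- list()
  for (id in setdiff(names(fragments), ref_id)) {
    export_scatter_data(mat, ref_id, id,
                        file.path(outdir, sprintf("scatter_%s_vs_%s_%s.tsv",
                                                  ref_id, id, method)))
    summaries[[id]] <- fold_change_summary(mat, ref_id, id)
  }
  for (id in names(fragments)) {
    track <- bin_coverage(fragments[[id]], layouts[[sp]], params$bin_width)
    write_bedgraph(track, file.path(outdir, sprintf("coverage_%s_%s.bedgraph",
                                                    id, method)))
  }
  write_provenance(cfg, paste0("quantify_", method), outdir)
  invisible(list(matrix = mat, islands = islands, summaries = summaries))
}

#' Stage: spike-in design report
#'
#' @param experimental_mass,genome_copy_ratio,spike_mass,total_tags See
#'   [design_report()].
#' @param path Optional TSV output path.
#' @return The design report data frame.
#' @export
run_design <- function(experimental_mass, genome_copy_ratio = 27,
                       spike_mass = NULL, total_tags = 50e6, path = NULL) {
  rep <- design_report(experimental_mass, genome_copy_ratio, spike_mass,
                       total_tags)
  if (!is.null(path)) {
    utils::write.table(rep, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  rep
}
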