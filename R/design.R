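# Spike-in experimental-design arithmetic: how much reference chromatin to
# add, and how many reference tags to expect at a planned sequencing depth.

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0)) {
      stop("'", nm, "' must be a positive number")
    }
  }
  invisible(TRUE)
}

#' Spike-in mass for genome copy-number equality
#'
#' The reference genome being `genome_copy_ratio` times smaller than the
#' experimental genome, a mass ratio equal to that constant puts the two
#' species at equal genome copy number; the spike mass is therefore
#' `experimental_mass / genome_copy_ratio`.  With the conventional ratio of
#' 27 for human versus fly, 30 ug of human chromatin calls for 1.11 ug of
#' spike-in.
#'
#' @param experimental_mass Mass of experimental-species chromatin (ug).
#' @param genome_copy_ratio Experimental-to-reference genome size ratio
#'   (default 27).  A stated design constant, not recomputed from assembly
#'   lengths.
#' @return Spike-in mass in ug.
#' @export
spike_mass_for_copy_equality <- function(experimental_mass,
                                         genome_copy_ratio = 27) {
  check_positive(experimental_mass = experimental_mass,
                 genome_copy_ratio = genome_copy_ratio)
  experimental_mass / genome_copy_ratio
}

#' Expected reference tags at a planned sequencing depth
#'
#' Assuming the two antibodies precipitate the same amount of chromatin per
#' unit input, the expected number of reference-species tags is
#' `total_tags * spike_mass / experimental_mass` -- normalized by the
#' experimental mass (the arithmetic that makes 50 M tags with 1.11 ug spike
#' per 30 ug yield 1.85 M reference tags).
#'
#' @param total_tags Planned total sequenced tags.
#' @param spike_mass Spike-in chromatin mass (ug).
#' @param experimental_mass Experimental chromatin mass (ug).
#' @return Expected reference tag count.
#' @export
expected_reference_tags <- function(total_tags, spike_mass,
                                    experimental_mass) {
  check_positive(total_tags = total_tags, spike_mass = spike_mass,
                 experimental_mass = experimental_mass)
  total_tags * spike_mass / experimental_mass
}

#' Experimental-to-spike chromatin mass ratio
#'
#' @param experimental_mass Experimental chromatin mass (ug).
#' @param spike_mass Spike-in chromatin mass (ug).
#' @return Dimensionless mass ratio (e.g. 40 for 30 ug : 0.75 ug).
#' @export
mass_ratio <- function(experimental_mass, spike_mass) {
  check_positive(experimental_mass = experimental_mass,
                 spike_mass = spike_mass)
  experimental_mass / spike_mass
}

#' Spike-in design report
#'
#' Combines the design arithmetic into one table: the copy-equality spike
#' mass, the mass actually planned (defaulting to the copy-equality amount),
#' the resulting mass ratio, and the expected reference tag yield.
#'
#' @param experimental_mass Experimental chromatin mass (ug).
#' @param genome_copy_ratio Genome size ratio (default 27).
#' @param spike_mass Planned spike mass (ug); default is the copy-equality
#'   amount.
#' @param total_tags Planned sequencing depth in tags (default 50e6).
#' @return A one-row data frame.
#' @export
design_report <- function(experimental_mass, genome_copy_ratio = 27,
                          spike_mass = NULL, total_tags = 50e6) {
  equality_mass <- spike_mass_for_copy_equality(experimental_mass,
                                                genome_copy_ratio)
  spike_mass <- spike_mass %||% equality_mass
  check_positive(spike_mass = spike_mass)
  data.frame(
    experimental_mass_ug = experimental_mass,
    genome_copy_ratio = genome_copy_ratio,
    copy_equality_spike_ug = equality_mass,
    spike_mass_ug = spike_mass,
    mass_ratio = mass_ratio(experimental_mass, spike_mass),
    total_tags = total_tags,
    expected_reference_tags = expected_reference_tags(total_tags, spike_mass,
                                                      experimental_mass))
}
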