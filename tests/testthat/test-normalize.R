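# Reference-tag counting, correction factors, seeded downsampling.

make_two_species_lib <- function(id, n_hum, n_fly, seed) {
  hum <- tiny_layout("human")
  fly <- genome_layout("fly", c("chrR1", "chrR2"), c(6000, 4000))
  sample_library(id, "control", "H3K27me3",
                 list(human = random_tags(n_hum, hum, seed = seed),
                      fly = random_tags(n_fly, fly, seed = seed + 1)),
                 list(human = hum, fly = fly))
}

test_that("reference counting honors the two strategies", {
  lib <- make_two_species_lib("s", 50, 100, seed = 51)
  expect_equal(count_reference_tags(lib, "fly", "whole_genome"), 100L)

  # restricted counting uses the 5' position; brute-force membership oracle
  set.seed(52)
  regions <- normalize_regions(
    GRanges(sample(c("chrR1", "chrR2"), 8, TRUE),
            IRanges(sample.int(3000, 8), width = sample(200:900, 8))))
  got <- count_reference_tags(lib, "fly", "restricted", regions)
  tags <- lib$tags$fly
  p5 <- spikechip:::five_prime_pos(tags)
  manual <- 0L
  for (i in seq_along(tags)) {
    ch <- as.character(seqnames(tags))[i]
    inside <- any(as.character(seqnames(regions)) == ch &
                    start(regions) <= p5[i] & p5[i] <= end(regions))
    manual <- manual + inside
  }
  expect_equal(got, manual)
  expect_lte(got, length(tags))

  expect_error(count_reference_tags(lib, "yeast", "whole_genome"),
               "yeast")
  expect_error(count_reference_tags(lib, "fly", "restricted", GRanges()),
               "non-empty")
})

test_that("restricted counting ignores reference tags outside the regions", {
  # the asymmetry that motivates region-restricted counting: adding
  # cross-reactive pull-down outside the spike-in regions changes the
  # whole-genome count but not the restricted one
  lib <- make_two_species_lib("s", 20, 200, seed = 61)
  regions <- GRanges("chrR1", IRanges(1, 2000))
  before_r <- count_reference_tags(lib, "fly", "restricted", regions)
  before_w <- count_reference_tags(lib, "fly", "whole_genome")
  extra <- GRanges("chrR2", IRanges(seq(100, 1090, by = 10), width = 50),
                   strand = "+", mapq = rep(60L, 100))
  lib$tags$fly <- c(lib$tags$fly, GRanges(seqnames(extra), ranges(extra),
                                          strand = strand(extra),
                                          mapq = mcols(extra)$mapq,
                                          seqinfo = seqinfo(lib$tags$fly)))
  expect_equal(count_reference_tags(lib, "fly", "restricted", regions),
               before_r)
  expect_equal(count_reference_tags(lib, "fly", "whole_genome"),
               before_w + 100L)
})

test_that("correction factors follow the reference/test ratio, rescaled to 1", {
  tab <- compute_correction_factors(c(DMSO = 1e6, EPZ = 4e6), "DMSO")
  expect_equal(tab$raw_factor, c(1, 0.25))
  expect_equal(tab$applied_factor, c(1, 0.25))

  # when the reference sample is the smaller library, rescaling caps at 1
  tab <- compute_correction_factors(c(DMSO = 4e6, EPZ = 1e6), "DMSO")
  expect_equal(tab$raw_factor, c(1, 4))
  expect_equal(tab$applied_factor, c(0.25, 1))

  # ratios preserved and all factors <= 1 for random counts; scale-invariant
  set.seed(7)
  for (i in 1:10) {
    counts <- stats::setNames(sample.int(5e6, 3), c("a", "b", "c"))
    tab <- compute_correction_factors(counts, "a")
    expect_true(all(tab$applied_factor <= 1 + 1e-12))
    expect_equal(max(tab$applied_factor), 1)
    expect_equal(tab$applied_factor[1] / tab$applied_factor[2],
                 unname(counts["b"] / counts["a"]))
    tab2 <- compute_correction_factors(counts * 17, "a")
    expect_equal(tab2$applied_factor, tab$applied_factor)
    expect_equal(tab2$raw_factor, tab$raw_factor)
  }

  expect_error(compute_correction_factors(c(a = 0, b = 10), "a"),
               "spike-in")
  expect_error(compute_correction_factors(c(a = 5, b = 10), "z"), "z")
})

test_that("downsampling meets the count contract and is reproducible", {
  gl <- tiny_layout()
  tags <- random_tags(1000, gl, seed = 71)
  kept <- downsample_tags(tags, 0.25, seed = 1)
  expect_length(kept, 250)
  expect_identical(downsample_tags(tags, 1, seed = 1), tags)
  expect_identical(downsample_tags(tags, 0.25, seed = 1), kept)
  expect_false(identical(downsample_tags(tags, 0.25, seed = 2), kept))
  # order preserved: kept tags appear in their original relative order
  tagged <- tags
  mcols(tagged)$id <- seq_along(tagged)
  idx <- mcols(downsample_tags(tagged, 0.25, seed = 4))$id
  expect_true(all(diff(idx) > 0))
  # round-half-to-even on the output size
  expect_length(downsample_tags(tags[1:25], 0.5, seed = 1), 12)
  expect_error(downsample_tags(tags, 0), "factor")
  expect_error(downsample_tags(tags, 1.2), "factor")
})

test_that("downsampling retains each tag at the requested rate", {
  gl <- tiny_layout()
  tags <- random_tags(400, gl, seed = 81)
  target <- paste(seqnames(tags), start(tags), strand(tags))[17]
  hits <- vapply(1:200, function(s) {
    kept <- downsample_tags(tags, 0.25, seed = s)
    target %in% paste(seqnames(kept), start(kept), strand(kept))
  }, logical(1))
  expect_equal(mean(hits), 0.25, tolerance = 0.35)  # binomial, n = 200
})

test_that("standard normalization equalizes experimental depth", {
  libs <- list(make_two_species_lib("a", 100, 10, seed = 91),
               make_two_species_lib("b", 80, 10, seed = 95))
  norm <- standard_normalize(libs, "human", seed = 3)
  expect_equal(vapply(norm, function(l) length(l$tags$human), 1L), c(80L, 80L))
  expect_identical(norm[[2]]$tags$human, libs[[2]]$tags$human)  # smallest

  same <- standard_normalize(list(libs[[1]], libs[[1]]), "human", seed = 3)
  expect_length(same[[1]]$tags$human, 100)

  set.seed(13)
  libs4 <- lapply(1:4, function(i) {
    make_two_species_lib(letters[i], sample(50:200, 1), 10, seed = 200 + i)
  })
  norm4 <- standard_normalize(libs4, "human", seed = 5)
  counts <- vapply(norm4, function(l) length(l$tags$human), 1L)
  expect_true(all(counts == min(vapply(libs4, function(l)
    length(l$tags$human), 1L))))
})

test_that("spike normalization scales experimental tags only", {
  libs <- list(make_two_species_lib("a", 100, 40, seed = 101),
               make_two_species_lib("b", 100, 40, seed = 105))
  tab <- compute_correction_factors(c(a = 1000, b = 4000), "a")
  norm <- spike_normalize(libs, tab, "human", seed = 9)
  expect_length(norm[[1]]$tags$human, 100)
  expect_length(norm[[2]]$tags$human, 25)
  expect_identical(norm[[1]]$tags$fly, libs[[1]]$tags$fly)
  expect_identical(norm[[2]]$tags$fly, libs[[2]]$tags$fly)

  ones <- compute_correction_factors(c(a = 500, b = 500), "a")
  id <- spike_normalize(libs, ones, "human", seed = 9)
  expect_identical(id[[1]]$tags$human, libs[[1]]$tags$human)

  bad <- compute_correction_factors(c(a = 500, z = 500), "a")
  expect_error(spike_normalize(libs, bad, "human", seed = 9), "b")
})
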