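# Domain types, format readers/writers, species partitioning.

test_that("genome layouts validate their invariants", {
  gl <- genome_layout("fly", c("chr2L", "chr2R"), c(100, 200))
  expect_equal(total_length(gl), 300)
  expect_equal(GenomeInfoDb::seqlengths(as_seqinfo(gl)),
               c(chr2L = 100L, chr2R = 200L))
  expect_error(genome_layout("fly", c("a", "a"), c(1, 2)), "duplicated")
  expect_error(genome_layout("fly", "a", 0), "positive")
  expect_error(genome_layout("fly", character(0), numeric(0)),
               "at least one")
})

test_that("chrom.sizes files round-trip", {
  gl <- tiny_layout()
  f <- tempfile()
  write_chrom_sizes(gl, f)
  back <- read_chrom_sizes(f, "human")
  expect_equal(back$lengths, gl$lengths)
  expect_equal(back$species, "human")
})

test_that("read_tags maps BED6 fields and validates records", {
  gl <- tiny_layout()
  # direct field mapping: 0-based half-open on disk, mapq from the score col
  p <- write_bed6("chrA\t100\t150\tt1\t37\t+")
  tg <- read_tags(p, "bed6", gl)
  expect_equal(as.character(seqnames(tg)), "chrA")
  expect_equal(start(tg), 101L)  # 0-based 100
  expect_equal(end(tg), 150L)
  expect_equal(as.character(strand(tg)), "+")
  expect_equal(mcols(tg)$mapq, 37L)

  # empty file is an empty tag set, not an error
  empty <- read_tags(write_bed6(character(0)), "bed6", gl)
  expect_length(empty, 0)
  expect_equal(S4Vectors::metadata(empty)$n_dropped, 0L)

  # records on unknown chromosomes are dropped and counted
  lines <- c(sprintf("chrA\t%d\t%d\tt\t30\t+", 0:7 * 100, 0:7 * 100 + 50),
             "chrZ\t0\t50\tt\t30\t+", "chrZ\t10\t60\tt\t30\t-")
  expect_message(tg <- read_tags(write_bed6(lines), "bed6", gl),
                 "dropped 2")
  expect_length(tg, 8)
  expect_equal(S4Vectors::metadata(tg)$n_dropped, 2L)

  # malformed records name the offending line
  expect_error(read_tags(write_bed6(c("chrA\t0\t50\tt\t30\t+",
                                      "chrA\t10\t60")), "bed6", gl),
               "line 2")
  expect_error(read_tags(write_bed6("chrA\t50\t50\tt\t30\t+"), "bed6", gl),
               "line 1")
  expect_error(read_tags(write_bed6("chrA\t0\t50\tt\t30\t?"), "bed6", gl),
               "strand")
  expect_error(read_tags(write_bed6("chrA\t0\t50000\tt\t30\t+"), "bed6", gl),
               "exceeds")
  expect_error(read_tags(write_bed6("chrA\tzero\t50\tt\t30\t+"), "bed6", gl),
               "line 1")
})

test_that("tag files round-trip through the 0-based/1-based boundary", {
  gl <- tiny_layout()
  tags <- random_tags(500, gl, seed = 4)
  f <- tempfile(fileext = ".bed")
  write_tags(tags, f)
  back <- read_tags(f, "bed6", gl)
  expect_equal(start(back), start(tags))
  expect_equal(end(back), end(tags))
  expect_equal(as.character(strand(back)), as.character(strand(tags)))
  expect_equal(mcols(back)$mapq, mcols(tags)$mapq)
})

test_that("read_regions sorts, merges, and rejects inverted intervals", {
  # overlapping intervals coalesce
  r <- read_regions(write_bed6(c("chrA\t0\t100", "chrA\t50\t200")))
  expect_length(r, 1)
  expect_equal(c(as.character(seqnames(r)), start(r), end(r)),
               c("chrA", 1L, 200L))
  # different chromosomes stay apart
  r <- read_regions(write_bed6(c("chrA\t0\t100", "chrB\t0\t100")))
  expect_length(r, 2)
  # shuffled disjoint intervals come back sorted (sort oracle)
  r <- read_regions(write_bed6(c("chrB\t500\t600", "chrA\t300\t400",
                                 "chrA\t0\t100")))
  expect_equal(start(r), c(1L, 301L, 501L))
  expect_equal(as.character(seqnames(r)), c("chrA", "chrA", "chrB"))
  expect_error(read_regions(write_bed6(c("chrA\t0\t100", "chrA\t60\t60"))),
               "line 2")
})

test_that("region normalization is idempotent", {
  set.seed(11)
  for (i in 1:5) {
    gr <- GRanges(sample(c("c1", "c2"), 30, TRUE),
                  IRanges(sample.int(1000, 30), width = sample.int(200, 30)))
    once <- normalize_regions(gr)
    expect_identical(normalize_regions(once), once)
    expect_true(all(start(once) <= end(once)))
    expect_true(isDisjoint(once))
  }
})

test_that("bedGraph output merges runs, omits zeros, and round-trips", {
  gl <- genome_layout("human", "chrA", 3200)
  tr <- bin_track(gl, 32)
  tr$values$chrA[3] <- 3  # bin index 2 in 0-based terms
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  expect_equal(readLines(f), "chrA\t64\t96\t3.0")

  # all-zero track: empty data section
  write_bedgraph(bin_track(gl, 32), f)
  expect_length(readLines(f), 0)

  # random track round-trips exactly at the written precision
  gl2 <- genome_layout("human", "chrA", 100 * 32)
  tr2 <- bin_track(gl2, 32)
  set.seed(9)
  tr2$values$chrA <- signif(round(runif(100, 0, 5), 2), 4)
  write_bedgraph(tr2, f)
  back <- read_bedgraph(f, gl2, 32)
  expect_equal(back$values$chrA, tr2$values$chrA)
})

test_that("bedGraph agrees with an independent reader", {
  skip_if_not_installed("rtracklayer")
  gl <- genome_layout("human", c("chrA", "chrB"), c(320, 352))
  tr <- bin_track(gl, 32)
  set.seed(21)
  tr$values$chrA <- signif(sample(c(0, 1.5, 2.25), 10, TRUE), 4)
  tr$values$chrB <- signif(sample(c(0, 0.5), 11, TRUE), 4)
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  imported <- rtracklayer::import(f, format = "bedGraph")
  # reconstruct per-bin values from the independent reader's records
  for (ch in gl$chrom) {
    v <- numeric(length(tr$values[[ch]]))
    rec <- imported[as.character(seqnames(imported)) == ch]
    for (i in seq_along(rec)) {
      bins <- ((start(rec)[i] - 1) %/% 32 + 1):((end(rec)[i] - 1) %/% 32 + 1)
      v[bins] <- mcols(rec)$score[i]
    }
    expect_equal(v, tr$values[[ch]])
  }
})

test_that("partition_species conserves tags in both modes", {
  hum <- genome_layout("hum", c("chr1", "chr2"), c(1000, 1000))
  fly <- genome_layout("fly", "chr2R", 500)
  layouts <- list(hum = hum, fly = fly)

  mixed <- GRanges(c("hum_chr1", "fly_chr2R", "hum_chr2"),
                   IRanges(c(1, 11, 21), width = 50),
                   strand = "+", mapq = c(60L, 60L, 60L))
  lib <- partition_species(mixed, layouts, "prefixed_chroms", "s1")
  expect_equal(unname(tag_counts(lib)), c(2L, 1L))
  expect_equal(as.character(seqnames(lib$tags$fly)), "chr2R")

  # all tags from one species: one empty bucket
  onesp <- GRanges(rep("fly_chr2R", 5), IRanges(1:5 * 10, width = 40),
                   strand = "-", mapq = rep(60L, 5))
  lib1 <- partition_species(onesp, layouts, "prefixed_chroms", "s2")
  expect_equal(unname(tag_counts(lib1)), c(0L, 5L))

  # conservation on 1,000 mixed tags, both conventions
  set.seed(5)
  n <- 1000
  chroms <- sample(c("chr1", "chr2", "chr2R"), n, TRUE)
  sp <- ifelse(chroms == "chr2R", "fly", "hum")
  plain <- GRanges(chroms, IRanges(sample.int(400, n, TRUE), width = 50),
                   strand = "+", mapq = rep(60L, n))
  pref <- GRanges(paste0(sp, "_", chroms), ranges(plain), strand = "+",
                  mapq = rep(60L, n))
  for (lib in list(partition_species(plain, layouts, "separate_files"),
                   partition_species(pref, layouts, "prefixed_chroms"))) {
    expect_equal(sum(tag_counts(lib)), n)
    expect_equal(unname(tag_counts(lib)["fly"]), sum(sp == "fly"))
  }

  expect_error(partition_species(
    GRanges("marsupial_chrX", IRanges(1, 50), strand = "+", mapq = 60L),
    layouts, "prefixed_chroms"), "marsupial_chrX")
  expect_error(partition_species(
    GRanges("chrX", IRanges(1, 50), strand = "+", mapq = 60L),
    layouts, "separate_files"), "chrX")
})

test_that("sample libraries validate tags against their layouts", {
  gl <- tiny_layout()
  tags <- random_tags(10, gl, seed = 2)
  lib <- sample_library("s", "control", "H3K27me3",
                        list(human = tags), list(human = gl))
  expect_s3_class(lib, "sample_library")
  stray <- GRanges("chrZ", IRanges(1, 50), strand = "+", mapq = 60L)
  expect_error(sample_library("s", tags = list(human = stray),
                              layouts = list(human = gl)), "chrZ")
  expect_error(sample_library("s", tags = list(moth = tags),
                              layouts = list(human = gl)), "moth")
})
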