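# Window scoring, eligibility, clustering, E-value threshold, full caller.

test_that("window scores are -log Poisson mass and monotone in the count", {
  # direct evaluation: P(5; 1) = e^-1 / 5! so the score is 1 + log(120)
  expect_equal(window_score(5, 1, min_count = 1), 1 + log(120),
               tolerance = 1e-12)
  expect_equal(window_score(2, 1, min_count = 3), 0)  # below eligibility
  for (lambda in c(0.1, 1, 5)) {
    k <- ceiling(lambda):(ceiling(lambda) + 20)
    s <- window_score(k, lambda, min_count = 1)
    expect_true(all(diff(s) > 0))
  }
  expect_error(window_score(3, -1), "lambda")
})

test_that("eligibility threshold matches brute-force tail sums", {
  expect_equal(eligibility_threshold(0.1, 0.2), 1L)  # P(X>=1) = 0.095 < 0.2
  expect_equal(eligibility_threshold(1e-9, 0.2), 1L) # any tag is surprising
  for (lambda in c(0.01, 0.05, 0.1, 0.5, 1, 2, 5)) {
    k <- eligibility_threshold(lambda, 0.2)
    tail_at <- function(j) sum(dpois(j:(j + 400), lambda))
    expect_lt(tail_at(k), 0.2)
    if (k > 1) expect_gte(tail_at(k - 1), 0.2)
  }
})

test_that("window counts assign by midpoint and are conserved", {
  gl <- genome_layout("human", "chrA", 10000)
  fr <- GRanges("chrA", IRanges(1, 200), seqinfo = as_seqinfo(gl))
  cnt <- window_counts(fr, gl, 200)
  expect_equal(cnt$chrA[1], 1L)           # midpoint 100 -> window 0
  expect_equal(sum(cnt$chrA), 1L)
  expect_equal(sum(window_counts(fr[0], gl, 200)$chrA), 0L)

  gl2 <- tiny_layout()
  fr <- extend_tags(random_tags(10000, gl2, seed = 17), 200)
  cnt <- window_counts(fr, gl2, 200)
  expect_equal(sum(vapply(cnt, sum, 1)), 10000)
})

test_that("island assembly follows the gap rule and matches a run oracle", {
  gl <- genome_layout("human", "chrA", 200 * 50)
  mk_counts <- function(idx0) {
    v <- integer(50); v[idx0 + 1L] <- 5L
    list(chrA = v)
  }
  lambda <- 0.5
  scores <- function(cnt) lapply(cnt, window_score, lambda = lambda,
                                 min_count = 2L)

  # eligible windows {0, 1, 5} with gap 3 windows form one island 0..5
  cnt <- mk_counts(c(0, 1, 5))
  isl <- assemble_islands(cnt, scores(cnt), 2L, 3L, gl, 200L)
  expect_length(isl, 1)
  expect_equal(c(start(isl), end(isl)), c(1L, 1200L))
  expect_equal(mcols(isl)$score, 3 * window_score(5, lambda, 2L))
  expect_equal(mcols(isl)$tag_count, 15L)

  # eligible windows {0, 10} are two islands
  cnt <- mk_counts(c(0, 10))
  expect_length(assemble_islands(cnt, scores(cnt), 2L, 3L, gl, 200L), 2)

  # random eligibility vectors against the independent linear-scan oracle
  set.seed(23)
  for (i in 1:20) {
    v <- rpois(50, 0.8)
    cnt <- list(chrA = v)
    gap_w <- sample(0:4, 1)
    isl <- assemble_islands(cnt, scores(cnt), 2L, gap_w, gl, 200L)
    # oracle via fragments placed at window midpoints
    frags <- GRanges("chrA", IRanges(rep((which(v > 0) - 1L) * 200L + 50L,
                                         v[v > 0]), width = 100),
                     seqinfo = as_seqinfo(gl))
    odf <- oracle_islands(frags, gl, 200L, gap_w * 200L, lambda, 2L, 0)
    expect_equal(islands_to_df(isl), odf, ignore_attr = TRUE)
    expect_true(isDisjoint(isl))
  }
})

test_that("the E-value threshold is seeded, monotone, and near an independent MC", {
  gl <- genome_layout("human", "chrA", 10000)  # 50 windows of 200 bp
  ip <- island_params(window = 200, gap = 600, e_value = 1,
                      effective_genome_fraction = 1, mc_draws = 4000,
                      seed = 5)
  t1 <- score_threshold_mc(gl, 50, ip)
  t2 <- score_threshold_mc(gl, 50, ip)
  expect_identical(as.numeric(t1), as.numeric(t2))  # determinism
  expect_equal(attr(t1, "lambda"), 1)               # 50 tags * 200 / 10 kb

  ip_strict <- island_params(window = 200, gap = 600, e_value = 0.1,
                             effective_genome_fraction = 1, mc_draws = 4000,
                             seed = 5)
  expect_gte(as.numeric(score_threshold_mc(gl, 50, ip_strict)),
             as.numeric(t1))
  ip_inf <- island_params(window = 200, gap = 600, e_value = Inf,
                          effective_genome_fraction = 1, seed = 5)
  expect_equal(as.numeric(score_threshold_mc(gl, 50, ip_inf)), 0)

  # independent R-level Monte Carlo of the same Poisson null
  lambda <- attr(t1, "lambda")
  k0 <- attr(t1, "min_count")
  draws <- 4000
  set.seed(99)
  pooled <- unlist(lapply(seq_len(draws), function(d) {
    v <- rpois(50, lambda)
    idx <- which(v >= k0)
    if (!length(idx)) return(numeric(0))
    cl <- cumsum(c(TRUE, diff(idx) > 4L))
    as.numeric(tapply(-dpois(v[idx], lambda, log = TRUE), cl, sum))
  }))
  # expected number of islands per genome at the package's threshold should
  # sit at (or within MC error below) the requested E-value
  e_at_thr <- sum(pooled >= as.numeric(t1)) / draws
  expect_lte(e_at_thr, 1.1)
  expect_gte(e_at_thr, 0.5)
})

test_that("the caller recovers a planted domain and nothing else", {
  gl <- genome_layout("human", "chrA", 100000)
  set.seed(41)
  bg <- uniform_fragments(2000, gl, seed = 41)        # lambda = 4 per window
  extra <- GRanges("chrA", IRanges(floor(runif(1900, 40000, 45000 - 200)),
                                   width = 200), seqinfo = as_seqinfo(gl))
  fr <- c(bg, extra)                                   # ~20x density inside
  ip <- island_params(window = 200, gap = 600, e_value = 1,
                      effective_genome_fraction = 1, mc_draws = 2000,
                      seed = 6)
  isl <- call_islands(fr, gl, ip)
  hit <- isl[mcols(isl)$score == max(mcols(isl)$score)]
  expect_lte(abs(start(hit) - 40001), 400)   # within two windows
  expect_lte(abs(end(hit) - 45000), 400)
  expect_lte(length(isl), 3)                 # E-value 1 background
  expect_true(isDisjoint(isl))
  expect_equal(S4Vectors::metadata(isl)$threshold,
               as.numeric(score_threshold_mc(gl, length(fr), ip)))
})

test_that("an empty sample yields an empty island set with a warning", {
  gl <- tiny_layout()
  expect_warning(isl <- call_islands(GRanges(seqinfo = as_seqinfo(gl)), gl,
                                     island_params()), "no fragments")
  expect_length(isl, 0)
})

test_that("the full caller equals exhaustive enumeration on small genomes", {
  # genomes of <= 50 windows, random fragments, fixed thresholds: the caller
  # must reproduce the independent scan's island set exactly
  set.seed(77)
  for (i in 1:12) {
    nchrom <- sample(1:2, 1)
    gl <- genome_layout("human", paste0("c", seq_len(nchrom)),
                        sample(c(4000, 6000, 10000), nchrom, TRUE))
    n <- sample(c(30, 80, 150), 1)
    fr <- uniform_fragments(n, gl, seed = 1000 + i, width = 150)
    gap <- sample(c(0, 200, 600), 1)
    ip <- island_params(window = 200, gap = gap, e_value = 1,
                        effective_genome_fraction = 1, seed = 2)
    thr <- sample(c(0, 2, 5, 10), 1)
    isl <- call_islands(fr, gl, ip, threshold = thr)
    lambda <- n * 200 / total_length(gl)
    k0 <- eligibility_threshold(lambda, 0.2)
    odf <- oracle_islands(fr, gl, 200L, gap, lambda, k0, thr)
    expect_equal(islands_to_df(isl), odf, ignore_attr = TRUE)
  }
})

test_that("island export writes BED5 and full-precision TSV", {
  gl <- genome_layout("human", "chrA", 100000)
  fr <- c(uniform_fragments(500, gl, seed = 3),
          GRanges("chrA", IRanges(floor(runif(500, 20000, 24800)),
                                  width = 200), seqinfo = as_seqinfo(gl)))
  ip <- island_params(window = 200, gap = 600, e_value = 1,
                      effective_genome_fraction = 1, mc_draws = 1000,
                      seed = 2)
  isl <- call_islands(fr, gl, ip)
  bed <- tempfile(fileext = ".bed"); tsv <- tempfile(fileext = ".tsv")
  write_islands(isl, bed, tsv)
  bl <- read.table(bed, sep = "\t")
  expect_equal(nrow(bl), length(isl))
  expect_true(all(bl$V5 >= 0 & bl$V5 <= 1000))
  tl <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(tl$score, mcols(isl)$score, tolerance = 1e-6)
  expect_equal(tl$start, start(isl) - 1L)
})
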