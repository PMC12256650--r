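mk_reads <- function(contig, start, end, strand) {
  read_set(contig = contig, start = start, end = end, strand = strand)
}

test_that("classify_length applies the 27-32 nt bounds inclusively", {
  reads <- mk_reads("c1", c(0, 100, 200, 300), c(26, 127, 232, 333),
                    c("+", "+", "-", "+"))  # lengths 26, 27, 32, 33
  parts <- classify_length(reads)
  expect_identical(parts$pirna$length, c(27L, 32L))
  expect_identical(parts$other$length, c(26L, 33L))

  # partition conserves reads and order
  expect_identical(sort(c(parts$pirna$name, parts$other$name)), sort(reads$name))

  empty <- mk_reads(character(0), integer(0), integer(0), character(0))
  parts <- classify_length(empty)
  expect_identical(nrow(parts$pirna) + nrow(parts$other), 0L)

  all22 <- mk_reads(rep("c1", 3), c(0, 50, 90), c(22, 72, 112), rep("+", 3))
  expect_identical(nrow(classify_length(all22)$pirna), 0L)
})

test_that("length_histogram is exact and conserves counts", {
  reads <- mk_reads(rep("c1", 2), c(0, 40), c(28, 68), c("+", "-"))
  h <- length_histogram(reads)
  expect_identical(h$count[h$length == 28], 2L)
  expect_true(h$is_pirna[h$length == 28])

  expect_identical(nrow(length_histogram(mk_reads(character(0), integer(0),
                                                  integer(0), character(0)))), 0L)

  # generator mixture: histogram matches weights within 3 binomial SD
  spec <- read_sim_spec(c(c1 = 100000L), n_reads = 5000,
                        length_probs = c("22" = 0.5, "28" = 0.5))
  reads <- gen_read_set(spec, seed = 9)
  h <- length_histogram(reads)
  expect_identical(sum(h$count), 5000L)
  p22 <- h$count[h$length == 22] / 5000
  expect_lt(abs(p22 - 0.5), 3 * sqrt(0.25 / 5000))
})

test_that("pingpong_profile follows the stated coordinate arithmetic", {
  # worked example: [100,128)+ and [82,110)- -> minus 5' 109, overlap 10
  reads <- mk_reads(rep("c1", 2), c(100, 82), c(128, 110), c("+", "-"))
  pp <- pingpong_profile(reads)
  expect_identical(unname(pp$counts[["10"]]), 1L)
  expect_identical(pp$total_pairs, 1L)
  expect_identical(pp$modal_overlap, 10L)

  # one strand only -> empty profile
  same <- mk_reads(rep("c1", 3), c(0, 5, 9), c(28, 33, 37), rep("+", 3))
  pp <- pingpong_profile(same)
  expect_identical(pp$total_pairs, 0L)
  expect_true(is.na(pp$modal_overlap))

  # reads on different contigs never pair
  apart <- mk_reads(c("c1", "c2"), c(100, 82), c(128, 110), c("+", "-"))
  expect_identical(pingpong_profile(apart)$total_pairs, 0L)

  # synthetic set with planted partners -> modal overlap exactly 10
  spec <- read_sim_spec(c(c1 = 300000L), n_reads = 5000, pingpong_fraction = 0.3)
  pp <- pingpong_profile(classify_length(gen_read_set(spec, seed = 31))$pirna)
  expect_identical(pp$modal_overlap, 10L)

  # a global strand swap maps each pair's overlap o to L1 + L2 - o
  pair <- mk_reads(rep("c1", 2), c(100, 82), c(128, 110), c("+", "-"))
  swapped <- pair
  swapped$strand <- ifelse(pair$strand == "+", "-", "+")
  pp_sw <- pingpong_profile(swapped, max_overlap = 60)
  expect_identical(unname(pp_sw$counts[[as.character(28 + 28 - 10)]]), 1L)
})

test_that("window_counts bins by start coordinate and validates bounds", {
  reads <- mk_reads(rep("c1", 3), c(100, 1999, 2000), c(130, 2029, 2030), rep("+", 3))
  wc <- window_counts(reads, c(c1 = 5000L))
  expect_identical(wc$count, c(2L, 1L, 0L))       # windows [0,2k),[2k,4k),[4k,5k)
  expect_identical(attr(wc, "total"), 3L)

  none <- window_counts(mk_reads(character(0), integer(0), integer(0), character(0)),
                        c(c1 = 5000L))
  expect_true(all(none$count == 0L))

  expect_error(window_counts(mk_reads("c1", 4990, 5020, "+"), c(c1 = 5000L)),
               "beyond contig")
  expect_error(window_counts(reads, c(other = 5000L)), "missing")

  # high-density report restricted by threshold
  many <- mk_reads(rep("c1", 1200), rep(10L, 1200), rep(40L, 1200), rep("+", 1200))
  hd <- high_density_windows(window_counts(many, c(c1 = 5000L)), min_count = 1000)
  expect_identical(nrow(hd), 1L)
  expect_identical(hd$window, 0L)
})

test_that("windows_to_cover returns the minimal top-window count", {
  fake_wc <- function(counts) {
    wc <- window_counts(mk_reads(character(0), integer(0), integer(0), character(0)),
                        c(c1 = length(counts) * 2000L))
    wc$count <- as.integer(counts)
    attr(wc, "total") <- sum(counts)
    wc
  }
  expect_identical(windows_to_cover(fake_wc(c(90, 5, 3, 1, 1)), 0.9), 1L)

  # uniform counts over w windows -> ceil(0.9 w)
  for (w in c(5, 10, 17)) {
    expect_identical(windows_to_cover(fake_wc(rep(4, w)), 0.9),
                     as.integer(ceiling(0.9 * w)))
  }

  # fraction 1.0 -> number of nonzero windows
  expect_identical(windows_to_cover(fake_wc(c(7, 0, 3, 0, 2)), 1.0), 3L)

  expect_error(windows_to_cover(fake_wc(c(0, 0))), "no piRNAs")
  expect_error(windows_to_cover(fake_wc(c(1, 2)), fraction = 0), "fraction")
})

test_that("clustering_ratio behaves as the permutation statistic", {
  lens <- c(c1 = 200000L)

  # uniform reads -> ratio ~ 1 (within 15%)
  spec <- read_sim_spec(lens, n_reads = 10000, cluster_fraction = 0,
                        length_probs = c("28" = 1))
  reads <- gen_read_set(spec, seed = 41)
  cr <- clustering_ratio(reads, lens, n_shuffles = 5, seed = 8)
  expect_lt(abs(cr$clustering_ratio - 1), 0.15)

  # all reads inside one 2-kb window of a 100-window contig:
  # real = 1, shuffled ~ 90 under uniform placement
  lens1 <- c(c1 = 200000L)
  set.seed(77)
  starts <- sample(0:1970, 2000, replace = TRUE)
  packed <- mk_reads(rep("c1", 2000), starts, starts + 28L, rep("+", 2000))
  cr <- clustering_ratio(packed, lens1, n_shuffles = 10, seed = 13)
  expect_identical(cr$windows_real_90, 1L)
  expect_gt(cr$clustering_ratio, 10)
  expect_lt(abs(cr$windows_shuffled_90 - 90), 8)

  # determinism
  cr2 <- clustering_ratio(packed, lens1, n_shuffles = 10, seed = 13)
  expect_identical(cr, cr2)

  # error on empty input
  expect_error(clustering_ratio(mk_reads(character(0), integer(0), integer(0),
                                         character(0)), lens, seed = 1),
               "no putative piRNAs")
})

test_that("clustering ratio rises monotonically with planted cluster_fraction", {
  lens <- c(c1 = 400000L)
  ratios <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(cf) {
    spec <- read_sim_spec(lens, n_reads = 6000, cluster_fraction = cf,
                          n_clusters = 3, length_probs = c("28" = 1))
    reads <- gen_read_set(spec, seed = 55)
    clustering_ratio(reads, lens, n_shuffles = 5, seed = 99)$clustering_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  # definitional consistency: higher ratio <=> fewer windows hold 90%
  reals <- vapply(c(0, 0.5, 1), function(cf) {
    spec <- read_sim_spec(lens, n_reads = 6000, cluster_fraction = cf,
                          n_clusters = 3, length_probs = c("28" = 1))
    reads <- gen_read_set(spec, seed = 55)
    windows_to_cover(window_counts(reads, lens), 0.9)
  }, integer(1))
  expect_true(all(diff(reals) < 0))
})

test_that("clustering ratio is invariant in expectation to contig relabeling", {
  lens <- c(a = 100000L, b = 100000L)
  spec <- read_sim_spec(lens, n_reads = 4000, cluster_fraction = 0.6, n_clusters = 2,
                        length_probs = c("28" = 1))
  reads <- gen_read_set(spec, seed = 3)
  cr1 <- clustering_ratio(reads, lens, n_shuffles = 5, seed = 10)
  relabeled <- reads
  relabeled$contig <- c(a = "b", b = "a")[reads$contig]
  cr2 <- clustering_ratio(relabeled, c(a = 100000L, b = 100000L),
                          n_shuffles = 5, seed = 10)
  expect_identical(cr1$windows_real_90, cr2$windows_real_90)
  expect_lt(abs(cr1$clustering_ratio - cr2$clustering_ratio) / cr1$clustering_ratio, 0.2)
})
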