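make_reads <- function(chrom, starts, len = 10L) {
  n <- length(starts)
  data.frame(chrom = rep(chrom, n), start = starts, end = starts + len,
             name = sprintf("r%d", seq_len(n)), score = rep(0L, n),
             strand = rep("+", n), stringsAsFactors = FALSE)
}

test_that("windowed coverage normalises and conserves reads", {
  lens <- c(chr1 = 1000)
  # 10 reads whose midpoints share one window, library of one million
  cov <- windowed_coverage(make_reads("chr1", rep(100L, 10)), lens,
                           window = 20, library_size = 1e6)
  expect_equal(cov$norm[cov$start == 100], 10)
  expect_equal(nrow(cov), 50)

  # no reads: all-zero vector of the tiled length
  empty <- windowed_coverage(make_reads("chr1", integer(0)), lens,
                             window = 20, library_size = 1)
  expect_equal(nrow(empty), 50)
  expect_true(all(empty$count == 0))
  expect_error(windowed_coverage(make_reads("chr1", integer(0)), lens),
               "empty library")

  # conservation: sum over windows x (library/1e6) equals the read count
  set.seed(42)
  rr <- make_reads("chr1", sample.int(990, 400, replace = TRUE) - 1L)
  cov <- windowed_coverage(rr, lens, window = 20)
  expect_equal(sum(cov$norm) * nrow(rr) / 1e6, nrow(rr))
  expect_equal(sum(cov$count), nrow(rr))
})

test_that("Poisson tail matches brute-force pmf summation", {
  for (lambda in c(0.3, 2, 7.5, 40)) {
    for (count in c(1, 5, 10, 12, 60, 100)) {
      expect_equal(poisson_tail(count, lambda),
                   bf_poisson_tail(count, lambda), tolerance = 1e-12)
    }
  }
  # the worked thresholds: 10 reads over lambda = 2 misses 1e-5, 12 passes
  expect_equal(poisson_tail(10, 2), 4.649808e-5, tolerance = 1e-6)
  expect_gt(poisson_tail(10, 2), 1e-5)
  expect_equal(poisson_tail(12, 2), 1.364615e-6, tolerance = 1e-6)
  expect_lt(poisson_tail(12, 2), 1e-5)
})

test_that("self-comparison yields no peaks and chromosome sets are checked", {
  cfg <- synthetic_config(seed = 6)
  gg <- generate_genome(cfg)
  lens <- chrom_lengths(gg$genome)
  lib <- simulate_chip(gg$genome, gg$truth, "WT", cfg)
  cov <- windowed_coverage(lib$treatment, lens,
                           fragment_length = cfg$fragment_length)
  cc <- caller_config(effective_genome_size = cfg$genome_length)
  expect_equal(nrow(call_peaks(cov, cov, cc)), 0)

  half <- structure(cov[cov$chrom == "chr1", ],
                    class = class(cov), window = attr(cov, "window"),
                    library_size = attr(cov, "library_size"),
                    chrom_lens = lens["chr1"])
  expect_error(call_peaks(cov, half, cc), "mismatched chromosome")
})

test_that("caller recovers planted sites and stays on them (seed 1)", {
  res <- run_contrast(synthetic_config(seed = 1))
  sites <- res$truth$sites
  wt <- res$peaks$WT
  recall <- mean(vapply(seq_len(nrow(sites)), function(i)
    any_overlap(sites$chrom[i], sites$start[i], sites$end[i], wt),
    logical(1)))
  expect_gte(recall, 0.95)
  on_planted <- vapply(seq_len(nrow(wt)), function(i)
    any_overlap(wt$chrom[i], wt$start[i], wt$end[i], sites), logical(1))
  expect_true(all(on_planted))
  # peak invariants
  expect_true(all(wt$p_value <= 1e-5))
  expect_true(all(wt$enrichment > 1))
  expect_true(all(wt$summit >= wt$start & wt$summit < wt$end))
})

test_that("caller is monotone in threshold and in treatment counts", {
  cfg <- synthetic_config(seed = 7)
  gg <- generate_genome(cfg)
  lens <- chrom_lengths(gg$genome)
  lib <- simulate_chip(gg$genome, gg$truth, "WT", cfg)
  trt <- windowed_coverage(lib$treatment, lens,
                           fragment_length = cfg$fragment_length)
  ctl <- windowed_coverage(lib$control, lens,
                           fragment_length = cfg$fragment_length)
  strict <- call_peaks(trt, ctl,
                       caller_config(p_threshold = 1e-7,
                                     effective_genome_size = cfg$genome_length))
  loose <- call_peaks(trt, ctl,
                      caller_config(p_threshold = 1e-4,
                                    effective_genome_size = cfg$genome_length))
  # every strict peak survives (is covered) at the looser threshold
  expect_true(all(vapply(seq_len(nrow(strict)), function(i)
    any_overlap(strict$chrom[i], strict$start[i], strict$end[i], loose),
    logical(1))))
  expect_gte(nrow(loose), nrow(strict))

  # more treatment reads in a window never increase its p-value
  lam <- c(0.5, 2, 11)
  for (l in lam) expect_true(all(diff(poisson_tail(1:60, l)) <= 0))
})

test_that("profile matrices have the documented geometry", {
  lens <- c(chr1 = 20000)
  # uniform field: one midpoint every 4 bases -> 5 per 20-bp window
  rr <- make_reads("chr1", seq(0L, 19996L, by = 4L))
  cov <- windowed_coverage(rr, lens, window = 20)
  pk <- data.frame(chrom = "chr1", start = 9900L, end = 10100L,
                   name = "peak_1", summit = 10000L)
  m <- profile_matrix(pk, cov, flank = 3000, bin = 20)
  expect_equal(ncol(m), 300)
  expect_equal(nrow(m), 1)
  expect_true(all(abs(m[1, ] - 5 / (nrow(rr) / 1e6)) < 1e-9))

  # spike at the summit shows up in the central two columns
  rr2 <- rbind(rr, make_reads("chr1", rep(10000L, 50)))
  cov2 <- windowed_coverage(rr2, lens, window = 20)
  m2 <- profile_matrix(pk, cov2, flank = 3000, bin = 20)
  expect_true(which.max(m2[1, ]) %in% c(150, 151))

  # summits too close to an end are dropped with a warning
  pk2 <- rbind(pk, data.frame(chrom = "chr1", start = 100L, end = 200L,
                              name = "peak_2", summit = 150L))
  expect_warning(m3 <- profile_matrix(pk2, cov, flank = 3000, bin = 20),
                 "dropped")
  expect_equal(nrow(m3), 1)
  expect_error(profile_matrix(pk[0, ], cov), "empty peak list")
})

test_that("profile k-means recovers planted shapes and degenerate k", {
  set.seed(9)
  sharp <- t(replicate(12, c(rep(0, 140), seq(0, 30, length.out = 10),
                             seq(30, 0, length.out = 10), rep(0, 140)) +
                         runif(300)))
  flat <- t(replicate(12, rep(3, 300) + runif(300)))
  mat <- rbind(sharp, flat)
  rownames(mat) <- paste0("p", 1:24)
  labels <- kmeans_profiles(mat, 2, seed = 1)
  expect_setequal(unique(labels), c(0L, 1L))
  expect_equal(length(unique(labels[1:12])), 1)
  expect_equal(length(unique(labels[13:24])), 1)
  expect_false(labels[[1]] == labels[[24]])
  # determinism
  expect_identical(labels, kmeans_profiles(mat, 2, seed = 1))

  expect_true(all(kmeans_profiles(mat, 1, seed = 1) == 0))
  all_own <- kmeans_profiles(mat, nrow(mat), seed = 1)
  expect_equal(sort(unique(all_own)), 0:(nrow(mat) - 1))
  expect_equal(attr(all_own, "tot.withinss"), 0)
  expect_error(kmeans_profiles(mat, 0, seed = 1), "positive")
  expect_error(kmeans_profiles(mat, 25, seed = 1), "exceed")
})
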