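test_that("consensus scanning matches, deduplicates and rejects N", {
  hits <- scan_gas(c(s = "TTCTAGGAA"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 0)
  expect_equal(hits$end, 9)
  expect_equal(hits$strand, "+")

  expect_equal(nrow(scan_gas(c(s = paste(rep("N", 40), collapse = "")))), 0)
  expect_equal(nrow(scan_gas(c(s = "TTCTNGGAA"))), 0)  # N inside the window
  expect_error(scan_gas(c(s = "TTCTA")), "shorter than motif")
})

test_that("every planted GAS element is recovered on the synthetic genome", {
  gg <- generate_genome(synthetic_config(seed = 1))
  hits <- scan_gas(gg$genome)
  sites <- gg$truth$sites
  for (i in seq_len(nrow(sites))) {
    # upstream 9-mer at the site start; for tetramer sites also the
    # downstream 9-mer at end - 9
    expect_true(any(hits$chrom == sites$chrom[i] &
                      hits$start == sites$start[i]))
    if (sites$kind[i] == "tetramer")
      expect_true(any(hits$chrom == sites$chrom[i] &
                        hits$start == sites$end[i] - 9L))
  }
  n_planted <- sum(sites$kind == "dimer") + 2 * sum(sites$kind == "tetramer")
  expect_gte(nrow(hits), n_planted)
})

test_that("scanning is strand-symmetric", {
  gg <- generate_genome(synthetic_config(genome_length = 4e4,
                                         n_chromosomes = 1,
                                         n_dimer_sites = 5,
                                         n_tetramer_sites = 5,
                                         min_site_separation = 500, seed = 8))
  seq1 <- gg$genome[[1]]
  L <- length(seq1)
  fwd <- scan_gas(Biostrings::DNAStringSet(list(chr1 = seq1)))
  rev <- scan_gas(Biostrings::DNAStringSet(
    list(chr1 = Biostrings::reverseComplement(seq1))))
  # hit at [s,e) on the forward sequence mirrors to [L-e, L-s)
  expect_setequal(paste(L - fwd$end, L - fwd$start), paste(rev$start, rev$end))
})

test_that("PWM scanning generalises the consensus", {
  gg <- generate_genome(synthetic_config(seed = 9))
  strict <- scan_gas(gg$genome)
  relaxed <- scan_gas(gg$genome,
                      gas_model(pwm = consensus_pwm(), score_threshold = 0.8))
  # every strict hit is also found by the relaxed matrix
  expect_true(all(paste(strict$chrom, strict$start) %in%
                    paste(relaxed$chrom, relaxed$start)))
  expect_gte(nrow(relaxed), nrow(strict))
  expect_error(gas_model(pwm = matrix(0.3, 4, 9)), "sum to 1")
})

test_that("tandem enumeration follows the spacer definition and brute force", {
  hits <- data.frame(chrom = "chr1", start = c(100L, 125L),
                     end = c(109L, 134L), strand = "+", score = 1)
  pairs <- find_tandem(hits, max_spacer = 30)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$spacer, 16)

  # three equally spaced hits: two adjacent pairs plus the long pair only
  # when it fits under max_spacer
  h3 <- data.frame(chrom = "chr1", start = c(0L, 19L, 38L),
                   end = c(9L, 28L, 47L), strand = "+", score = 1)
  expect_equal(nrow(find_tandem(h3, max_spacer = 30)), 3)   # 10,10,29
  expect_equal(nrow(find_tandem(h3, max_spacer = 15)), 2)
  expect_equal(nrow(find_tandem(h3[1, ], 30)), 0)

  set.seed(11)
  for (rep in 1:5) {
    n <- 60
    rnd <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                      start = sort(sample.int(3000, n)))
    rnd$end <- rnd$start + 9L
    rnd$strand <- "+"; rnd$score <- 1
    rnd <- rnd[order(rnd$chrom, rnd$start), ]
    got <- find_tandem(rnd, max_spacer = 25)
    want <- bf_find_tandem(rnd, max_spacer = 25)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$up_start, got$down_start),
                    paste(rnd$start[want$i], rnd$start[want$j]))
  }
})

test_that("spacing distribution recovers planted spacers", {
  # degenerate distribution: all planted spacers are 16
  gg <- generate_genome(synthetic_config(n_dimer_sites = 0,
                                         n_tetramer_sites = 50,
                                         spacer_distribution = c("16" = 1),
                                         seed = 1))
  hits <- scan_gas(gg$genome)
  pairs <- find_tandem(hits, 30)
  sd <- spacing_distribution(pairs, restrict_to = gg$truth$sites)
  expect_equal(sd$modes, 16)
  expect_gte(sd$histogram$count[sd$histogram$spacer == 16] / sd$total_pairs,
             0.9)
  expect_equal(sum(sd$histogram$count), sd$total_pairs)

  expect_equal(spacing_distribution(pairs[0, ])$total_pairs, 0)

  # 400 planted pairs from the uniform {11,12,13,16} mixture land within
  # +/- 5 percentage points of 25% each
  big <- generate_genome(synthetic_config(
    genome_length = 2.5e5, n_chromosomes = 1, n_dimer_sites = 0,
    n_tetramer_sites = 400, read_length = 30, fragment_length = 30,
    min_site_separation = 150, seed = 2))
  sdm <- spacing_distribution(
    find_tandem(scan_gas(big$genome), 30), restrict_to = big$truth$sites)
  props <- sdm$histogram$count / sdm$total_pairs
  names(props) <- sdm$histogram$spacer
  expect_setequal(names(props), c("11", "12", "13", "16"))
  expect_true(all(abs(props - 0.25) <= 0.05))
})

test_that("peaks are classified by their motif content", {
  hits <- data.frame(chrom = "chr1", start = c(100L, 125L, 500L),
                     end = c(109L, 134L, 509L), strand = "+", score = 1)
  peaks <- data.frame(chrom = "chr1", start = c(90L, 480L, 900L),
                      end = c(150L, 520L, 950L))
  expect_equal(classify_peak_motif(peaks, hits),
               c("tetramer-like", "dimer-like", "none"))

  # on synthetic WT peaks, peaks over tetramer-only sites contain the
  # planted tandem pair
  res <- run_contrast(synthetic_config(seed = 1))
  hits <- scan_gas(res$genome)
  kinds <- peak_site_kind(res$peaks$WT, res$truth$sites)
  cls <- classify_peak_motif(res$peaks$WT, hits)
  expect_gte(mean(cls[kinds == "tetramer"] == "tetramer-like", na.rm = TRUE),
             0.9)
})
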