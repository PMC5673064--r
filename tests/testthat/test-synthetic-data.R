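test_that("genome generation is deterministic and honours the truth contract", {
  cfg <- synthetic_config(seed = 1)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$sites, b$truth$sites)

  sites <- a$truth$sites
  expect_equal(nrow(sites), cfg$n_dimer_sites + cfg$n_tetramer_sites)
  # tetramer sites carry a spacer and are WT-only; dimer sites the reverse
  expect_true(all(!is.na(sites$spacer[sites$kind == "tetramer"])))
  expect_true(all(is.na(sites$spacer[sites$kind == "dimer"])))
  expect_true(all(sites$active_in[sites$kind == "tetramer"] == "WT"))
  expect_true(all(sites$active_in[sites$kind == "dimer"] == "WT,DKI"))
  expect_true(all(sites$spacer[sites$kind == "tetramer"] %in%
                    as.integer(names(cfg$spacer_distribution))))
  # non-overlapping, away from chromosome ends
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, ]
    s <- s[order(s$start), ]
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
    expect_true(all(s$start >= cfg$fragment_length))
  }
  # each planted motif is literally present in the sequence
  for (i in seq_len(nrow(sites))) {
    sub <- as.character(Biostrings::subseq(a$genome[[sites$chrom[i]]],
                                           sites$start[i] + 1, sites$start[i] + 9))
    expect_match(sub, "^TTC[CT][ACGT][AG]GAA$")
  }
})

test_that("degenerate and empty site configurations behave", {
  none <- generate_genome(synthetic_config(n_tetramer_sites = 0, seed = 2))
  expect_true(all(is.na(none$truth$sites$spacer)))

  fixed <- generate_genome(synthetic_config(
    n_dimer_sites = 0, n_tetramer_sites = 50,
    spacer_distribution = c("16" = 1), seed = 3))
  expect_identical(unique(fixed$truth$sites$spacer), 16L)

  expect_error(synthetic_config(genome_length = 2e4, seed = 1),
               "10 \\* n_sites")
  expect_error(generate_genome(synthetic_config(
    genome_length = 1.1e5, n_dimer_sites = 25, n_tetramer_sites = 25,
    fragment_length = 200, seed = 1)), "cannot place")
})

test_that("truth registry round-trips through its TSV serialisation", {
  sites <- generate_genome(synthetic_config(seed = 4))$truth$sites
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_sites(sites, path)
  expect_identical(read_truth_sites(path), sites)
})

test_that("ChIP simulation enriches active sites in the right genotype", {
  cfg <- synthetic_config(depth_treatment = 1e5, depth_control = 1e5, seed = 1)
  gg <- generate_genome(cfg)
  lens <- chrom_lengths(gg$genome)
  sites <- gg$truth$sites
  tet <- sites[sites$kind == "tetramer", ]

  wt <- simulate_chip(gg$genome, gg$truth, "WT", cfg)
  cov <- windowed_coverage(wt$treatment, lens,
                           fragment_length = cfg$fragment_length)
  onsite <- vapply(seq_len(nrow(cov)), function(i)
    any_overlap(cov$chrom[i], cov$start[i], cov$end[i], sites), logical(1))
  expect_gt(mean(cov$count[onsite]), mean(cov$count))

  # DKI coverage at tetramer sites is indistinguishable from background
  dki <- simulate_chip(gg$genome, gg$truth, "DKI", cfg)
  covd <- windowed_coverage(dki$treatment, lens,
                            fragment_length = cfg$fragment_length)
  ontet <- vapply(seq_len(nrow(covd)), function(i)
    any_overlap(covd$chrom[i], covd$start[i], covd$end[i], tet), logical(1))
  background <- vapply(seq_len(nrow(covd)), function(i)
    !any_overlap(covd$chrom[i], covd$start[i] - 300, covd$end[i] + 300, sites),
    logical(1))
  p <- stats::wilcox.test(covd$count[ontet], covd$count[background])$p.value
  expect_gt(p, 0.01)

  # genotype contract: aggregate tetramer-site treatment signal differs by
  # roughly enrichment_fold between genotypes
  ratio <- sum(cov$count[ontet]) / sum(covd$count[ontet])
  expect_gt(ratio, cfg$enrichment_fold / 2)
  expect_lt(ratio, cfg$enrichment_fold * 2)

  expect_error(simulate_chip(gg$genome, gg$truth, "WT",
                             synthetic_config(depth_treatment = 0, seed = 1)),
               "zero-depth")
})

test_that("chip simulation is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 5)
  gg <- generate_genome(cfg)
  a <- simulate_chip(gg$genome, gg$truth, "WT", cfg)
  b <- simulate_chip(gg$genome, gg$truth, "WT", cfg)
  expect_identical(a, b)
})

test_that("count simulation plants transition and genotype effects", {
  genes <- gene_models(paste0("g", 1:4), "chr1", "+",
                       c(0, 5000, 10000, 15000), c(3000, 8000, 13000, 18000))
  genes$baseline_rpkm <- c(20, 20, 0, 20)
  reg <- de_registry(c("g1", "g4"), c("Q1Q2", "Q2Q3"), c("up", "up"),
                     c(4, 4), c("none", "dki_lost"))

  tab <- simulate_counts(genes, reg, "WT", n_reps = 10, seed = 1)
  ex <- rpkm(tab$counts, tab$exon_bp, tab$library_sizes, tab$conditions)
  q1 <- rowMeans(ex$rpkm[, tab$conditions$population == "Q1"])
  q2 <- rowMeans(ex$rpkm[, tab$conditions$population == "Q2"])
  expect_gt(q2[["g1"]] / q1[["g1"]], 2.5)
  expect_lt(q2[["g1"]] / q1[["g1"]], 6)
  # baseline-zero gene yields all-zero counts
  expect_identical(sum(tab$counts["g3", ]), 0)

  # genotype_effect = none: WT and DKI agree within 1.5-fold on expectation
  wt <- simulate_counts(genes, reg, "WT", n_reps = 10, seed = 2)
  dki <- simulate_counts(genes, reg, "DKI", n_reps = 10, seed = 3)
  r <- mean(wt$counts["g2", ]) / mean(dki$counts["g2", ])
  expect_lt(max(r, 1 / r), 1.5)
  # dki_lost: the Q3 change is present in WT, suppressed in DKI
  expect_gt(mean(wt$counts["g4", wt$conditions$population == "Q3"]) /
              mean(dki$counts["g4", dki$conditions$population == "Q3"]), 2.5)

  expect_error(simulate_counts(genes, reg, "WT", dispersion = 0, seed = 1),
               "dispersion")
  expect_error(simulate_counts(genes, de_registry("nope", "Q1Q2", "up", 2,
                                                  "none"),
                               "WT", seed = 1), "missing from gene models")
})
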