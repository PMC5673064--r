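# Independent brute-force oracles and shared fixtures for the suite.

# Poisson upper tail by direct pmf summation (independent of ppois)
bf_poisson_tail <- function(count, lambda, kmax = 500) {
  sum(exp(-lambda + (count:kmax) * log(lambda) - lfactorial(count:kmax)))
}

# all-pairs double loop over motif hits
bf_find_tandem <- function(hits, max_spacer) {
  out <- list()
  for (i in seq_len(nrow(hits))) for (j in seq_len(nrow(hits))) {
    if (i == j || hits$chrom[i] != hits$chrom[j]) next
    spacer <- hits$start[j] - hits$end[i]
    if (spacer >= 0 && spacer <= max_spacer)
      out[[length(out) + 1L]] <- c(i = i, j = j, spacer = spacer)
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(),
                                      spacer = integer()))
  as.data.frame(do.call(rbind, out))
}

# per-base membership oracle for the bound-gene rule
bf_gene_bound <- function(peak, gene, upstream = 5000) {
  gene_bases <- seq(gene$start, gene$end - 1L)
  up_bases <- if (gene$strand == "+") {
    seq(max(0L, gene$start - upstream), gene$start - 1L)
  } else {
    seq(gene$end, gene$end + upstream - 1L)
  }
  member <- union(gene_bases, up_bases)
  peak_bases <- seq(peak$start, peak$end - 1L)
  gene$chrom == peak$chrom && length(intersect(member, peak_bases)) > 0
}

# does interval [s1,e1) overlap any row of a (chrom,start,end) table?
any_overlap <- function(chrom, s, e, tab) {
  any(tab$chrom == chrom & tab$start < e & s < tab$end)
}

# shared end-to-end contrast run on synthetic defaults: genome -> reads ->
# coverage -> peaks -> WT-vs-DKI classification
run_contrast <- function(cfg) {
  gg <- generate_genome(cfg)
  lens <- chrom_lengths(gg$genome)
  cc <- caller_config(effective_genome_size = cfg$genome_length)
  covs <- lapply(c(WT = "WT", DKI = "DKI"), function(g) {
    l <- simulate_chip(gg$genome, gg$truth, g, cfg)
    list(trt = windowed_coverage(l$treatment, lens, cc$window,
                                 fragment_length = cfg$fragment_length),
         ctl = windowed_coverage(l$control, lens, cc$window,
                                 fragment_length = cfg$fragment_length))
  })
  peaks <- lapply(covs, function(x) call_peaks(x$trt, x$ctl, cc))
  contrast <- classify_tetramer_sites(peaks$WT, peaks$DKI,
                                      covs$WT$trt, covs$DKI$trt)
  list(genome = gg$genome, truth = gg$truth, lens = lens, cov = covs,
       peaks = peaks, contrast = contrast)
}

# planted-site kind overlapped by each contrast row (NA when off-site)
peak_site_kind <- function(contrast, sites) {
  vapply(seq_len(nrow(contrast)), function(i) {
    k <- sites$kind[sites$chrom == contrast$chrom[i] &
                      sites$start < contrast$end[i] &
                      contrast$start[i] < sites$end]
    if (length(k)) k[1] else NA_character_
  }, character(1))
}
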