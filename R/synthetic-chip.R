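#' Simulate ChIP treatment and control libraries for one genotype
#'
#' Control reads are fragments placed uniformly over the genome. Treatment
#' reads are the same uniform background plus, at every site active in the
#' requested genotype, excess fragments whose midpoints fall uniformly
#' within half a fragment length of the site centre. The expected excess at
#' a fully active site is `(enrichment_fold - 1)` times the local
#' background fragment rate, so total coverage there is about
#' `enrichment_fold` times background. In the DKI genotype, tetramer sites
#' retain only `cfg$residual_enrichment` of that excess (0 by default:
#' background-only coverage), while dimer sites stay fully active --- the
#' genotype asymmetry that the downstream contrast is designed to detect.
#'
#' Reads are single-end, fixed length, on random strands; the 5' end of a
#' plus-strand read is the fragment start and of a minus-strand read the
#' fragment end, as in real single-end ChIP-seq.
#'
#' @param genome `DNAStringSet` from [generate_genome()] (only lengths are
#'   used).
#' @param truth truth list (or its `sites` data.frame) from
#'   [generate_genome()].
#' @param genotype `"WT"` or `"DKI"`.
#' @param cfg the [synthetic_config()] used to build the genome.
#' @return list with sorted BED-like data.frames `treatment` and `control`
#'   (chrom, start, end, name, score, strand).
#' @export
simulate_chip <- function(genome, truth, genotype = c("WT", "DKI"), cfg) {
  genotype <- match.arg(genotype)
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$depth_treatment <= 0 || cfg$depth_control <= 0)
    stop("zero-depth request: depth_treatment and depth_control must be > 0",
         call. = FALSE)
  sites <- if (is.data.frame(truth)) truth else truth$sites
  lens <- chrom_lengths(genome)
  glen <- sum(lens)
  with_seed(cfg$seed + match(genotype, c("WT", "DKI")), {
    bg_rate <- cfg$depth_treatment / glen      # background fragments per base

    uniform_frags <- function(n, prefix) {
      chrom <- sample(names(lens), n, replace = TRUE, prob = lens / glen)
      start <- floor(runif(n, 0, lens[chrom] - cfg$fragment_length))
      make_reads(chrom, start, n, prefix)
    }
    make_reads <- function(chrom, frag_start, n, prefix) {
      strand <- sample(c("+", "-"), n, replace = TRUE)
      rs <- ifelse(strand == "+", frag_start,
                   frag_start + cfg$fragment_length - cfg$read_length)
      data.frame(chrom = chrom, start = as.integer(rs),
                 end = as.integer(rs + cfg$read_length),
                 name = paste0(prefix, seq_len(n)), score = 0L,
                 strand = strand, stringsAsFactors = FALSE)
    }

    trt <- uniform_frags(cfg$depth_treatment, "t")
    if (nrow(sites)) {
      activity <- ifelse(
        vapply(strsplit(sites$active_in, ","), function(g) genotype %in% g,
               logical(1)),
        1, ifelse(sites$kind == "tetramer", cfg$residual_enrichment, 0))
      excess_mean <- (cfg$enrichment_fold - 1) * activity * bg_rate *
        cfg$fragment_length
      n_excess <- rpois(nrow(sites), excess_mean)
      keep <- n_excess > 0
      if (any(keep)) {
        centre <- (sites$start + sites$end) / 2
        mid <- unlist(mapply(function(c0, n) {
          c0 + runif(n, -cfg$fragment_length / 2, cfg$fragment_length / 2)
        }, centre[keep], n_excess[keep], SIMPLIFY = FALSE))
        chrom <- rep(sites$chrom[keep], n_excess[keep])
        fs <- pmax(0, pmin(floor(mid - cfg$fragment_length / 2),
                           lens[chrom] - cfg$fragment_length))
        trt <- rbind(trt, make_reads(chrom, fs, length(fs), "e"))
      }
    }
    ctl <- uniform_frags(cfg$depth_control, "c")
    trt <- trt[order(trt$chrom, trt$start), , drop = FALSE]
    ctl <- ctl[order(ctl$chrom, ctl$start), , drop = FALSE]
    rownames(trt) <- rownames(ctl) <- NULL
    list(treatment = trt, control = ctl)
  })
}

#' Fragment-midpoint positions of single-end reads
#'
#' Shifts each read half a fragment length towards its 3' end, so coverage
#' is counted at the estimated fragment midpoint rather than at the read.
#'
#' @param reads BED-like data.frame with chrom, start, end, strand.
#' @param fragment_length library fragment length in bases.
#' @return data.frame with columns chrom, pos (0-based midpoint).
#' @export
fragment_midpoints <- function(reads, fragment_length) {
  pos <- ifelse(reads$strand == "-",
                reads$end - round(fragment_length / 2),
                reads$start + round(fragment_length / 2))
  data.frame(chrom = reads$chrom, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}
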