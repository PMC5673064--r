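#' GAS consensus used for planted motifs
#'
#' The 9-mer IUPAC consensus `TTCYNRGAA` of the gamma-interferon activated
#' sequence. It is its own reverse complement at the degenerate level, which
#' is why single-strand deduplication of motif hits is required downstream.
#' @export
GAS_CONSENSUS <- "TTCYNRGAA"

# sample n concrete expansions of the degenerate GAS consensus
sample_gas <- function(n) {
  if (n == 0L) return(character(0))
  y <- sample(c("C", "T"), n, replace = TRUE)
  nn <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  r <- sample(c("A", "G"), n, replace = TRUE)
  paste0("TTC", y, nn, r, "GAA")
}

# place n site start positions in [margin, L - margin - width) with at
# least `sep` bases between consecutive starts; capacity error otherwise
place_sites <- function(n, chrom_length, margin, sep, width) {
  if (n == 0L) return(integer(0))
  usable <- chrom_length - 2 * margin - width
  slack <- usable - (n - 1) * sep
  if (slack < 0)
    stop("cannot place ", n, " sites on a ", chrom_length,
         "-bp chromosome without overlap; increase genome_length or reduce sites",
         call. = FALSE)
  margin + floor(sort(runif(n, 0, slack))) + (seq_len(n) - 1L) * sep
}

#' Generate a synthetic genome with planted GAS sites
#'
#' Draws an i.i.d. base sequence at the requested GC content and plants
#' non-overlapping binding sites: *dimer* sites carry a single concrete
#' expansion of [GAS_CONSENSUS]; *tetramer* sites carry two tandem
#' expansions separated by a spacer drawn from
#' `cfg$spacer_distribution` (spacer = bases strictly between the last base
#' of the upstream 9-mer and the first base of the downstream 9-mer). Sites
#' are kept at least `cfg$min_site_separation` apart and at least
#' `cfg$fragment_length` from chromosome ends. Every plant is recorded in
#' the truth registry; tetramer sites are active only in WT, dimer sites in
#' both genotypes.
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `genome` (a [Biostrings::DNAStringSet]),
#'   `truth` (list with a `sites` data.frame: site_id, chrom, start, end,
#'   kind, spacer, active_in), and `cfg`.
#' @examples
#' gg <- generate_genome(synthetic_config(seed = 1))
#' head(gg$truth$sites)
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    chrom_len <- rep(floor(cfg$genome_length / cfg$n_chromosomes),
                     cfg$n_chromosomes)
    chrom_len[cfg$n_chromosomes] <- cfg$genome_length -
      sum(chrom_len[-cfg$n_chromosomes])
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    names(chrom_len) <- chroms

    n_sites <- cfg$n_dimer_sites + cfg$n_tetramer_sites
    # spread sites over chromosomes proportionally to length
    n_per <- floor(n_sites * chrom_len / sum(chrom_len))
    i <- 1L
    while (sum(n_per) < n_sites) {             # distribute the remainder
      n_per[i] <- n_per[i] + 1L
      i <- i %% cfg$n_chromosomes + 1L
    }
    kind <- sample(rep(c("dimer", "tetramer"),
                       c(cfg$n_dimer_sites, cfg$n_tetramer_sites)))
    max_width <- 9L + 9L +
      if (length(cfg$spacer_distribution)) max(as.integer(names(cfg$spacer_distribution))) else 0L

    base_pool <- c("A", "C", "G", "T")
    base_prob <- c((1 - cfg$gc_content) / 2, cfg$gc_content / 2,
                   cfg$gc_content / 2, (1 - cfg$gc_content) / 2)

    seqs <- character(cfg$n_chromosomes)
    sites <- list()
    k <- 0L
    for (ci in seq_len(cfg$n_chromosomes)) {
      letters_vec <- sample(base_pool, chrom_len[ci], replace = TRUE,
                            prob = base_prob)
      starts <- place_sites(n_per[ci], chrom_len[ci],
                            margin = cfg$fragment_length,
                            sep = cfg$min_site_separation,
                            width = max_width)
      for (s in starts) {
        k <- k + 1L
        if (kind[k] == "dimer") {
          motif <- strsplit(sample_gas(1L), "")[[1]]
          letters_vec[(s + 1L):(s + 9L)] <- motif
          sites[[k]] <- data.frame(
            site_id = sprintf("site_%03d", k), chrom = chroms[ci],
            start = as.integer(s), end = as.integer(s + 9L), kind = "dimer",
            spacer = NA_integer_, active_in = "WT,DKI",
            stringsAsFactors = FALSE)
        } else {
          spacer <- as.integer(sample(names(cfg$spacer_distribution), 1L,
                                      prob = cfg$spacer_distribution))
          m1 <- strsplit(sample_gas(1L), "")[[1]]
          m2 <- strsplit(sample_gas(1L), "")[[1]]
          letters_vec[(s + 1L):(s + 9L)] <- m1
          d0 <- s + 9L + spacer                 # start of downstream 9-mer
          letters_vec[(d0 + 1L):(d0 + 9L)] <- m2
          sites[[k]] <- data.frame(
            site_id = sprintf("site_%03d", k), chrom = chroms[ci],
            start = as.integer(s), end = as.integer(d0 + 9L),
            kind = "tetramer", spacer = spacer, active_in = "WT",
            stringsAsFactors = FALSE)
        }
      }
      seqs[ci] <- paste(letters_vec, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chroms
    sites <- if (length(sites)) do.call(rbind, sites) else
      data.frame(site_id = character(), chrom = character(),
                 start = integer(), end = integer(), kind = character(),
                 spacer = integer(), active_in = character(),
                 stringsAsFactors = FALSE)
    sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
    rownames(sites) <- NULL
    list(genome = genome,
         truth = list(sites = sites, de_genes = NULL),
         cfg = cfg)
  })
}

#' Chromosome lengths of a genome
#' @param genome a `DNAStringSet` or named vector of lengths.
#' @return named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(genome) {
  if (inherits(genome, "DNAStringSet"))
    setNames(Biostrings::width(genome), names(genome))
  else genome
}

#' Write / read the planted-site truth registry
#'
#' TSV serialisation with a header row; round-trips losslessly.
#' @param sites truth `sites` data.frame from [generate_genome()].
#' @param path file path.
#' @export
write_truth_sites <- function(sites, path) write_tsv(sites, path)

#' @rdname write_truth_sites
#' @export
read_truth_sites <- function(path) {
  x <- read_tsv(path)
  x$spacer <- as.integer(x$spacer)
  x
}
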