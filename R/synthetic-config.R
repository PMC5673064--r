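#' Configuration for the synthetic ChIP-seq study
#'
#' Bundles every parameter of the simulated two-genotype ChIP-seq experiment:
#' a random genome with planted GAS motifs (single motifs standing for dimer
#' sites, tandem motif pairs for tetramer sites), fragment coverage enriched
#' at planted sites, and matched input control. Tetramer sites are active
#' only in the wild-type (WT) genotype; dimer sites are active in both WT
#' and the tetramer-deficient knockin (DKI), which encodes the biological
#' premise that the knockin abolishes tetramer but not dimer binding.
#'
#' Defaults describe a desk-scale study: a 500-kb genome over two
#' chromosomes, 25 dimer and 25 tetramer sites separated by at least 7 kb,
#' 25,000 single-end 50-bp reads per library (about one background fragment
#' midpoint per 20-bp window), 20-fold enrichment at active sites, and a
#' tetramer spacer mixture concentrated on 11, 12, 13 and 16 nt.
#'
#' @param genome_length total genome length in bases (summed over
#'   chromosomes).
#' @param n_chromosomes number of chromosomes; lengths are split evenly.
#' @param gc_content fraction of G+C bases in the background sequence.
#' @param n_dimer_sites,n_tetramer_sites numbers of planted sites.
#' @param spacer_distribution named numeric vector mapping spacer length
#'   (bases strictly between the two 9-mers of a tandem pair) to
#'   probability; must sum to 1.
#' @param read_length,fragment_length single-end read and ChIP fragment
#'   lengths in bases.
#' @param depth_treatment,depth_control background reads per treatment /
#'   control library (enriched fragments are emitted on top of the
#'   treatment background; realised library sizes are recorded).
#' @param enrichment_fold local fragment rate at an active site relative to
#'   background; must be >= 1.
#' @param residual_enrichment fraction of the tetramer-site excess retained
#'   in the DKI genotype (0 = complete loss; the in-vivo residual dimer
#'   occupancy at tetramer sites is unknown, so it is a knob, not a fact).
#' @param min_site_separation minimum distance in bases between planted
#'   sites (also enforced against chromosome ends via `fragment_length`).
#' @param seed mandatory RNG seed; identical seed implies identical output.
#' @return an object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' cfg
#' @export
synthetic_config <- function(genome_length = 5e5,
                             n_chromosomes = 2,
                             gc_content = 0.42,
                             n_dimer_sites = 25,
                             n_tetramer_sites = 25,
                             spacer_distribution = c("11" = 0.25, "12" = 0.25,
                                                     "13" = 0.25, "16" = 0.25),
                             read_length = 50,
                             fragment_length = 200,
                             depth_treatment = 25000,
                             depth_control = 25000,
                             enrichment_fold = 20,
                             residual_enrichment = 0,
                             min_site_separation = 7000,
                             seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  stopifnot_scalar(genome_length, "genome_length", min = 1000)
  stopifnot_scalar(n_chromosomes, "n_chromosomes", min = 1)
  stopifnot_scalar(gc_content, "gc_content", min = 0, max = 1)
  stopifnot_scalar(n_dimer_sites, "n_dimer_sites", min = 0)
  stopifnot_scalar(n_tetramer_sites, "n_tetramer_sites", min = 0)
  stopifnot_scalar(enrichment_fold, "enrichment_fold", min = 1)
  stopifnot_scalar(residual_enrichment, "residual_enrichment", min = 0, max = 1)
  stopifnot_scalar(read_length, "read_length", min = 1)
  stopifnot_scalar(fragment_length, "fragment_length", min = read_length)
  stopifnot_scalar(depth_treatment, "depth_treatment", min = 0)
  stopifnot_scalar(depth_control, "depth_control", min = 0)
  if (is.null(names(spacer_distribution)) ||
      any(is.na(suppressWarnings(as.integer(names(spacer_distribution))))))
    stop("'spacer_distribution' must be named by integer spacer lengths",
         call. = FALSE)
  if (abs(sum(spacer_distribution) - 1) > 1e-9)
    stop("'spacer_distribution' probabilities must sum to 1", call. = FALSE)
  n_sites <- n_dimer_sites + n_tetramer_sites
  if (n_sites > 0 && genome_length < 10 * n_sites * fragment_length)
    stop("genome_length must be >= 10 * n_sites * fragment_length",
         call. = FALSE)
  structure(list(
    genome_length = genome_length, n_chromosomes = as.integer(n_chromosomes),
    gc_content = gc_content,
    n_dimer_sites = as.integer(n_dimer_sites),
    n_tetramer_sites = as.integer(n_tetramer_sites),
    spacer_distribution = spacer_distribution,
    read_length = as.integer(read_length),
    fragment_length = as.integer(fragment_length),
    depth_treatment = depth_treatment, depth_control = depth_control,
    enrichment_fold = enrichment_fold,
    residual_enrichment = residual_enrichment,
    min_site_separation = min_site_separation,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic genotype-contrast ChIP-seq configuration\n")
  cat(sprintf("  genome: %s bp over %d chromosome(s), GC %.2f\n",
              format(x$genome_length, big.mark = ","), x$n_chromosomes,
              x$gc_content))
  cat(sprintf("  planted sites: %d dimer + %d tetramer (spacers: %s)\n",
              x$n_dimer_sites, x$n_tetramer_sites,
              paste(sprintf("%s nt @ %.2f", names(x$spacer_distribution),
                            x$spacer_distribution), collapse = ", ")))
  cat(sprintf("  libraries: %g treatment / %g control reads, %d bp reads, %d bp fragments\n",
              x$depth_treatment, x$depth_control, x$read_length,
              x$fragment_length))
  cat(sprintf("  enrichment: %gx at active sites (DKI residual at tetramer sites: %gx)\n",
              x$enrichment_fold, x$residual_enrichment))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
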