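#' Peak-caller configuration
#'
#' Parameters of the Poisson sliding-window caller. The defaults mirror
#' standard transcription-factor ChIP-seq practice on mouse data: a p-value
#' threshold of 1e-5 and an effective (mappable) genome size of 2.7e9
#' bases. For synthetic or toy genomes, set `effective_genome_size` to the
#' actual genome length so the genome-wide background expectation is on the
#' right scale.
#'
#' @param p_threshold Poisson upper-tail probability below which a window
#'   is candidate-enriched.
#' @param effective_genome_size mappable genome length in bases, the
#'   denominator of the genome-wide background rate.
#' @param window window width in bases.
#' @param merge_gap candidate windows closer than this many bases merge
#'   into one peak (default: one window, so contiguous significant windows
#'   form one site).
#' @return object of class `caller_config`.
#' @export
caller_config <- function(p_threshold = 1e-5,
                          effective_genome_size = 2.7e9,
                          window = 20,
                          merge_gap = window) {
  stopifnot_scalar(p_threshold, "p_threshold")
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("'p_threshold' must be in (0, 1)", call. = FALSE)
  stopifnot_scalar(effective_genome_size, "effective_genome_size", min = 1)
  stopifnot_scalar(window, "window", min = 1)
  stopifnot_scalar(merge_gap, "merge_gap", min = 0)
  structure(list(p_threshold = p_threshold,
                 effective_genome_size = effective_genome_size,
                 window = as.integer(window),
                 merge_gap = as.integer(merge_gap)),
            class = "caller_config")
}

#' Poisson upper-tail probability
#'
#' `P(X >= count)` for `X ~ Poisson(lambda)` --- the enrichment p-value of
#' a window with `count` treatment reads under background rate `lambda`.
#'
#' @param count observed window count (vectorised).
#' @param lambda background expectation (vectorised).
#' @return upper-tail probabilities.
#' @examples
#' poisson_tail(10, 2)   # ~4.6e-5, not significant at 1e-5
#' poisson_tail(12, 2)   # ~1.4e-6, significant
#' @export
poisson_tail <- function(count, lambda) {
  ppois(count - 1, lambda, lower.tail = FALSE)
}

#' Call enriched peaks from treatment vs control window coverage
#'
#' A window is candidate-enriched when the Poisson upper tail of its
#' treatment count is at most `cfg$p_threshold` under a background rate
#' taken as the maximum of three expectations (a MACS-style dynamic
#' background): the depth-scaled control count in the window itself, the
#' depth-scaled control rate in a surrounding 1-kb region, and the
#' genome-wide treatment expectation
#' `library_size * window / effective_genome_size`. Candidate windows
#' separated by at most `cfg$merge_gap` bases merge into one peak. The
#' summit is the centre of the maximum-count window (leftmost on ties);
#' enrichment is treatment count over background at the summit window.
#'
#' @param treatment,control `window_coverage` objects on the same
#'   chromosomes and window grid; control is scaled to treatment depth by
#'   the ratio of library sizes.
#' @param cfg a [caller_config()].
#' @return data.frame of class `peak_set` with columns chrom, start, end,
#'   name, summit, enrichment, p_value, norm_height.
#' @export
call_peaks <- function(treatment, control, cfg = caller_config()) {
  stopifnot(inherits(treatment, "window_coverage"),
            inherits(control, "window_coverage"),
            inherits(cfg, "caller_config"))
  if (!setequal(unique(treatment$chrom), unique(control$chrom)))
    stop("mismatched chromosome sets between treatment and control",
         call. = FALSE)
  w <- attr(treatment, "window")
  if (w != attr(control, "window"))
    stop("treatment and control must use the same window width", call. = FALSE)
  lib_t <- attr(treatment, "library_size")
  lib_c <- attr(control, "library_size")
  if (lib_t <= 0 || lib_c <= 0) stop("empty library", call. = FALSE)
  scale <- lib_t / lib_c
  lam_global <- lib_t * w / cfg$effective_genome_size

  peaks <- list()
  for (ch in unique(treatment$chrom)) {
    trt <- treatment[treatment$chrom == ch, , drop = FALSE]
    ctl <- control[control$chrom == ch, , drop = FALSE]
    n <- nrow(trt)
    half <- max(1L, round(1000 / w / 2))
    cs <- cumsum(c(0, ctl$count))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    lam_1kb <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L) * scale
    lam <- pmax(ctl$count * scale, lam_1kb, lam_global)
    pv <- poisson_tail(trt$count, lam)
    cand <- which(pv <= cfg$p_threshold & trt$count > lam)
    if (!length(cand)) next
    gap_bp <- trt$start[cand[-1]] - trt$end[cand[-length(cand)]]
    grp <- cumsum(c(1L, as.integer(gap_bp > cfg$merge_gap)))
    for (g in unique(grp)) {
      idx <- cand[grp == g]
      best <- idx[which.max(trt$count[idx])]   # which.max is leftmost on ties
      summit <- min(trt$start[best] + w %/% 2L, trt$end[best] - 1L)
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = ch, start = trt$start[idx[1L]], end = trt$end[idx[length(idx)]],
        summit = summit,
        enrichment = trt$count[best] / lam[best],
        p_value = min(pv[idx]),
        norm_height = trt$norm[best],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               summit = integer(), enrichment = numeric(),
               p_value = numeric(), norm_height = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- if (nrow(out)) sprintf("peak_%d", seq_len(nrow(out))) else character(0)
  out <- out[, c("chrom", "start", "end", "name", "summit", "enrichment",
                 "p_value", "norm_height")]
  rownames(out) <- NULL
  structure(out, class = c("peak_set", "data.frame"), cfg = cfg)
}

#' Export peaks as BED6+ and full TSV
#'
#' BED score column carries `-log10(p_value)`.
#' @param peaks a `peak_set`.
#' @param bed,tsv output paths (either may be NULL to skip).
#' @export
write_peaks <- function(peaks, bed = NULL, tsv = NULL) {
  if (!is.null(bed)) {
    b <- peaks
    b$score <- round(-log10(pmax(peaks$p_value, 1e-300)), 2)
    b$strand <- "."
    write_bed(b, bed)
  }
  if (!is.null(tsv)) write_tsv(as.data.frame(peaks), tsv)
  invisible(peaks)
}
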