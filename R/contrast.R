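#' Match peaks between two peak sets
#'
#' Pairs peaks one-to-one: a peak in A may match a peak in B when their
#' intervals overlap by at least 1 bp (`rule = "overlap"`) or when their
#' summits are within `max_summit_dist` bases (`rule = "summit"`).
#' Candidate pairs are resolved greedily by smallest summit distance, ties
#' to the leftmost peak, which is deterministic and equals the optimal
#' assignment when peaks are well separated.
#'
#' @param peaks_a,peaks_b peak data.frames (chrom, start, end, summit).
#' @param rule matching rule, `"overlap"` or `"summit"`.
#' @param max_summit_dist summit-distance cutoff in bases for
#'   `rule = "summit"`.
#' @return list of class `peak_match`: `pairs` (data.frame a, b,
#'   summit_dist of row indices), `unmatched_a`, `unmatched_b` (row
#'   indices).
#' @export
match_peaks <- function(peaks_a, peaks_b, rule = c("overlap", "summit"),
                        max_summit_dist = 100) {
  rule <- match.arg(rule)
  cand <- list()
  if (nrow(peaks_a) && nrow(peaks_b)) {
    for (ch in intersect(unique(peaks_a$chrom), unique(peaks_b$chrom))) {
      ia <- which(peaks_a$chrom == ch)
      ib <- which(peaks_b$chrom == ch)
      if (rule == "overlap") {
        ov <- IRanges::findOverlaps(
          IRanges::IRanges(peaks_a$start[ia] + 1L, peaks_a$end[ia]),
          IRanges::IRanges(peaks_b$start[ib] + 1L, peaks_b$end[ib]),
          minoverlap = 1L)
        ai <- ia[S4Vectors_from(ov)]
        bi <- ib[S4Vectors_to(ov)]
      } else {
        grid <- expand.grid(ai = ia, bi = ib)
        d <- abs(peaks_a$summit[grid$ai] - peaks_b$summit[grid$bi])
        keep <- d <= max_summit_dist
        ai <- grid$ai[keep]; bi <- grid$bi[keep]
      }
      if (length(ai))
        cand[[ch]] <- data.frame(
          a = ai, b = bi,
          summit_dist = abs(peaks_a$summit[ai] - peaks_b$summit[bi]))
    }
  }
  pairs <- data.frame(a = integer(), b = integer(), summit_dist = integer())
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$summit_dist, cand$a, cand$b), , drop = FALSE]
    used_a <- logical(nrow(peaks_a)); used_b <- logical(nrow(peaks_b))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!used_a[cand$a[i]] && !used_b[cand$b[i]]) {
        keep[i] <- TRUE
        used_a[cand$a[i]] <- TRUE
        used_b[cand$b[i]] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(seq_len(nrow(peaks_a)), pairs$a),
                 unmatched_b = setdiff(seq_len(nrow(peaks_b)), pairs$b),
                 rule = rule),
            class = "peak_match")
}

# thin wrappers so the S4 Hits accessors stay in one place
S4Vectors_from <- function(ov) as.integer(S4Vectors::queryHits(ov))
S4Vectors_to <- function(ov) as.integer(S4Vectors::subjectHits(ov))

#' Shared/specific accounting of two peak sets
#'
#' Totals, shared (matched) count and the two specific counts, with the
#' shared fraction per set; the arithmetic identities
#' `a_specific = set_a_total - shared` and
#' `b_specific = set_b_total - shared` are enforced.
#'
#' @param set_a_total,set_b_total,shared counts; or pass peak sets to
#'   [venn_accounting()] to compute `shared` by matching.
#' @return object of class `venn_counts` with fields set_a_total,
#'   set_b_total, shared, a_specific, b_specific, union,
#'   shared_fraction_a, shared_fraction_b.
#' @examples
#' venn_counts(2748, 11526, 1935)
#' @export
venn_counts <- function(set_a_total, set_b_total, shared) {
  stopifnot_scalar(set_a_total, "set_a_total", min = 0)
  stopifnot_scalar(set_b_total, "set_b_total", min = 0)
  stopifnot_scalar(shared, "shared", min = 0)
  if (shared > set_a_total || shared > set_b_total)
    stop("'shared' cannot exceed either total", call. = FALSE)
  out <- list(set_a_total = set_a_total, set_b_total = set_b_total,
              shared = shared,
              a_specific = set_a_total - shared,
              b_specific = set_b_total - shared,
              union = set_a_total + set_b_total - shared,
              shared_fraction_a = if (set_a_total > 0) shared / set_a_total else NA_real_,
              shared_fraction_b = if (set_b_total > 0) shared / set_b_total else NA_real_)
  structure(out, class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("Venn counts: |A| = %d, |B| = %d, shared = %d\n",
              x$set_a_total, x$set_b_total, x$shared))
  cat(sprintf("  A-specific = %d, B-specific = %d, union = %d\n",
              x$a_specific, x$b_specific, x$union))
  cat(sprintf("  shared fraction: %.1f%% of A, %.1f%% of B\n",
              100 * x$shared_fraction_a, 100 * x$shared_fraction_b))
  invisible(x)
}

#' @rdname venn_counts
#' @param peaks_a,peaks_b peak sets to match.
#' @param rule,max_summit_dist passed to [match_peaks()].
#' @export
venn_accounting <- function(peaks_a, peaks_b, rule = "overlap",
                            max_summit_dist = 100) {
  m <- match_peaks(peaks_a, peaks_b, rule, max_summit_dist)
  venn_counts(nrow(peaks_a), nrow(peaks_b), nrow(m$pairs))
}

#' Classify WT peaks as tetramer-specific or shared against DKI
#'
#' A WT peak is `tetramer_specific` when its depth-normalised WT/DKI
#' intensity ratio is at least `reduction_fold`; otherwise it is `shared`
#' (dimer-compatible binding). For peaks with no matching DKI peak the DKI
#' intensity is the DKI coverage at the WT summit, so a site genuinely
#' absent in DKI shows a ratio far above the threshold, while a WT peak
#' that merely fragmented at the calling step (leaving its twin DKI signal
#' matched to another fragment) is still recognised as shared. Matched
#' peaks passing the ratio are flagged `reduced = TRUE` (binding retained
#' but markedly weaker); absent and reduced flavours stay distinguishable
#' in the output. DKI-only peaks are reported in the `dki_only` attribute.
#'
#' The ratio is pseudocount-stabilised:
#' `(WT_rpm + pseudocount) / (DKI_rpm + pseudocount)` with intensities in
#' reads per million. For matched peaks both intensities are the peaks' own
#' summit heights; taking each genotype's height at its own summit keeps
#' the estimator symmetric (each is equally biased by summit selection),
#' whereas reading the DKI library at the WT summit would systematically
#' inflate the ratio. For unmatched WT peaks the DKI intensity is the DKI
#' coverage at the WT summit.
#'
#' @param wt_peaks,dki_peaks `peak_set`s for the two genotypes.
#' @param wt_cov,dki_cov `window_coverage` of the two treatment libraries
#'   (already depth-normalised via their library sizes).
#' @param reduction_fold intensity ratio at or above which a matched site
#'   counts as lost/reduced (default 2).
#' @param pseudocount reads-per-million pseudocount (default 0.5).
#' @param rule,max_summit_dist passed to [match_peaks()].
#' @return data.frame of class `site_contrast`: WT peak columns plus
#'   dki_peak (matched peak name or NA), dki_height, intensity_ratio,
#'   classification, reduced; attribute `dki_only` holds unmatched DKI
#'   peaks.
#' @export
classify_tetramer_sites <- function(wt_peaks, dki_peaks, wt_cov, dki_cov,
                                    reduction_fold = 2, pseudocount = 0.5,
                                    rule = "overlap", max_summit_dist = 100) {
  if (nrow(wt_peaks) == 0L) stop("empty WT peak set", call. = FALSE)
  m <- match_peaks(wt_peaks, dki_peaks, rule, max_summit_dist)
  wt_h <- if ("norm_height" %in% names(wt_peaks)) wt_peaks$norm_height else
    coverage_at(wt_cov, wt_peaks$chrom, wt_peaks$summit)
  dki_h <- coverage_at(dki_cov, wt_peaks$chrom, wt_peaks$summit)
  if ("norm_height" %in% names(dki_peaks))
    dki_h[m$pairs$a] <- dki_peaks$norm_height[m$pairs$b]
  ratio <- (wt_h + pseudocount) / (dki_h + pseudocount)
  dki_name <- rep(NA_character_, nrow(wt_peaks))
  dki_name[m$pairs$a] <- dki_peaks$name[m$pairs$b]
  matched <- !is.na(dki_name)
  reduced <- matched & ratio >= reduction_fold
  classification <- ifelse(ratio >= reduction_fold,
                           "tetramer_specific", "shared")
  out <- data.frame(wt_peaks, dki_peak = dki_name, dki_height = dki_h,
                    wt_height = wt_h, intensity_ratio = ratio,
                    classification = classification, reduced = reduced,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("site_contrast", "data.frame"),
            dki_only = dki_peaks[m$unmatched_b, , drop = FALSE])
}
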