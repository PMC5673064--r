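#' Binding-profile matrix around peak summits
#'
#' For each retained summit, takes the `2 * flank / bin` coverage windows
#' spanning +/- `flank` around the summit's window (so a 3-kb flank at
#' 20-bp bins gives 300 columns) and fills the row with library-size-
#' normalised counts. Summits closer than `flank` to a chromosome end are
#' dropped with a warning.
#'
#' @param peaks a `peak_set` (or data.frame with chrom and summit).
#' @param coverage a `window_coverage` whose window width equals `bin`.
#' @param flank half-width of the profiled region in bases.
#' @param bin bin width in bases; must match the coverage window.
#' @return numeric matrix of class `profile_matrix` (rows = summits,
#'   columns = bins), rownames = peak names.
#' @export
profile_matrix <- function(peaks, coverage, flank = 3000, bin = 20) {
  stopifnot(inherits(coverage, "window_coverage"))
  if (nrow(peaks) == 0L) stop("empty peak list", call. = FALSE)
  w <- attr(coverage, "window")
  if (w != bin)
    stop("'bin' must equal the coverage window width (", w, ")", call. = FALSE)
  if (flank %% bin != 0) stop("'flank' must be a multiple of 'bin'", call. = FALSE)
  half <- flank %/% bin
  lens <- attr(coverage, "chrom_lens")
  ok <- peaks$summit >= flank & peaks$summit < lens[peaks$chrom] - flank
  if (any(!ok))
    warning(sum(!ok), " summit(s) closer than ", flank,
            " bp to a chromosome end were dropped")
  peaks <- peaks[ok, , drop = FALSE]
  if (nrow(peaks) == 0L) stop("no summit is at least 'flank' from chromosome ends",
                              call. = FALSE)
  # index of the first window of each chromosome block in `coverage`
  block0 <- match(names(lens), coverage$chrom)
  names(block0) <- names(lens)
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    centre <- block0[[peaks$chrom[i]]] + peaks$summit[i] %/% w
    coverage$norm[centre + seq(-half, half - 1L)]
  })
  m <- do.call(rbind, rows)
  rownames(m) <- if ("name" %in% names(peaks)) peaks$name else NULL
  structure(m, class = c("profile_matrix", "matrix", "array"),
            bin = bin, flank = flank)
}

#' K-means grouping of binding profiles
#'
#' Clusters profile rows with `stats::kmeans` under a fixed seed; labels
#' are reported 0-based to match the package's 0-based conventions. With
#' `k` equal to the number of rows every row is its own cluster (zero
#' within-cluster sum of squares).
#'
#' @param mat a [profile_matrix()] (any numeric matrix works).
#' @param k number of clusters, `1 <= k <= nrow(mat)`.
#' @param seed RNG seed for the k-means initialisation.
#' @return integer vector of labels in `0:(k-1)`, named by rownames, with
#'   the within-cluster sum of squares in attribute `tot.withinss`.
#' @export
kmeans_profiles <- function(mat, k, seed) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  if (k > nrow(mat)) stop("'k' must not exceed the number of rows", call. = FALSE)
  if (k == nrow(mat)) {
    labels <- seq_len(nrow(mat)) - 1L
  } else {
    fit <- with_seed(seed, kmeans(unclass(mat), centers = k,
                                  nstart = 5, iter.max = 100))
    labels <- fit$cluster - 1L
    attr(labels, "tot.withinss") <- fit$tot.withinss
  }
  names(labels) <- rownames(mat)
  if (k == nrow(mat)) attr(labels, "tot.withinss") <- 0
  labels
}
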