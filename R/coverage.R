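#' Windowed, library-size-normalised read coverage
#'
#' Tiles each chromosome with fixed-width windows and counts reads per
#' window, assigning each read to the window containing its fragment
#' midpoint (when `fragment_length` is given; otherwise the read-interval
#' midpoint). Raw counts are divided by `library_size / 1e6`, i.e. reported
#' in reads per million. Every read falls in exactly one window, so
#' `sum(norm) * library_size / 1e6` equals the read count (coverage
#' conservation).
#'
#' @param reads BED-like data.frame (chrom, start, end, strand).
#' @param chrom_lens named vector of chromosome lengths (see
#'   [chrom_lengths()]).
#' @param window window width in bases (default 20).
#' @param library_size reads in the library; defaults to `nrow(reads)`.
#' @param fragment_length if given, reads are shifted to fragment midpoints
#'   first (see [fragment_midpoints()]).
#' @return object of class `window_coverage`: a data.frame with chrom,
#'   start, end, count, norm, carrying `window`, `library_size` and
#'   `chrom_lens` attributes.
#' @export
windowed_coverage <- function(reads, chrom_lens, window = 20,
                              library_size = nrow(reads),
                              fragment_length = NULL) {
  if (is.null(library_size) || library_size <= 0)
    stop("empty library: library_size must be > 0", call. = FALSE)
  stopifnot_scalar(window, "window", min = 1)
  pos <- if (!is.null(fragment_length))
    fragment_midpoints(reads, fragment_length)
  else data.frame(chrom = reads$chrom,
                  pos = as.integer((reads$start + reads$end) %/% 2L),
                  stringsAsFactors = FALSE)
  out <- lapply(names(chrom_lens), function(ch) {
    L <- chrom_lens[[ch]]
    nwin <- ceiling(L / window)
    p <- pos$pos[pos$chrom == ch]
    p <- pmin(pmax(p, 0L), L - 1L)             # clip shifted midpoints
    counts <- tabulate(p %/% window + 1L, nbins = nwin)
    data.frame(chrom = ch,
               start = (seq_len(nwin) - 1L) * as.integer(window),
               end = pmin(seq_len(nwin) * as.integer(window), L),
               count = counts,
               norm = counts / (library_size / 1e6),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("window_coverage", "data.frame"),
            window = as.integer(window), library_size = library_size,
            chrom_lens = chrom_lens)
}

# normalised coverage of the window containing position `pos` on `chrom`
coverage_at <- function(cov, chrom, pos) {
  w <- attr(cov, "window")
  idx <- match(paste(chrom, pos %/% w), paste(cov$chrom, cov$start %/% w))
  cov$norm[idx]
}
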