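#' @importFrom stats ppois rpois rbinom rnbinom runif kmeans setNames
#' @importFrom utils write.table read.table packageVersion
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state,
# so every generator is a pure function of (cfg, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  invisible(x)
}

#' Write genomic intervals as BED6
#'
#' Coordinates throughout the package are 0-based half-open, i.e. BED's
#' native convention, so intervals are written without any shift.
#'
#' @param x data.frame with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bed <- data.frame(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file into the package's interval data.frame
#'
#' @param path BED file (0-based half-open, as written by [write_bed()]).
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(x)[seq_len(min(6L, ncol(x)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6L, ncol(x)))]
  x
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# interval overlap (0-based half-open): TRUE when [s1,e1) and [s2,e2) share
# at least one base
overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
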