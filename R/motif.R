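#' GAS motif model
#'
#' Describes how GAS elements are recognised: either strict matching of an
#' IUPAC consensus (default [GAS_CONSENSUS], `TTCYNRGAA`), or relaxed
#' position-weight-matrix scoring for the lower-affinity, "non-consensus"
#' elements characteristic of tetramer half-sites. `N` bases in the
#' scanned sequence never match.
#'
#' @param consensus IUPAC consensus string (used when `pwm` is NULL).
#' @param pwm optional 4 x L probability matrix with rows A, C, G, T;
#'   columns must each sum to 1.
#' @param score_threshold fraction of the PWM score range (0-1) a window
#'   must reach to be reported; ignored for consensus matching.
#' @return object of class `gas_model`.
#' @seealso [consensus_pwm()] to build a permissive matrix from a
#'   consensus.
#' @export
gas_model <- function(consensus = GAS_CONSENSUS, pwm = NULL,
                      score_threshold = 0.85) {
  if (!is.null(pwm)) {
    stopifnot(is.matrix(pwm), nrow(pwm) == 4L)
    if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
    if (any(abs(colSums(pwm) - 1) > 1e-9))
      stop("PWM columns must sum to 1", call. = FALSE)
    stopifnot_scalar(score_threshold, "score_threshold", min = 0, max = 1)
  } else {
    stopifnot(is.character(consensus), length(consensus) == 1L,
              nchar(consensus) >= 1L)
  }
  structure(list(consensus = consensus, pwm = pwm,
                 score_threshold = score_threshold,
                 length = if (is.null(pwm)) nchar(consensus) else ncol(pwm)),
            class = "gas_model")
}

#' Probability matrix from an IUPAC consensus
#'
#' Each column puts `1 - soft` mass uniformly on the bases allowed by the
#' IUPAC code and `soft` uniformly on the rest, giving a relaxed matrix
#' whose strictness is tuned by the model's `score_threshold`.
#'
#' @param consensus IUPAC string.
#' @param soft probability mass given to disallowed bases per column.
#' @return 4 x L probability matrix (rows A, C, G, T).
#' @export
consensus_pwm <- function(consensus = GAS_CONSENSUS, soft = 0.08) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  cols <- lapply(strsplit(consensus, "")[[1]], function(b) {
    allowed <- strsplit(iupac[[b]], "")[[1]]
    p <- setNames(rep(soft / (4 - length(allowed)), 4), c("A", "C", "G", "T"))
    if (length(allowed) == 4L) p[] <- 0.25
    else p[allowed] <- (1 - soft) / length(allowed)
    p
  })
  m <- do.call(cbind, cols)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

# single-chromosome scan; returns 0-based hits
scan_one <- function(seq, model, chrom) {
  hits <- list()
  if (is.null(model$pwm)) {
    pat <- Biostrings::DNAString(model$consensus)
    for (str in c("+", "-")) {
      p <- if (str == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::matchPattern(p, seq, fixed = "subject")
      if (length(m))
        hits[[str]] <- data.frame(
          chrom = chrom, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), strand = str, score = 1,
          stringsAsFactors = FALSE)
    }
  } else {
    w <- log2((model$pwm + 1e-4) / 0.25)       # log-odds vs uniform background
    rng <- sum(apply(w, 2, max)) - sum(apply(w, 2, min))
    minsc <- sum(apply(w, 2, min)) + model$score_threshold * rng
    for (str in c("+", "-")) {
      ww <- if (str == "+") w else Biostrings::reverseComplement(w)
      m <- Biostrings::matchPWM(ww, seq, min.score = minsc)
      if (length(m)) {
        sc <- Biostrings::PWMscoreStartingAt(ww, seq, Biostrings::start(m))
        hits[[str]] <- data.frame(
          chrom = chrom, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), strand = str,
          score = (sc - sum(apply(ww, 2, min))) / rng,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(NULL)
  out <- do.call(rbind, hits)
  # drop windows containing N (or any non-ACGT letter)
  sub <- as.character(Biostrings::extractAt(
    seq, IRanges::IRanges(out$start + 1L, out$end)))
  out <- out[!grepl("[^ACGT]", sub), , drop = FALSE]
  out
}

#' Scan sequence for GAS motif hits on both strands
#'
#' Reports every position whose subsequence matches the model on either
#' strand. Because the GAS consensus is quasi-palindromic, a site usually
#' matches on both strands at the same interval; such self-matches are
#' deduplicated by genomic interval (the plus-strand record is kept), so
#' each physical element is reported once.
#'
#' @param sequence a `DNAStringSet` (named by chromosome), `DNAString`, or
#'   character vector.
#' @param model a [gas_model()].
#' @return data.frame of class `motif_hits`: chrom, start, end (0-based
#'   half-open), strand, score; sorted by position.
#' @examples
#' scan_gas(c(chr1 = "GGTTCTAGGAATT"), gas_model())
#' @export
scan_gas <- function(sequence, model = gas_model()) {
  if (is.character(sequence)) sequence <- Biostrings::DNAStringSet(sequence)
  if (inherits(sequence, "DNAString"))
    sequence <- Biostrings::DNAStringSet(list(seq = sequence))
  if (is.null(names(sequence)))
    names(sequence) <- paste0("seq", seq_along(sequence))
  if (any(Biostrings::width(sequence) < model$length))
    stop("sequence shorter than motif", call. = FALSE)
  res <- lapply(names(sequence), function(ch)
    scan_one(sequence[[ch]], model, ch))
  res <- res[!vapply(res, is.null, logical(1))]
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), score = numeric(),
               stringsAsFactors = FALSE)
  # deduplicate palindromic self-matches by interval, preferring "+"
  out <- out[order(out$chrom, out$start,
                   factor(out$strand, levels = c("+", "-"))), , drop = FALSE]
  out <- out[!duplicated(out[, c("chrom", "start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("motif_hits", "data.frame"))
}

#' Enumerate tandemly linked motif pairs
#'
#' Every ordered pair of hits on one chromosome whose spacer --- the number
#' of bases strictly between the upstream hit's end and the downstream
#' hit's start --- is between 0 and `max_spacer`. Hit strands are ignored
#' (the GAS element is quasi-palindromic) and one hit may belong to several
#' pairs.
#'
#' @param hits a [scan_gas()] result (sorted by position).
#' @param max_spacer largest spacer, in bases, to report.
#' @return data.frame of class `tandem_pairs`: chrom, up_start, up_end,
#'   up_strand, down_start, down_end, down_strand, spacer.
#' @export
find_tandem <- function(hits, max_spacer = 30) {
  stopifnot_scalar(max_spacer, "max_spacer", min = 0)
  cols <- c("chrom", "up_start", "up_end", "up_strand",
            "down_start", "down_end", "down_strand", "spacer")
  empty <- setNames(data.frame(character(), integer(), integer(), character(),
                               integer(), integer(), character(), integer(),
                               stringsAsFactors = FALSE), cols)
  if (nrow(hits) < 2L)
    return(structure(empty, class = c("tandem_pairs", "data.frame")))
  out <- list()
  for (ch in unique(hits$chrom)) {
    h <- hits[hits$chrom == ch, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    n <- nrow(h)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        spacer <- h$start[j] - h$end[i]
        if (spacer > max_spacer) break
        if (spacer >= 0)
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, up_start = h$start[i], up_end = h$end[i],
            up_strand = h$strand[i], down_start = h$start[j],
            down_end = h$end[j], down_strand = h$strand[j],
            spacer = spacer, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(out)) do.call(rbind, out) else empty
  rownames(out) <- NULL
  structure(out, class = c("tandem_pairs", "data.frame"))
}

#' Spacer-length distribution of tandem pairs
#'
#' Histogram of spacer lengths, optionally restricted to pairs whose span
#' lies inside a given peak set --- the restriction used when asking which
#' spacings are preferred at bound sites rather than genome-wide.
#'
#' @param pairs a [find_tandem()] result.
#' @param restrict_to optional peak data.frame (chrom, start, end); only
#'   pairs fully contained in some peak are counted.
#' @return object of class `spacing_distribution`: list with `histogram`
#'   (data.frame spacer, count), `total_pairs` and `modes` (spacer values
#'   with maximal count).
#' @export
spacing_distribution <- function(pairs, restrict_to = NULL) {
  if (!is.null(restrict_to) && nrow(pairs)) {
    keep <- vapply(seq_len(nrow(pairs)), function(i) {
      p <- restrict_to[restrict_to$chrom == pairs$chrom[i], , drop = FALSE]
      any(p$start <= pairs$up_start[i] & pairs$down_end[i] <= p$end)
    }, logical(1))
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs)) {
    tab <- table(pairs$spacer)
    hist <- data.frame(spacer = as.integer(names(tab)),
                       count = as.integer(tab))
    modes <- hist$spacer[hist$count == max(hist$count)]
  } else {
    hist <- data.frame(spacer = integer(), count = integer())
    modes <- integer()
  }
  structure(list(histogram = hist, total_pairs = nrow(pairs), modes = modes),
            class = "spacing_distribution")
}

#' @export
print.spacing_distribution <- function(x, ...) {
  cat("Tandem GAS spacing distribution:", x$total_pairs, "pair(s)\n")
  if (nrow(x$histogram)) {
    print(x$histogram, row.names = FALSE)
    cat("mode(s):", paste(x$modes, collapse = ", "), "nt\n")
  }
  invisible(x)
}

#' @export
plot.spacing_distribution <- function(x, ...) {
  if (!nrow(x$histogram)) stop("empty spacing distribution", call. = FALSE)
  graphics::barplot(setNames(x$histogram$count, x$histogram$spacer),
                    xlab = "spacer (nt between tandem GAS motifs)",
                    ylab = "pairs", ...)
  invisible(x)
}

#' Classify peaks by their motif content
#'
#' A peak is `tetramer-like` when it fully contains at least one tandem
#' pair, `dimer-like` when it contains at least one single GAS hit but no
#' pair, and `none` otherwise.
#'
#' @param peaks peak data.frame (chrom, start, end).
#' @param hits a [scan_gas()] result.
#' @param max_spacer largest spacer defining a tandem pair.
#' @return character vector (one of `"tetramer-like"`, `"dimer-like"`,
#'   `"none"`) aligned with the rows of `peaks`.
#' @export
classify_peak_motif <- function(peaks, hits, max_spacer = 30) {
  vapply(seq_len(nrow(peaks)), function(i) {
    h <- hits[hits$chrom == peaks$chrom[i] &
                hits$start >= peaks$start[i] &
                hits$end <= peaks$end[i], , drop = FALSE]
    if (nrow(h) == 0L) return("none")
    if (nrow(find_tandem(h, max_spacer)) > 0L) "tetramer-like" else "dimer-like"
  }, character(1))
}
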