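#' Construct a gene-model table
#'
#' Validates the invariants of the package's gene representation: one TSS
#' per gene (the body start on the plus strand, `end - 1` on the minus
#' strand, 0-based), and exons sorted, non-overlapping and inside the gene
#' body. Exons are encoded as a `"start-end;start-end"` string in the
#' `exons` column; `exon_bp` is their summed length, the RPKM denominator.
#'
#' @param gene_id,chrom,strand,start,end vectors describing gene bodies
#'   (0-based half-open; strand `"+"` or `"-"`).
#' @param exons character vector of exon strings; defaults to one exon
#'   covering the whole body.
#' @return data.frame of class `gene_models` with a derived `tss` and
#'   `exon_bp` column.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end, exons = NULL) {
  if (!all(strand %in% c("+", "-")))
    stop("malformed strand: must be '+' or '-'", call. = FALSE)
  stopifnot(all(start < end))
  if (is.null(exons)) exons <- paste0(start, "-", end)
  exon_bp <- integer(length(exons))
  for (i in seq_along(exons)) {
    e <- parse_exons(exons[i])
    if (any(e$start < start[i]) || any(e$end > end[i]) ||
        any(e$start >= e$end) ||
        (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])))
      stop("exons of ", gene_id[i],
           " must be sorted, non-overlapping and inside the gene body",
           call. = FALSE)
    exon_bp[i] <- sum(e$end - e$start)
  }
  out <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                    start = start, end = end,
                    tss = ifelse(strand == "+", start, end - 1L),
                    exons = exons, exon_bp = exon_bp,
                    stringsAsFactors = FALSE)
  structure(out, class = c("gene_models", "data.frame"))
}

parse_exons <- function(s) {
  parts <- strsplit(strsplit(s, ";")[[1]], "-")
  data.frame(start = as.integer(vapply(parts, `[`, "", 1L)),
             end = as.integer(vapply(parts, `[`, "", 2L)))
}

# strand-aware regulatory window: 5-kb upstream of the TSS plus the gene
# body, as one interval (half-open; clipped at zero / chromosome end)
gene_window <- function(genes, upstream = 5000, chrom_lens = NULL) {
  ws <- ifelse(genes$strand == "+", pmax(0L, genes$start - upstream),
               genes$start)
  we <- ifelse(genes$strand == "+", genes$end, genes$end + upstream)
  if (!is.null(chrom_lens))
    we <- pmin(we, unname(chrom_lens[genes$chrom]))
  data.frame(start = as.integer(ws), end = as.integer(we))
}

#' Assign peaks to genes by the bound-gene rule
#'
#' A peak supports a gene when its interval overlaps, by at least 1 bp,
#' the union of the strand-aware 5-kb-upstream window and the gene body.
#' A peak may support several genes; a call row is returned for every
#' gene. When the peaks carry a `classification` column (from
#' [classify_tetramer_sites()]) the distinct classifications of a gene's
#' supporting peaks are collapsed into `classes`.
#'
#' @param peaks peak data.frame (chrom, start, end, optionally name and
#'   classification).
#' @param genes a [gene_models()] table.
#' @param upstream upstream window size in bases (default 5000).
#' @param chrom_lens optional chromosome lengths for clipping.
#' @return data.frame of class `gene_binding_calls`: gene_id, bound,
#'   n_peaks, supporting_peaks (comma-separated peak names), classes.
#' @export
assign_peaks <- function(peaks, genes, upstream = 5000, chrom_lens = NULL) {
  stopifnot(is.data.frame(peaks), is.data.frame(genes))
  if (!all(genes$strand %in% c("+", "-")))
    stop("malformed strand: must be '+' or '-'", call. = FALSE)
  win <- gene_window(genes, upstream, chrom_lens)
  pk_names <- if ("name" %in% names(peaks)) peaks$name else
    sprintf("peak_%d", seq_len(nrow(peaks)))
  sup <- lapply(seq_len(nrow(genes)), function(g) {
    which(peaks$chrom == genes$chrom[g] &
            overlaps(peaks$start, peaks$end, win$start[g], win$end[g]))
  })
  out <- data.frame(
    gene_id = genes$gene_id,
    bound = lengths(sup) > 0L,
    n_peaks = lengths(sup),
    supporting_peaks = vapply(sup, function(i)
      paste(pk_names[i], collapse = ","), character(1)),
    classes = if ("classification" %in% names(peaks))
      vapply(sup, function(i)
        paste(sort(unique(peaks$classification[i])), collapse = ","),
        character(1))
    else NA_character_,
    stringsAsFactors = FALSE)
  structure(out, class = c("gene_binding_calls", "data.frame"))
}

#' Genes supported by tetramer-specific sites
#'
#' Collapses site-level contrast calls to the gene level: the unique genes
#' supported by at least one `tetramer_specific` peak under the bound-gene
#' rule. Several sites in one gene count once, so the gene count is at
#' most the site count.
#'
#' @param contrasts a [classify_tetramer_sites()] table.
#' @param genes a [gene_models()] table.
#' @param upstream,chrom_lens passed to [assign_peaks()].
#' @return sorted character vector of gene ids.
#' @export
tetramer_genes <- function(contrasts, genes, upstream = 5000,
                           chrom_lens = NULL) {
  tet <- contrasts[contrasts$classification == "tetramer_specific", ,
                   drop = FALSE]
  if (nrow(tet) == 0L) return(character(0))
  calls <- assign_peaks(tet, genes, upstream, chrom_lens)
  sort(calls$gene_id[calls$bound])
}
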