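#' RPKM expression matrix
#'
#' Converts raw exon counts to Reads Per Kilobase of exon model per
#' Million mapped reads:
#' `rpkm = count * 1e9 / (exon_bp * library_size)` cell-wise. Conditions
#' are described by a metadata table carrying the maturation population
#' (Q1 = CD11b-CD27+, Q2 = CD11b+CD27+, Q3 = CD11b+CD27low, or `bulk`),
#' genotype (WT / DKI) and treatment (`none` / `IL15_24h`).
#'
#' @param counts gene x condition matrix of non-negative raw counts
#'   (rownames = gene ids).
#' @param exon_bp per-gene exon length in bases (named or aligned with
#'   rows).
#' @param library_sizes per-condition mapped-read totals (aligned with
#'   columns).
#' @param conditions optional data.frame with columns condition,
#'   population, genotype, treatment; by default parsed from column names
#'   of the form `"WT.Q1"` / `"DKI.Q3.IL15_24h"`.
#' @return object of class `expr_matrix`: list with `rpkm`, `counts`,
#'   `exon_bp`, `library_sizes`, `conditions`.
#' @examples
#' m <- matrix(100, 1, 1, dimnames = list("g1", "WT.Q1"))
#' rpkm(m, exon_bp = 2000, library_sizes = 1e7)$rpkm   # 5
#' @export
rpkm <- function(counts, exon_bp, library_sizes, conditions = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (any(exon_bp <= 0)) stop("exon lengths must be > 0", call. = FALSE)
  if (any(library_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  exon_bp <- rep_len(unname(exon_bp), nrow(counts))
  library_sizes <- rep_len(unname(library_sizes), ncol(counts))
  vals <- sweep(sweep(counts * 1e9, 1, exon_bp, "/"), 2, library_sizes, "/")
  if (is.null(conditions)) {
    parts <- strsplit(colnames(counts), ".", fixed = TRUE)
    conditions <- data.frame(
      condition = colnames(counts),
      genotype = vapply(parts, `[`, "", 1L),
      population = vapply(parts, function(p)
        if (length(p) >= 2L) p[2L] else "bulk", character(1)),
      treatment = vapply(parts, function(p)
        if (length(p) >= 3L) p[3L] else "none", character(1)),
      stringsAsFactors = FALSE)
  }
  structure(list(rpkm = vals, counts = counts, exon_bp = exon_bp,
                 library_sizes = library_sizes, conditions = conditions),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("RPKM expression matrix: %d genes x %d conditions\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  print(x$conditions, row.names = FALSE)
  invisible(x)
}

# mean RPKM over the conditions selected by a logical/index vector
condition_rpkm <- function(expr, sel) {
  m <- expr$rpkm[, sel, drop = FALSE]
  if (ncol(m) == 0L) stop("unknown condition", call. = FALSE)
  rowMeans(m)
}

#' Threshold-based differential-expression calls
#'
#' For an ordered pair of conditions, a gene passes when the larger of its
#' two RPKM values is at least `rpkm_min` and the pseudocount-stabilised
#' fold change `(a + eps) / (b + eps)`, oriented to be >= 1, is at least
#' `fc_min`. Direction is `"up"` when the second condition of the contrast
#' is higher. No p-values and no multiple-testing correction are involved:
#' the definition is purely threshold-based.
#'
#' @param expr an [rpkm()] object.
#' @param contrast character vector of two condition names (columns of the
#'   RPKM matrix), ordered `c(from, to)`.
#' @param rpkm_min expression floor applied to the larger of the pair
#'   (default 5).
#' @param fc_min fold-change threshold (1.5 for maturation-transition and
#'   genotype contrasts, 2 for the cytokine-induction contrast).
#' @param pseudocount RPKM pseudocount stabilising ratios near zero.
#' @return data.frame of class `de_calls`: gene_id, rpkm_from, rpkm_to,
#'   fold_change, direction, passes.
#' @export
de_call <- function(expr, contrast, rpkm_min = 5, fc_min = 1.5,
                    pseudocount = 0.1) {
  stopifnot(inherits(expr, "expr_matrix"), length(contrast) == 2L)
  if (!all(contrast %in% colnames(expr$rpkm)))
    stop("unknown condition: ",
         paste(setdiff(contrast, colnames(expr$rpkm)), collapse = ", "),
         call. = FALSE)
  a <- expr$rpkm[, contrast[1L]]
  b <- expr$rpkm[, contrast[2L]]
  r <- (b + pseudocount) / (a + pseudocount)
  fc <- pmax(r, 1 / r)
  out <- data.frame(
    gene_id = rownames(expr$rpkm),
    rpkm_from = unname(a), rpkm_to = unname(b),
    fold_change = unname(fc),
    direction = ifelse(b >= a, "up", "down"),
    passes = unname(pmax(a, b) >= rpkm_min & fc >= fc_min),
    stringsAsFactors = FALSE)
  structure(out, class = c("de_calls", "data.frame"))
}

#' Differential expression across the two maturation transitions
#'
#' Applies [de_call()] to the Q1 to Q2 and Q2 to Q3 transitions of one
#' genotype (replicate conditions of a population are averaged first) and
#' reports the two passing gene sets, their intersection and the union
#' count, which always satisfies
#' `union = |Q1Q2| + |Q2Q3| - |both|`.
#'
#' @param expr an [rpkm()] object whose conditions cover populations Q1,
#'   Q2 and Q3 for `genotype`.
#' @param genotype genotype whose transitions are examined.
#' @param rpkm_min,fc_min,pseudocount passed to [de_call()].
#' @return object of class `transition_report`: list with `q1q2_set`,
#'   `q2q3_set`, `both_set`, `union_count` and the two `de_calls` tables.
#' @export
transition_report <- function(expr, genotype = "WT", rpkm_min = 5,
                              fc_min = 1.5, pseudocount = 0.1) {
  stopifnot(inherits(expr, "expr_matrix"))
  cond <- expr$conditions
  pop_mean <- lapply(c("Q1", "Q2", "Q3"), function(p) {
    sel <- cond$genotype == genotype & cond$population == p &
      cond$treatment == "none"
    if (!any(sel))
      stop("missing population ", p, " for genotype ", genotype, call. = FALSE)
    condition_rpkm(expr, which(sel))
  })
  mat <- do.call(cbind, setNames(pop_mean, c("Q1", "Q2", "Q3")))
  pooled <- structure(list(
    rpkm = mat, counts = NULL, exon_bp = expr$exon_bp,
    library_sizes = expr$library_sizes,
    conditions = data.frame(condition = c("Q1", "Q2", "Q3"),
                            genotype = genotype,
                            population = c("Q1", "Q2", "Q3"),
                            treatment = "none")), class = "expr_matrix")
  de12 <- de_call(pooled, c("Q1", "Q2"), rpkm_min, fc_min, pseudocount)
  de23 <- de_call(pooled, c("Q2", "Q3"), rpkm_min, fc_min, pseudocount)
  q1q2 <- de12$gene_id[de12$passes]
  q2q3 <- de23$gene_id[de23$passes]
  both <- intersect(q1q2, q2q3)
  structure(list(q1q2_set = q1q2, q2q3_set = q2q3, both_set = both,
                 union_count = length(q1q2) + length(q2q3) - length(both),
                 de_q1q2 = de12, de_q2q3 = de23, genotype = genotype),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("Maturation-transition DE report (%s):\n", x$genotype))
  cat(sprintf("  Q1->Q2: %d genes; Q2->Q3: %d genes; both: %d; union: %d\n",
              length(x$q1q2_set), length(x$q2q3_set), length(x$both_set),
              x$union_count))
  invisible(x)
}

#' Nominate direct tetramer target genes
#'
#' Among genes carrying tetramer-specific binding sites, keeps those whose
#' WT RPKM is at least `fc_min`-fold higher than in DKI --- binding lost
#' without tetramers *and* expression reduced without tetramers, the
#' definition of a direct tetramer target. The IL-15-treated conditions
#' are used when present, otherwise untreated; replicate conditions per
#' genotype are averaged.
#'
#' @param tet_genes character vector of tetramer-bound gene ids (see
#'   [tetramer_genes()]).
#' @param expr an [rpkm()] object with WT and DKI conditions.
#' @param fc_min required WT/DKI fold (default 1.5).
#' @param pseudocount RPKM pseudocount.
#' @return character vector of target gene ids, with a `details`
#'   data.frame attribute (gene_id, wt_rpkm, dki_rpkm, fold_change).
#' @export
tetramer_targets <- function(tet_genes, expr, fc_min = 1.5,
                             pseudocount = 0.1) {
  stopifnot(inherits(expr, "expr_matrix"))
  cond <- expr$conditions
  trt <- if (any(cond$treatment == "IL15_24h")) "IL15_24h" else "none"
  wt <- condition_rpkm(expr, which(cond$genotype == "WT" & cond$treatment == trt))
  dki <- condition_rpkm(expr, which(cond$genotype == "DKI" & cond$treatment == trt))
  present <- intersect(tet_genes, rownames(expr$rpkm))
  fc <- (wt[present] + pseudocount) / (dki[present] + pseudocount)
  details <- data.frame(gene_id = present, wt_rpkm = unname(wt[present]),
                        dki_rpkm = unname(dki[present]),
                        fold_change = unname(fc),
                        stringsAsFactors = FALSE)
  targets <- sort(present[fc >= fc_min])
  attr(targets, "details") <- details
  targets
}
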