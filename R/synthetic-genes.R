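#' Synthetic gene models over a planted-site genome
#'
#' Builds a toy RefSeq-like gene table on the synthetic genome: one gene
#' hosting each planted binding site (the site falls inside the gene body,
#' mimicking the intronic/promoter-proximal binding the contrast is meant
#' to annotate) plus background genes placed so that neither their bodies
#' nor their 5-kb upstream windows touch any planted site. Each gene gets
#' 2--3 exons and a lognormal baseline expression level.
#'
#' @param genome `DNAStringSet` from [generate_genome()].
#' @param truth truth list (or `sites` data.frame).
#' @param gene_length gene-body length in bases.
#' @param n_background_genes genes without any planted site.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of the
#'   per-gene baseline RPKM (defaults give a median of 20 RPKM).
#' @param seed RNG seed.
#' @return a [gene_models()] data.frame with extra columns `host_site`
#'   (site_id or NA) and `baseline_rpkm`.
#' @export
synthetic_gene_models <- function(genome, truth, gene_length = 3000,
                                  n_background_genes = 30,
                                  baseline_meanlog = log(20),
                                  baseline_sdlog = 1, seed) {
  sites <- if (is.data.frame(truth)) truth else truth$sites
  lens <- chrom_lengths(genome)
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(sites))) {
      ch <- sites$chrom[i]
      centre <- (sites$start[i] + sites$end[i]) %/% 2L
      off <- floor(runif(1, 0.25, 0.75) * gene_length)
      s <- max(0L, min(centre - off, lens[[ch]] - gene_length))
      rows[[length(rows) + 1L]] <- list(chrom = ch, start = s,
                                        end = s + gene_length,
                                        host = sites$site_id[i])
    }
    # background genes: keep the whole regulatory window clear of tetramer
    # sites (so tetramer peaks only ever annotate to their host gene);
    # proximity to dimer sites is harmless and realistic
    tet <- sites[sites$kind == "tetramer", , drop = FALSE]
    placed <- 0L
    attempts <- 0L
    while (placed < n_background_genes && attempts < 200L * n_background_genes) {
      attempts <- attempts + 1L
      ch <- sample(names(lens), 1L, prob = lens / sum(lens))
      s <- floor(runif(1, 0, lens[[ch]] - gene_length))
      clear_lo <- s - 5500L
      clear_hi <- s + gene_length + 5500L
      ssch <- tet[tet$chrom == ch, , drop = FALSE]
      busy <- any(overlaps(ssch$start, ssch$end, clear_lo, clear_hi))
      for (r in rows)
        if (r$chrom == ch && overlaps(r$start, r$end, s, s + gene_length))
          busy <- TRUE
      if (!busy) {
        placed <- placed + 1L
        rows[[length(rows) + 1L]] <- list(chrom = ch, start = s,
                                          end = s + gene_length,
                                          host = NA_character_)
      }
    }
    if (placed < n_background_genes)
      warning("placed only ", placed, " of ", n_background_genes,
              " background genes")
    n <- length(rows)
    exon_str <- vapply(rows, function(r) {
      k <- sample(2:3, 1L)
      seg <- floor(gene_length / k)
      es <- vapply(seq_len(k), function(j) {
        w <- floor(seg * runif(1, 0.3, 0.6))
        o <- floor(runif(1, 0, seg - w))
        sprintf("%d-%d", r$start + (j - 1L) * seg + o,
                r$start + (j - 1L) * seg + o + w)
      }, character(1))
      paste(es, collapse = ";")
    }, character(1))
    g <- gene_models(
      gene_id = sprintf("gene_%03d", seq_len(n)),
      chrom = vapply(rows, `[[`, "", "chrom"),
      strand = sample(c("+", "-"), n, replace = TRUE),
      start = vapply(rows, function(r) as.integer(r$start), integer(1)),
      end = vapply(rows, function(r) as.integer(r$end), integer(1)),
      exons = exon_str)
    g$host_site <- vapply(rows, `[[`, "", "host")
    g$baseline_rpkm <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
    g
  })
}

#' Planted differential-expression registry
#'
#' Declares which genes change across the maturation transitions and how
#' the change depends on genotype. `genotype_effect = "dki_lost"` means
#' the transition change happens in WT but is suppressed in DKI (the
#' signature of a tetramer-dependent gene); `"dki_gained"` the reverse;
#' `"none"` the change is genotype-independent.
#'
#' @param gene_id,transition,direction,fold,genotype_effect aligned
#'   vectors; `transition` in `{"Q1Q2","Q2Q3","both"}`, `direction` in
#'   `{"up","down"}`, `fold >= 1`, `genotype_effect` in
#'   `{"none","dki_lost","dki_gained"}`.
#' @return data.frame of class `de_registry`.
#' @export
de_registry <- function(gene_id, transition, direction, fold,
                        genotype_effect) {
  stopifnot(all(transition %in% c("Q1Q2", "Q2Q3", "both")),
            all(direction %in% c("up", "down")),
            all(fold >= 1),
            all(genotype_effect %in% c("none", "dki_lost", "dki_gained")))
  out <- data.frame(gene_id = gene_id, transition = transition,
                    direction = direction, fold = fold,
                    genotype_effect = genotype_effect,
                    stringsAsFactors = FALSE)
  structure(out, class = c("de_registry", "data.frame"))
}

#' Default planted-DE registry for a synthetic gene table
#'
#' Marks every tetramer-site host gene as a tetramer-dependent
#' (`dki_lost`) up-gene at the Q2 to Q3 transition, and plants additional
#' genotype-independent transition-DE genes among the remaining genes.
#'
#' @param genes a [synthetic_gene_models()] table.
#' @param truth truth list or `sites` data.frame (to identify tetramer
#'   hosts).
#' @param n_q1q2,n_q2q3,n_both numbers of genotype-independent DE genes
#'   per transition class.
#' @param fold planted fold change.
#' @param seed RNG seed.
#' @return a [de_registry()].
#' @export
synthetic_de_registry <- function(genes, truth, n_q1q2 = 10, n_q2q3 = 10,
                                  n_both = 4, fold = 4, seed) {
  sites <- if (is.data.frame(truth)) truth else truth$sites
  tet_sites <- sites$site_id[sites$kind == "tetramer"]
  hosts <- genes$gene_id[genes$host_site %in% tet_sites]
  with_seed(seed, {
    free <- setdiff(genes$gene_id, hosts)
    n_extra <- n_q1q2 + n_q2q3 + n_both
    if (n_extra > length(free))
      stop("not enough genes for the requested DE plants", call. = FALSE)
    extra <- sample(free, n_extra)
    de_registry(
      gene_id = c(hosts, extra),
      transition = c(rep("Q2Q3", length(hosts)),
                     rep(c("Q1Q2", "Q2Q3", "both"), c(n_q1q2, n_q2q3, n_both))),
      direction = c(rep("up", length(hosts)),
                    sample(c("up", "down"), n_extra, replace = TRUE)),
      fold = rep(fold, length(hosts) + n_extra),
      genotype_effect = c(rep("dki_lost", length(hosts)),
                          rep("none", n_extra)))
  })
}

#' Simulate stage-structured RNA-seq count tables
#'
#' Negative-binomial exon counts for the maturation populations Q1, Q2, Q3
#' of one genotype. Gene means follow the per-gene baseline RPKM; a
#' planted transition-DE gene changes its mean by `fold` at its transition
#' (and keeps the new level in later populations). Whether the change is
#' applied depends on the registry's `genotype_effect` and the simulated
#' genotype. Nominal mapped-library sizes are recorded and used as the
#' RPKM denominator.
#'
#' @param genes a gene table with `exon_bp` and `baseline_rpkm` columns.
#' @param registry a [de_registry()]; every registry gene must exist in
#'   `genes`.
#' @param genotype `"WT"` or `"DKI"`.
#' @param n_populations fixed at 3 (Q1, Q2, Q3).
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); must be > 0.
#' @param library_size nominal mapped reads per library.
#' @param n_reps replicate libraries per population.
#' @param seed RNG seed.
#' @return list of class `count_table`: `counts` (gene x condition
#'   matrix), `conditions` metadata, `library_sizes`, `exon_bp`.
#' @export
simulate_counts <- function(genes, registry, genotype = c("WT", "DKI"),
                            n_populations = 3, dispersion = 0.01,
                            library_size = 5e6, n_reps = 1, seed) {
  genotype <- match.arg(genotype)
  if (n_populations != 3)
    stop("exactly three maturation populations (Q1, Q2, Q3) are supported",
         call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (!all(registry$gene_id %in% genes$gene_id))
    stop("registry genes missing from gene models: ",
         paste(setdiff(registry$gene_id, genes$gene_id), collapse = ", "),
         call. = FALSE)
  pops <- c("Q1", "Q2", "Q3")
  base <- if ("baseline_rpkm" %in% names(genes)) genes$baseline_rpkm else
    rep(20, nrow(genes))
  mu_rpkm <- matrix(base, nrow(genes), 3,
                    dimnames = list(genes$gene_id, pops))
  for (i in seq_len(nrow(registry))) {
    apply_change <- switch(registry$genotype_effect[i],
                           none = TRUE,
                           dki_lost = genotype == "WT",
                           dki_gained = genotype == "DKI")
    if (!apply_change) next
    f <- if (registry$direction[i] == "up") registry$fold[i] else
      1 / registry$fold[i]
    g <- registry$gene_id[i]
    mu_rpkm[g, ] <- mu_rpkm[g, ] * switch(registry$transition[i],
                                          Q1Q2 = c(1, f, f),
                                          Q2Q3 = c(1, 1, f),
                                          both = c(1, f, f * f))
  }
  mu_counts <- mu_rpkm * genes$exon_bp / 1e3 * library_size / 1e6
  with_seed(seed, {
    cols <- list()
    meta <- list()
    for (p in pops) for (r in seq_len(n_reps)) {
      nm <- if (n_reps == 1) paste(genotype, p, sep = ".") else
        sprintf("%s.%s.rep%d", genotype, p, r)
      cols[[nm]] <- rnbinom(nrow(genes), mu = mu_counts[, p],
                            size = 1 / dispersion)
      meta[[nm]] <- data.frame(condition = nm, genotype = genotype,
                               population = p, treatment = "none",
                               stringsAsFactors = FALSE)
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- genes$gene_id
    structure(list(counts = counts,
                   conditions = do.call(rbind, meta),
                   library_sizes = setNames(rep(library_size, ncol(counts)),
                                            colnames(counts)),
                   exon_bp = setNames(genes$exon_bp, genes$gene_id)),
              class = "count_table")
  })
}

#' Combine genotype count tables into an RPKM matrix
#'
#' @param ... `count_table` objects (e.g. one per genotype) over the same
#'   genes.
#' @return an [rpkm()] `expr_matrix`.
#' @export
combine_counts <- function(...) {
  tabs <- list(...)
  counts <- do.call(cbind, lapply(tabs, `[[`, "counts"))
  rpkm(counts,
       exon_bp = tabs[[1L]]$exon_bp,
       library_sizes = unlist(lapply(tabs, `[[`, "library_sizes")),
       conditions = do.call(rbind, lapply(tabs, `[[`, "conditions")))
}
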