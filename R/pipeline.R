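#' Run the tetramer-site discovery workflow end to end
#'
#' Chains the pipeline's six stages on a synthetic study: (1) genome with
#' planted sites, (2) WT and DKI treatment/control libraries, (3) Poisson
#' window peak calling per genotype, (4) GAS scanning with tandem-pair
#' spacing restricted to WT peaks, (5) WT-vs-DKI contrast plus
#' shared/specific accounting, (6) gene annotation of tetramer-specific
#' sites. All intermediate artifacts are written to `out_dir` along with a
#' machine-readable run manifest (parameters, stages, file checksums);
#' a rerun with the same configuration is byte-identical.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @param caller a [caller_config()]; by default the package defaults with
#'   `effective_genome_size` set to the synthetic genome length.
#' @param gas a [gas_model()].
#' @param max_spacer tandem-pair spacer cutoff in bases.
#' @param reduction_fold,upstream contrast and annotation thresholds.
#' @param gene_length,n_background_genes passed to
#'   [synthetic_gene_models()].
#' @return (invisibly) a list with genome, truth, peaks, coverages,
#'   contrast table, venn counts, spacing distribution, gene models,
#'   tetramer gene list, and the manifest.
#' @export
run_discovery <- function(cfg, out_dir, caller = NULL, gas = gas_model(),
                          max_spacer = 30, reduction_fold = 2,
                          upstream = 5000, gene_length = 3000,
                          n_background_genes = 30) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(caller))
    caller <- caller_config(effective_genome_size = cfg$genome_length)
  stages <- character(0)
  log_stage <- function(s) {
    stages <<- c(stages, s)
    message("[tetrasite] stage: ", s)
  }

  log_stage("simulate_genome")
  gg <- generate_genome(cfg)
  lens <- chrom_lengths(gg$genome)
  Biostrings::writeXStringSet(gg$genome, file.path(out_dir, "genome.fa"))
  write_truth_sites(gg$truth$sites, file.path(out_dir, "truth_sites.tsv"))

  log_stage("simulate_chip")
  libs <- list(WT = simulate_chip(gg$genome, gg$truth, "WT", cfg),
               DKI = simulate_chip(gg$genome, gg$truth, "DKI", cfg))
  for (g in names(libs)) {
    write_bed(libs[[g]]$treatment,
              file.path(out_dir, paste0("reads_", g, "_treatment.bed")))
    write_bed(libs[[g]]$control,
              file.path(out_dir, paste0("reads_", g, "_control.bed")))
  }

  log_stage("call_peaks")
  cov <- lapply(libs, function(l) list(
    treatment = windowed_coverage(l$treatment, lens, caller$window,
                                  fragment_length = cfg$fragment_length),
    control = windowed_coverage(l$control, lens, caller$window,
                                fragment_length = cfg$fragment_length)))
  peaks <- lapply(cov, function(cc)
    call_peaks(cc$treatment, cc$control, caller))
  for (g in names(peaks))
    write_peaks(peaks[[g]],
                bed = file.path(out_dir, paste0("peaks_", g, ".bed")),
                tsv = file.path(out_dir, paste0("peaks_", g, ".tsv")))

  log_stage("motif_scan")
  hits <- scan_gas(gg$genome, gas)
  pairs <- find_tandem(hits, max_spacer)
  spacing <- spacing_distribution(pairs, restrict_to = peaks$WT)
  write_tsv(as.data.frame(hits), file.path(out_dir, "gas_hits.tsv"))
  write_tsv(as.data.frame(pairs), file.path(out_dir, "tandem_pairs.tsv"))
  write_tsv(spacing$histogram, file.path(out_dir, "spacing_histogram.tsv"))

  log_stage("genotype_contrast")
  contrast <- classify_tetramer_sites(peaks$WT, peaks$DKI,
                                      cov$WT$treatment, cov$DKI$treatment,
                                      reduction_fold = reduction_fold)
  venn <- venn_accounting(peaks$WT, peaks$DKI)
  write_tsv(as.data.frame(contrast), file.path(out_dir, "site_contrast.tsv"))
  jsonlite::write_json(unclass(venn), file.path(out_dir, "venn_counts.json"),
                       auto_unbox = TRUE, digits = NA)

  log_stage("gene_annotation")
  genes <- synthetic_gene_models(gg$genome, gg$truth,
                                 gene_length = gene_length,
                                 n_background_genes = n_background_genes,
                                 seed = cfg$seed + 10L)
  tet_genes <- tetramer_genes(contrast, genes, upstream, lens)
  write_tsv(as.data.frame(genes), file.path(out_dir, "gene_models.tsv"))
  writeLines(tet_genes, file.path(out_dir, "tetramer_genes.txt"))

  manifest <- write_manifest(
    out_dir, workflow = "discovery", stages = stages,
    parameters = list(synthetic = unclass(cfg), caller = unclass(caller),
                      gas_consensus = gas$consensus, max_spacer = max_spacer,
                      reduction_fold = reduction_fold, upstream = upstream,
                      gene_length = gene_length,
                      n_background_genes = n_background_genes))

  invisible(list(genome = gg$genome, truth = gg$truth, cfg = cfg,
                 coverage = cov, peaks = peaks, hits = hits, pairs = pairs,
                 spacing = spacing, contrast = contrast, venn = venn,
                 genes = genes, tetramer_genes = tet_genes,
                 manifest = manifest))
}

#' Run the expression-integration workflow
#'
#' Simulates stage-structured count tables for both genotypes over the
#' synthetic gene models, computes RPKM, reports differential expression
#' across the Q1 to Q2 and Q2 to Q3 maturation transitions, and nominates
#' direct tetramer targets among `tet_genes` (genes whose binding is
#' tetramer-specific) by the WT-over-DKI expression fold.
#'
#' @param cfg a [synthetic_config()] (drives gene/DE simulation seeds).
#' @param out_dir output directory.
#' @param tet_genes character vector of tetramer-bound genes, e.g. from
#'   [run_discovery()]; if NULL, the genes hosting planted tetramer sites
#'   are used (the planted truth).
#' @param fc_min,rpkm_min DE thresholds.
#' @param dispersion,library_size,n_reps passed to [simulate_counts()].
#' @param gene_length,n_background_genes passed to
#'   [synthetic_gene_models()].
#' @return (invisibly) list with gene models, DE registry, expression
#'   matrix, transition report, target list and manifest.
#' @export
run_integration <- function(cfg, out_dir, tet_genes = NULL, fc_min = 1.5,
                            rpkm_min = 5, dispersion = 0.01,
                            library_size = 5e6, n_reps = 1,
                            gene_length = 3000, n_background_genes = 30) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  log_stage <- function(s) {
    stages <<- c(stages, s)
    message("[tetrasite] stage: ", s)
  }

  log_stage("simulate_genes")
  gg <- generate_genome(cfg)
  genes <- synthetic_gene_models(gg$genome, gg$truth,
                                 gene_length = gene_length,
                                 n_background_genes = n_background_genes,
                                 seed = cfg$seed + 10L)
  registry <- synthetic_de_registry(genes, gg$truth, seed = cfg$seed + 11L)
  write_tsv(as.data.frame(registry), file.path(out_dir, "truth_de_genes.tsv"))

  log_stage("simulate_counts")
  wt <- simulate_counts(genes, registry, "WT", dispersion = dispersion,
                        library_size = library_size, n_reps = n_reps,
                        seed = cfg$seed + 12L)
  dki <- simulate_counts(genes, registry, "DKI", dispersion = dispersion,
                         library_size = library_size, n_reps = n_reps,
                         seed = cfg$seed + 13L)
  write_tsv(data.frame(gene_id = rownames(wt$counts), wt$counts, dki$counts),
            file.path(out_dir, "counts.tsv"))

  log_stage("rpkm")
  expr <- combine_counts(wt, dki)
  write_tsv(data.frame(gene_id = rownames(expr$rpkm), round(expr$rpkm, 4)),
            file.path(out_dir, "rpkm.tsv"))

  log_stage("transition_de")
  report <- transition_report(expr, "WT", rpkm_min = rpkm_min,
                              fc_min = fc_min)

  log_stage("tetramer_targets")
  if (is.null(tet_genes)) {
    tet_sites <- gg$truth$sites$site_id[gg$truth$sites$kind == "tetramer"]
    tet_genes <- genes$gene_id[genes$host_site %in% tet_sites]
  }
  targets <- tetramer_targets(tet_genes, expr, fc_min = fc_min)
  writeLines(targets, file.path(out_dir, "tetramer_targets.txt"))
  write_tsv(data.frame(set = c("q1q2", "q2q3", "both", "union"),
                       n = c(length(report$q1q2_set), length(report$q2q3_set),
                             length(report$both_set), report$union_count)),
            file.path(out_dir, "transition_sets.tsv"))

  manifest <- write_manifest(
    out_dir, workflow = "integration", stages = stages,
    parameters = list(synthetic = unclass(cfg), fc_min = fc_min,
                      rpkm_min = rpkm_min, dispersion = dispersion,
                      library_size = library_size, n_reps = n_reps))

  invisible(list(genes = genes, registry = registry, expr = expr,
                 report = report, tetramer_genes = tet_genes,
                 targets = targets, manifest = manifest))
}

# machine-readable record from which a run can be reproduced: package
# version, parameters, stage order and md5 of every artifact
write_manifest <- function(out_dir, workflow, stages, parameters) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    tool = "tetrasite",
    version = as.character(packageVersion("tetrasite")),
    workflow = workflow,
    stages = stages,
    parameters = parameters,
    outputs = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
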