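#' Run the full integrative pipeline on a synthetic dataset
#'
#' Executes every stage in fixed order on data generated from `config`:
#'
#' 1. simulate counts, annotation, per-mark coverage/peaks/reads, and
#'    target predictions;
#' 2. gene differential expression (FPKM expressed filter at >= `min_fpkm`,
#'    median-of-ratios normalisation, NB test, BH FDR < `gene_fdr`);
#' 3. miRNA differential expression (`mirna_fdr`, |log2FC| >
#'    `mirna_min_lfc`);
#' 4. quintile assignment of DE genes on condition-mean FPKM and the 5x5
#'    rank-transition matrix;
#' 5. miRNA-target anticorrelation filtering and FC1/FC2 ranking;
#' 6. per mark: peak union into candidate regions, deduplicated read
#'    counting, differential region calling (FDR < `region_fdr`, |log2FC| >
#'    `region_min_lfc`), gene assignment;
#' 7. per mark: RPKM metagene (TSS/TTS) and gene-element profiles plus the
#'    peak-element distribution;
#' 8. per mark: expression/mark sign-concordance integration, then the
#'    cross-mark gene overlap.
#'
#' All outputs are written as TSV/BED under `outdir`, and a JSON manifest
#' records the configuration, per-stage row counts, file checksums and the
#' package version.  Rerunning with an identical config reproduces identical
#' data files.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param gene_fdr,mirna_fdr,mirna_min_lfc,region_fdr,region_min_lfc,min_fpkm
#'   stage thresholds (defaults: 0.05; 0.05 and 1; 0.01 and 2; 3).
#' @param marks epigenetic marks to simulate and integrate.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         gene_fdr = 0.05,
                         mirna_fdr = 0.05, mirna_min_lfc = 1.0,
                         region_fdr = 0.01, region_min_lfc = 2.0,
                         min_fpkm = 3.0,
                         marks = c("medip", "h3k27me3")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage_rows <- list()
  t0 <- Sys.time()

  # -- stage 1: simulate ----------------------------------------------------
  sim <- simulate_counts(config)
  annotation <- simulate_annotation(config)
  truth <- sim$truth
  mark_data <- list()
  for (mk in marks) {
    md <- simulate_coverage_and_peaks(config, annotation, truth, mark = mk)
    truth <- md$truth
    mark_data[[mk]] <- md
  }
  tp <- simulate_target_predictions(config, truth)
  truth <- tp$truth
  write_counts(sim$genes, file.path(outdir, "gene_counts.tsv"))
  write_counts(sim$mirnas, file.path(outdir, "mirna_counts.tsv"))
  write_annotation_bed12(annotation, file.path(outdir, "annotation.bed"))
  write_tsv(tp$predictions, file.path(outdir, "target_predictions.tsv"))
  write_tsv(truth$de_genes, file.path(outdir, "truth_de_genes.tsv"))
  write_tsv(truth$de_mirnas, file.path(outdir, "truth_de_mirnas.tsv"))
  write_tsv(truth$anticorrelated, file.path(outdir, "truth_anticorrelated.tsv"))
  if (!is.null(truth$shifted_regions)) {
    write_tsv(truth$shifted_regions,
              file.path(outdir, "truth_shifted_regions.tsv"))
  }
  write_tsv(truth$true_targets, file.path(outdir, "truth_targets.tsv"))
  stage_rows$simulate <- c(genes = nrow(sim$genes$counts),
                           mirnas = nrow(sim$mirnas$counts),
                           predictions = nrow(tp$predictions))

  # -- stage 2: gene DE -----------------------------------------------------
  lengths <- setNames(annotation$end - annotation$start, annotation$gene_id)
  fpkm <- fpkm_table(sim$genes, lengths)
  expressed <- expressed_filter(fpkm, min_fpkm = min_fpkm)
  gcounts <- count_matrix(
    sim$genes$counts[expressed$gene_id, , drop = FALSE],
    sim$genes$design$condition, sim$genes$design$replicate)
  gene_res <- nb_test(gcounts)
  de_genes <- call_de_genes(gene_res, fdr = gene_fdr)
  write_tsv(gene_res, file.path(outdir, "de_genes_all.tsv"))
  write_tsv(de_genes, file.path(outdir, "de_genes_called.tsv"))
  stage_rows$de_genes <- c(expressed = nrow(expressed), called = nrow(de_genes))

  # -- stage 3: miRNA DE ----------------------------------------------------
  mirna_res <- nb_test(sim$mirnas)
  de_mirnas <- call_de_mirnas(mirna_res, fdr = mirna_fdr,
                              min_abs_log2fc = mirna_min_lfc)
  write_tsv(mirna_res, file.path(outdir, "de_mirnas_all.tsv"))
  write_tsv(de_mirnas, file.path(outdir, "de_mirnas_called.tsv"))
  stage_rows$de_mirnas <- c(tested = nrow(mirna_res), called = nrow(de_mirnas))

  # -- stage 4: quintiles on DE genes ---------------------------------------
  quint <- NULL
  if (nrow(de_genes) >= 5) {
    fx <- fpkm[match(de_genes$feature_id, fpkm$gene_id), ]
    qc <- assign_quintiles(data.frame(gene_id = fx$gene_id,
                                      abundance = fx$mean_control))
    qt <- assign_quintiles(data.frame(gene_id = fx$gene_id,
                                      abundance = fx$mean_treated))
    quint <- rank_transitions(qc, qt)
    write_tsv(quint, file.path(outdir, "quintile_transitions.tsv"))
    tm <- transition_matrix(qc, qt)
    write_tsv(data.frame(rank_control = rownames(tm), tm, check.names = FALSE),
              file.path(outdir, "quintile_matrix.tsv"))
  }
  stage_rows$quintile <- c(genes = if (is.null(quint)) 0L else nrow(quint))

  # -- stage 5: miRNA-target integration ------------------------------------
  pairs <- filter_anticorrelated(tp$predictions, de_mirnas, de_genes)
  write_tsv(rank_pairs(pairs), file.path(outdir, "mirna_target_pairs.tsv"))
  write_tsv(targets_per_mirna(pairs),
            file.path(outdir, "mirna_target_counts.tsv"))
  stage_rows$mirna_integration <- c(pairs = nrow(pairs))

  # -- stages 6-8 per mark --------------------------------------------------
  mark_records <- list()
  for (mk in marks) {
    md <- mark_data[[mk]]
    cdmr <- merge_peaks(md$peaks)
    calls <- data.frame()
    gene_marks <- summarize_gene_marks(
      data.frame(gene_id = character(), log2fc = numeric(),
                 mark = character()))
    if (nrow(cdmr) > 0) {
      rc <- count_reads_in_regions(cdmr, md$reads,
                                   md$coverage$design$condition)
      calls <- call_dmrs(rc, fdr = region_fdr,
                         min_abs_log2fc = region_min_lfc, mark = mk)
      calls <- assign_regions_to_genes(calls, annotation)
      gene_marks <- summarize_gene_marks(calls)
    }
    write_bed(cdmr, file.path(outdir, paste0(mk, "_cdmr.bed")))
    write_tsv(calls, file.path(outdir, paste0(mk, "_dmr_calls.tsv")))
    write_tsv(gene_marks, file.path(outdir, paste0(mk, "_gene_marks.tsv")))

    cov <- rpkm_bins(md$coverage)
    write_tsv(metagene_profile(cov, annotation, "tss"),
              file.path(outdir, paste0(mk, "_profile_tss.tsv")))
    write_tsv(metagene_profile(cov, annotation, "tts"),
              file.path(outdir, paste0(mk, "_profile_tts.tsv")))
    write_tsv(element_profile(cov, annotation),
              file.path(outdir, paste0(mk, "_profile_elements.tsv")))
    write_tsv(peak_element_distribution(md$peaks, annotation,
                                        md$coverage$design),
              file.path(outdir, paste0(mk, "_peak_elements.tsv")))

    records <- join_expression_mark(de_genes, gene_marks)
    write_tsv(records, file.path(outdir, paste0(mk, "_integration.tsv")))
    write_tsv(summarize_integration(records),
              file.path(outdir, paste0(mk, "_integration_summary.tsv")))
    mark_records[[mk]] <- records
    stage_rows[[paste0("region_", mk)]] <-
      c(cdmr = nrow(cdmr), calls = nrow(calls), joined = nrow(records),
        negative = sum(records$correlation == "negative", na.rm = TRUE))
  }

  overlap <- if (length(marks) >= 2) {
    cross_mark_overlap(mark_records[[marks[1]]], mark_records[[marks[2]]])
  } else character(0)
  write_tsv(data.frame(gene_id = overlap),
            file.path(outdir, "cross_mark_overlap.tsv"))
  stage_rows$overlap <- c(genes = length(overlap))

  # -- manifest -------------------------------------------------------------
  files <- sort(list.files(outdir, pattern = "\\.(tsv|bed)$"))
  manifest <- list(
    package_version = as.character(packageVersion("tgfomics")),
    config = unclass(config),
    thresholds = list(gene_fdr = gene_fdr, mirna_fdr = mirna_fdr,
                      mirna_min_lfc = mirna_min_lfc, region_fdr = region_fdr,
                      region_min_lfc = region_min_lfc, min_fpkm = min_fpkm),
    stages = stage_rows,
    checksums = as.list(tools::md5sum(file.path(outdir, files))),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(truth = truth, annotation = annotation,
                 gene_results = gene_res, de_genes = de_genes,
                 mirna_results = mirna_res, de_mirnas = de_mirnas,
                 quintiles = quint, pairs = pairs,
                 mark_records = mark_records, overlap = overlap,
                 manifest = manifest))
}
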