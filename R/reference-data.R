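#' Bundled reference tables
#'
#' Small worked-example tables transcribed from a published integrative study
#' of TGF-beta1-treated mouse mesangial cells, shipped under `extdata`:
#'
#' * `rank_transitions` --- DE genes with extreme quintile rank changes
#'   between control and treated samples.
#' * `de_mirnas` --- differentially expressed miRNAs with printed linear fold
#'   change and |log2FC|.
#' * `mirna_target_counts` --- the enriched DE-miRNAs and their numbers of
#'   anticorrelated target DE-genes.
#' * `top_pairs` --- the top-10 miRNA-target pairs ranked by FC1/FC2
#'   relationship strength (all negative).
#' * `medip_integration` --- gene expression log2FC paired with DNA
#'   methylation log2FC for the 32 methylated DE-genes.
#' * `h3k27me3_integration` --- the 15 DE-genes with differential H3K27me3.
#'
#' @param name one of the table names above.
#' @return a data.frame.
#' @examples
#' summarize_integration(
#'   transform(reference_table("medip_integration"),
#'             correlation = classify_correlation(expr_log2fc,
#'                                                mark_log2fc)$correlation))
#' @export
reference_table <- function(name = c("rank_transitions", "de_mirnas",
                                     "mirna_target_counts", "top_pairs",
                                     "medip_integration",
                                     "h3k27me3_integration")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("reference_", name, ".tsv"),
                      package = "tgfomics", mustWork = TRUE)
  read_tsv(path)
}

#' Integration records from a reference fold-change table
#'
#' Convenience wrapper turning a reference integration table (gene id plus
#' expression and mark log2 fold changes) into classified records compatible
#' with [summarize_integration()] and [cross_mark_overlap()].
#'
#' @param name `"medip_integration"` or `"h3k27me3_integration"`.
#' @param mark mark label to attach.
#' @return data.frame as returned by [join_expression_mark()].
#' @export
reference_integration_records <- function(name, mark = name) {
  tab <- reference_table(name)
  cls <- classify_correlation(tab$expr_log2fc, tab$mark_log2fc)
  data.frame(gene_id = tab$gene_id,
             expr_log2fc = tab$expr_log2fc,
             mark_log2fc = tab$mark_log2fc,
             mark = mark,
             correlation = cls$correlation,
             subclass = cls$subclass,
             stringsAsFactors = FALSE)
}
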