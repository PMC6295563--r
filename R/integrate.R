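#' Classify the expression/mark correlation of a gene
#'
#' A gene with nonzero expression and mark log2 fold changes is negatively
#' correlated iff the two signs are opposite.  The subclass names the sign
#' pair: `down+hyper` (expression down, mark up), `up+hypo`, `down+hypo`,
#' `up+hyper`.
#'
#' @param expr_log2fc,mark_log2fc numeric vectors (recycled to equal length).
#' @return data.frame `correlation` (`"positive"`/`"negative"`) and
#'   `subclass`; zero fold changes raise an error (they cannot be
#'   sign-classified).
#' @examples
#' classify_correlation(-0.633, 1.48896494)  # negative, down+hyper
#' classify_correlation(3.703, -1.38683764)  # negative, up+hypo
#' @export
classify_correlation <- function(expr_log2fc, mark_log2fc) {
  n <- max(length(expr_log2fc), length(mark_log2fc))
  e <- rep_len(expr_log2fc, n)
  m <- rep_len(mark_log2fc, n)
  if (any(e == 0 | m == 0)) {
    stop("unclassifiable: zero fold change has no sign")
  }
  data.frame(
    correlation = ifelse(sign(e) * sign(m) < 0, "negative", "positive"),
    subclass = paste0(ifelse(e > 0, "up", "down"), "+",
                      ifelse(m > 0, "hyper", "hypo")),
    stringsAsFactors = FALSE)
}

#' Join gene expression changes with gene-level mark changes
#'
#' Inner join on gene id between called DE genes and per-gene mark summaries
#' (one record per gene on each side; duplicates are an error).  Records
#' where either fold change is exactly zero are kept but flagged
#' unclassifiable (`correlation = NA`) and excluded from [
#' summarize_integration()].
#'
#' @param de_genes called DE subset ([call_de_genes()]); gene ids in
#'   `feature_id` (or `gene_id`).
#' @param mark_genes per-gene mark table ([summarize_gene_marks()]).
#' @return data.frame `gene_id`, `expr_log2fc`, `mark_log2fc`, `mark`,
#'   `correlation`, `subclass`, sorted by gene id.
#' @export
join_expression_mark <- function(de_genes, mark_genes) {
  gid <- if ("gene_id" %in% names(de_genes)) de_genes$gene_id else
    de_genes$feature_id
  if (anyDuplicated(gid) || anyDuplicated(mark_genes$gene_id)) {
    stop("input error: duplicate gene ids within one input")
  }
  common <- intersect(gid, mark_genes$gene_id)
  if (length(common) == 0) {
    return(data.frame(gene_id = character(), expr_log2fc = numeric(),
                      mark_log2fc = numeric(), mark = character(),
                      correlation = character(), subclass = character(),
                      stringsAsFactors = FALSE))
  }
  common <- sort(common)
  e <- de_genes$log2fc[match(common, gid)]
  m <- mark_genes$mark_log2fc[match(common, mark_genes$gene_id)]
  zero <- e == 0 | m == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with a zero fold change are unclassifiable")
  }
  cls <- data.frame(correlation = rep(NA_character_, length(common)),
                    subclass = rep(NA_character_, length(common)),
                    stringsAsFactors = FALSE)
  if (any(!zero)) cls[!zero, ] <- classify_correlation(e[!zero], m[!zero])
  data.frame(gene_id = common,
             expr_log2fc = e,
             mark_log2fc = m,
             mark = mark_genes$mark[match(common, mark_genes$gene_id)],
             correlation = cls$correlation,
             subclass = cls$subclass,
             stringsAsFactors = FALSE)
}

#' Summarise an expression/mark integration
#'
#' Exact counts of joined, positively and negatively correlated genes and of
#' each sign subclass; unclassifiable (zero-FC) records are counted
#' separately, so `positive + negative + unclassifiable = joined`.
#'
#' @param records data.frame from [join_expression_mark()].
#' @return one-row data.frame with counts `joined`, `positive`, `negative`,
#'   `down_hyper`, `up_hypo`, `down_hypo`, `up_hyper`, `unclassifiable`.
#' @export
summarize_integration <- function(records) {
  cls <- records$correlation
  sub <- records$subclass
  data.frame(joined = nrow(records),
             positive = sum(cls == "positive", na.rm = TRUE),
             negative = sum(cls == "negative", na.rm = TRUE),
             down_hyper = sum(sub == "down+hyper", na.rm = TRUE),
             up_hypo = sum(sub == "up+hypo", na.rm = TRUE),
             down_hypo = sum(sub == "down+hypo", na.rm = TRUE),
             up_hyper = sum(sub == "up+hyper", na.rm = TRUE),
             unclassifiable = sum(is.na(cls)))
}

#' Genes shared between two mark integrations
#'
#' Set intersection of the gene ids of two integration record sets, e.g.
#' DNA methylation versus H3K27me3.
#'
#' @param records_a,records_b data.frames carrying a `gene_id` column.
#' @return sorted character vector of shared gene ids (possibly empty).
#' @export
cross_mark_overlap <- function(records_a, records_b) {
  sort(intersect(unique(records_a$gene_id), unique(records_b$gene_id)))
}
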