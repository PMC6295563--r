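#' Relationship strength of a miRNA-target pair
#'
#' The ratio FC1/FC2 of the target gene's log2 fold change (FC1) to the
#' miRNA's log2 fold change (FC2).  For anticorrelated pairs (opposite signs)
#' the ratio is negative, and more negative values mark stronger
#' repression-consistent relationships.
#'
#' @param fc1 gene log2 fold change (treated vs control).
#' @param fc2 miRNA log2 fold change; must be nonzero.
#' @return `fc1 / fc2`, vectorised.
#' @export
relationship_strength <- function(fc1, fc2) {
  if (any(fc2 == 0)) stop("undefined relationship: miRNA fold change is zero")
  fc1 / fc2
}

# Dedup predicted (miRNA, gene) rows, keeping the first site class seen.
dedup_predictions <- function(predictions) {
  req <- c("mirna_id", "gene_id")
  if (!all(req %in% names(predictions))) {
    stop("predictions need mirna_id and gene_id columns")
  }
  if (!"site_class" %in% names(predictions)) predictions$site_class <- NA
  predictions[!duplicated(predictions[, req]), , drop = FALSE]
}

#' Retain anticorrelated predicted miRNA-target pairs
#'
#' Intersects a target-prediction table with the called DE-miRNAs and
#' DE-genes, keeping only the pairs whose expression changes have opposite
#' signs (miRNA up with gene down, or miRNA down with gene up).  Each
#' retained pair is scored with [relationship_strength()], so every retained
#' relationship is negative.  Called features with a fold change of exactly
#' zero cannot be sign-classified and are dropped with a warning.
#'
#' @param predictions data.frame with `mirna_id`, `gene_id` and optionally
#'   `site_class`; duplicate (miRNA, gene) rows are collapsed.
#' @param de_mirnas called subset from [call_de_mirnas()] (carries `log2fc`).
#' @param de_genes called subset from [call_de_genes()].
#' @return data.frame `mirna_id`, `gene_id`, `fc1`, `fc2`, `relationship`,
#'   `site_class`, sorted by (miRNA id, gene id).
#' @export
filter_anticorrelated <- function(predictions, de_mirnas, de_genes) {
  pred <- dedup_predictions(predictions)
  fc2 <- setNames(de_mirnas$log2fc, de_mirnas$feature_id)
  fc1 <- setNames(de_genes$log2fc, de_genes$feature_id)
  keep <- pred$mirna_id %in% names(fc2) & pred$gene_id %in% names(fc1)
  pred <- pred[keep, , drop = FALSE]
  f1 <- as.numeric(fc1[pred$gene_id])
  f2 <- as.numeric(fc2[pred$mirna_id])
  zero <- f1 == 0 | f2 == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with a zero fold change excluded")
  }
  anti <- !zero & sign(f1) != sign(f2)
  out <- data.frame(mirna_id = pred$mirna_id[anti],
                    gene_id = pred$gene_id[anti],
                    fc1 = f1[anti],
                    fc2 = f2[anti],
                    relationship = f1[anti] / f2[anti],
                    site_class = pred$site_class[anti],
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank miRNA-target pairs by relationship strength
#'
#' Default ordering is ascending by the signed relationship, so the most
#' negative (strongest anticorrelated) pair comes first; ties are broken by
#' (miRNA id, gene id).  `by = "abs"` ranks by descending |relationship|
#' instead.
#'
#' @param pairs data.frame from [filter_anticorrelated()].
#' @param top_n how many pairs to return (default all).
#' @param by `"signed"` (default) or `"abs"`.
#' @return the first `top_n` rows of the sorted table.
#' @export
rank_pairs <- function(pairs, top_n = Inf, by = c("signed", "abs")) {
  by <- match.arg(by)
  key <- if (by == "signed") pairs$relationship else -abs(pairs$relationship)
  ord <- order(key, pairs$mirna_id, pairs$gene_id)
  out <- pairs[ord, , drop = FALSE]
  rownames(out) <- NULL
  head(out, n = if (is.finite(top_n)) top_n else nrow(out))
}

#' Number of retained target genes per miRNA
#'
#' @param pairs data.frame from [filter_anticorrelated()].
#' @return data.frame `mirna_id`, `n_targets`, sorted by miRNA id; the counts
#'   sum to the number of retained pairs.
#' @export
targets_per_mirna <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(data.frame(mirna_id = character(), n_targets = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(pairs$mirna_id)
  data.frame(mirna_id = names(tab), n_targets = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Intersection of two target-prediction tables
#'
#' Keeps the (miRNA, gene) pairs predicted by both sources, mirroring the
#' practice of retaining targets supported by two independent predictors.
#' Site classes are taken from the first table.
#'
#' @param a,b prediction data.frames (`mirna_id`, `gene_id`, `site_class`).
#' @return the subset of `a` whose (miRNA, gene) pairs also occur in `b`.
#' @export
intersect_predictions <- function(a, b) {
  a <- dedup_predictions(a)
  b <- dedup_predictions(b)
  key_a <- paste(a$mirna_id, a$gene_id, sep = "\r")
  key_b <- paste(b$mirna_id, b$gene_id, sep = "\r")
  out <- a[key_a %in% key_b, , drop = FALSE]
  rownames(out) <- NULL
  out
}
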