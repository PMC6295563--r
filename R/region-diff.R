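# Regions are data.frames (chrom, start, end), 0-based half-open (BED).

validate_regions <- function(regions) {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(regions))) stop("regions need chrom/start/end")
  if (nrow(regions) &&
      (any(regions$start < 0) || any(regions$start >= regions$end))) {
    stop("malformed interval: require 0 <= start < end")
  }
  regions
}

regions_to_granges <- function(regions) {
  validate_regions(regions)
  GenomicRanges::GRanges(
    seqnames = as.character(regions$chrom),
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end))
}

granges_to_regions <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Merge replicate peak sets into candidate regions
#'
#' Interval union across all input peak sets (replicates of both conditions),
#' yielding the candidate differentially methylated regions (CDMRs) that the
#' downstream count test evaluates.  Overlapping or abutting intervals are
#' fused; intervals separated by at least one uncovered base stay separate.
#' The union is idempotent, commutative and associative in its inputs.
#'
#' @param peaksets one region data.frame (`chrom`, `start`, `end`) or a list
#'   of them (one per sample).
#' @return region data.frame, sorted by (chrom, start), pairwise disjoint.
#' @examples
#' merge_peaks(list(data.frame(chrom = "c", start = 10, end = 100),
#'                  data.frame(chrom = "c", start = 50, end = 150)))
#' @export
merge_peaks <- function(peaksets) {
  if (is.data.frame(peaksets)) peaksets <- list(peaksets)
  if (length(peaksets) == 0) stop("need at least one peak set")
  all_regions <- do.call(rbind, lapply(peaksets, function(p) {
    validate_regions(p)[, c("chrom", "start", "end"), drop = FALSE]
  }))
  if (nrow(all_regions) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  granges_to_regions(GenomicRanges::reduce(regions_to_granges(all_regions)))
}

#' Count deduplicated reads per region
#'
#' Reads are represented by their 5' start positions.  Within each sample,
#' reads sharing a start position are counted once (sequencing-duplicate
#' rule); a read is then counted for a region iff its start lies in
#' `[start, end)`.  Regions must be disjoint (as produced by
#' [merge_peaks()]), so each read contributes to at most one region.
#'
#' @param regions region data.frame; auto-sorted, must be non-overlapping.
#' @param read_starts named list (one element per sample) of either integer
#'   position vectors (single-chromosome data; chromosome taken from the
#'   regions) or data.frames with `chrom` and `start`.
#' @param condition condition label per sample, same order as `read_starts`.
#' @return a [count_matrix()] with one row per region, named
#'   `chrom:start-end`.
#' @export
count_reads_in_regions <- function(regions, read_starts, condition) {
  validate_regions(regions)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  gr <- regions_to_granges(regions)
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1L)) {
    stop("regions overlap; merge them first")
  }
  single_chrom <- unique(as.character(regions$chrom))
  counts <- vapply(read_starts, function(rs) {
    if (is.data.frame(rs)) {
      rs <- rs[!duplicated(rs[, c("chrom", "start")]), , drop = FALSE]
      pts <- GenomicRanges::GRanges(as.character(rs$chrom),
                                    IRanges::IRanges(rs$start + 1L, width = 1L))
    } else {
      if (length(single_chrom) != 1L) {
        stop("bare position vectors need single-chromosome regions")
      }
      pos <- unique(as.integer(rs))
      pts <- GenomicRanges::GRanges(single_chrom,
                                    IRanges::IRanges(pos + 1L, width = 1L))
    }
    GenomicRanges::countOverlaps(gr, pts)
  }, integer(length(gr)))
  counts <- matrix(counts, nrow = length(gr))
  colnames(counts) <- names(read_starts)
  rownames(counts) <- sprintf("%s:%d-%d", regions$chrom,
                              as.integer(regions$start),
                              as.integer(regions$end))
  count_matrix(counts, condition)
}

#' Call differentially methylated / modified regions
#'
#' Runs the negative-binomial test ([nb_test()]) on a region count matrix and
#' calls a region when `padj < fdr` and `|log2fc| > min_abs_log2fc` (defaults
#' FDR 0.01 and |log2FC| > 2, both strict).  Direction is `"hyper"` when the
#' mark signal is higher in the treated condition, `"hypo"` otherwise.
#'
#' @param region_counts [count_matrix()] from [count_reads_in_regions()].
#' @param fdr,min_abs_log2fc call thresholds.
#' @param mark label attached to every call, e.g. `"DNA-methylation"` or
#'   `"H3K27me3"`.
#' @param size_factors optional per-sample factors; estimated when `NULL`.
#' @return data.frame of calls: `chrom`, `start`, `end`, `log2fc`, `pvalue`,
#'   `padj`, `direction`, `mark`.
#' @export
call_dmrs <- function(region_counts, fdr = 0.01, min_abs_log2fc = 2.0,
                      mark = "DNA-methylation", size_factors = NULL) {
  res <- nb_test(region_counts, size_factors = size_factors)
  keep <- !is.na(res$padj) & res$padj < fdr & abs(res$log2fc) > min_abs_log2fc
  res <- res[keep, , drop = FALSE]
  coords <- do.call(rbind, lapply(strsplit(res$feature_id, "[:-]"), function(x) {
    n <- length(x) # chrom may itself contain separators; take last two fields
    data.frame(chrom = paste(x[seq_len(n - 2)], collapse = ":"),
               start = as.integer(x[n - 1]), end = as.integer(x[n]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(coords)) {
    coords <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  }
  out <- cbind(coords,
               res[, c("log2fc", "pvalue", "padj"), drop = FALSE])
  out$direction <- ifelse(out$log2fc > 0, "hyper", "hypo")
  out$mark <- if (nrow(out)) mark else character(0)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign called regions to genes
#'
#' A region is a candidate for every gene whose 2-kb-extended span
#' `[min(TSS,TTS) - 2000, max(TSS,TTS) + 2000)` it overlaps; among candidates
#' the gene with the nearest TSS wins (distance zero when the TSS falls
#' inside the region), with lexicographic gene id as tie break.  Regions
#' overlapping no extended span get `gene_id = NA`.
#'
#' @param calls data.frame from [call_dmrs()].
#' @param annotation gene annotation from [simulate_annotation()] or
#'   [read_annotation_bed12()].
#' @param flank extension in bases on both sides of the gene span.
#' @return `calls` with a `gene_id` column appended.
#' @export
assign_regions_to_genes <- function(calls, annotation, flank = 2000L) {
  if (nrow(calls) == 0) {
    calls$gene_id <- character(0)
    return(calls)
  }
  ann <- annotation
  tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  span <- data.frame(chrom = ann$chrom,
                     start = pmax(ann$start - flank, 0),
                     end = ann$end + flank)
  gr_span <- regions_to_granges(span)
  gr_calls <- regions_to_granges(calls)
  hits <- GenomicRanges::findOverlaps(gr_calls, gr_span)
  gene_id <- rep(NA_character_, nrow(calls))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    # distance from region to the candidate gene's TSS (0 if TSS inside)
    d <- pmax(calls$start[qi] - tss[si], tss[si] - (calls$end[qi] - 1L), 0)
    ord <- order(qi, d, ann$gene_id[si])
    first <- !duplicated(qi[ord])
    gene_id[qi[ord][first]] <- ann$gene_id[si[ord][first]]
  }
  calls$gene_id <- gene_id
  calls
}

#' Per-gene mark summary from region calls
#'
#' Collapses gene-assigned region calls to one record per gene: the gene's
#' mark log2 fold change is that of its assigned region with the largest
#' |log2fc| (`summary = "max"`, the default) or the mean over its regions.
#'
#' @param assigned_calls output of [assign_regions_to_genes()].
#' @param summary `"max"` or `"mean"`.
#' @return data.frame `gene_id`, `mark_log2fc`, `direction`, `mark`, sorted
#'   by gene id.
#' @export
summarize_gene_marks <- function(assigned_calls, summary = c("max", "mean")) {
  summary <- match.arg(summary)
  x <- assigned_calls[!is.na(assigned_calls$gene_id), , drop = FALSE]
  if (nrow(x) == 0) {
    return(data.frame(gene_id = character(), mark_log2fc = numeric(),
                      direction = character(), mark = character(),
                      stringsAsFactors = FALSE))
  }
  lst <- split(x$log2fc, x$gene_id)
  lfc <- vapply(lst, function(v) {
    if (summary == "max") v[which.max(abs(v))] else mean(v)
  }, numeric(1))
  data.frame(gene_id = names(lfc),
             mark_log2fc = as.numeric(lfc),
             direction = ifelse(lfc > 0, "hyper", "hypo"),
             mark = x$mark[1],
             stringsAsFactors = FALSE)
}
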