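#' RPKM-normalise binned coverage
#'
#' Per-bin reads-per-kilobase-per-million:
#' `rpkm = count / (bin_size/1000) / (total_mapped_reads/1e6)`.
#'
#' @param coverage a `binned_coverage` object (see
#'   [simulate_coverage_and_peaks()] / [read_coverage()]).
#' @param total_reads per-sample total mapped reads; defaults to the column
#'   sums of the raw bin counts.
#' @return the coverage object with an `rpkm` matrix added.
#' @examples
#' # one bin of 100 bp with 10 reads out of 1e6 -> RPKM 100
#' @export
rpkm_bins <- function(coverage, total_reads = NULL) {
  stopifnot(inherits(coverage, "binned_coverage"))
  if (is.null(total_reads)) total_reads <- colSums(coverage$counts)
  if (any(total_reads <= 0)) stop("zero total reads; cannot RPKM-normalize")
  coverage$rpkm <- sweep(coverage$counts, 2, total_reads / 1e6, "/") /
    (coverage$bin_size / 1000)
  coverage
}

cov_rpkm <- function(coverage) {
  if (is.null(coverage$rpkm)) coverage <- rpkm_bins(coverage)
  coverage
}

condition_means <- function(mat, design) {
  out <- sapply(unique(design$condition), function(cnd) {
    rowMeans(mat[, design$condition == cnd, drop = FALSE])
  })
  colnames(out) <- paste0("mean_rpkm_", unique(design$condition))
  out
}

#' Metagene profile around TSS or TTS
#'
#' For each gene, takes the coverage bins spanning
#' `[anchor - flank, anchor + flank)` on the genome, orients them by strand
#' (minus-strand genes are reversed so upstream always points left), and
#' averages RPKM values across genes per offset.  Condition values are the
#' means of the replicate profiles.  Genes whose window leaves the
#' chromosome are skipped.
#'
#' @param coverage a `binned_coverage` (RPKM computed on demand).
#' @param annotation gene annotation data.frame.
#' @param anchor `"tss"` or `"tts"`.
#' @param flank half-window in bases; must be a multiple of the bin size.
#' @return data.frame: `offset` (bin start relative to anchor) plus one
#'   `mean_rpkm_<condition>` column per condition.
#' @export
metagene_profile <- function(coverage, annotation, anchor = c("tss", "tts"),
                             flank = 2000L) {
  anchor <- match.arg(anchor)
  coverage <- cov_rpkm(coverage)
  bs <- coverage$bin_size
  if (flank %% bs != 0) stop("flank must be a multiple of the bin size")
  nf <- flank %/% bs
  n_bins <- nrow(coverage$counts)
  ann <- gene_elements(annotation)
  a <- if (anchor == "tss") ann$tss else ann$tts
  abin <- a %/% bs
  ok <- abin - nf >= 0 & abin + nf <= n_bins
  if (!any(ok)) stop("no gene window fits inside the chromosome")
  if (any(!ok)) {
    message(sum(!ok), " gene(s) skipped: window outside chromosome")
  }
  idx <- t(vapply(which(ok), function(i) {
    bins <- (abin[i] - nf):(abin[i] + nf - 1) + 1L
    if (ann$strand[i] == "-") bins <- rev(bins)
    bins
  }, integer(2 * nf)))
  prof <- apply(coverage$rpkm, 2, function(v) colMeans(matrix(v[idx],
                                                              ncol = 2 * nf)))
  data.frame(offset = seq(-flank, flank - bs, by = bs),
             condition_means(prof, coverage$design),
             check.names = FALSE)
}

# Length-weighted mean RPKM over k equal slices of [start, end).
# W[s, b] = bases of slice s covered by bin b; values = W %*% rpkm / width.
slice_means <- function(start, end, k, bs, rpkm) {
  bounds <- start + (end - start) * (0:k) / k
  first_bin <- start %/% bs
  last_bin <- (end - 1) %/% bs
  bins <- first_bin:last_bin
  sl <- rep(seq_len(k), each = length(bins))
  bn <- rep(bins, times = k)
  lo <- pmax(bounds[sl], bn * bs)
  hi <- pmin(bounds[sl + 1], (bn + 1) * bs)
  w <- pmax(hi - lo, 0)
  W <- matrix(w, nrow = k, byrow = TRUE)
  (W %*% rpkm[bins + 1L, , drop = FALSE]) / ((end - start) / k)
}

#' Scaled gene-element profile (Up2k | CDS | Down2k)
#'
#' Averages RPKM coverage over the three gene elements on a common axis: the
#' 2-kb upstream and downstream flanks on fixed axes of `flank/bin_size`
#' positions, and the CDS rescaled to `n_cds_bins` positions (each position
#' is the length-weighted mean of the bin RPKMs it covers, i.e. the per-base
#' mean over that slice).  Minus-strand genes are reversed so transcription
#' runs left to right.  Genes with a CDS shorter than one bin or flanks
#' outside the chromosome are skipped.
#'
#' @inheritParams metagene_profile
#' @param n_cds_bins number of positions on the rescaled CDS axis.
#' @return data.frame `element` (`up2k`/`cds`/`down2k`), `position` (1-based
#'   within element), plus `mean_rpkm_<condition>` columns.
#' @export
element_profile <- function(coverage, annotation, flank = 2000L,
                            n_cds_bins = 40L) {
  coverage <- cov_rpkm(coverage)
  bs <- coverage$bin_size
  if (flank %% bs != 0) stop("flank must be a multiple of the bin size")
  nf <- flank %/% bs
  genome_len <- nrow(coverage$counts) * bs
  ann <- gene_elements(annotation, flank = flank)
  ok <- ann$up2k_start >= 0 & ann$up2k_end <= genome_len &
    ann$down2k_start >= 0 & ann$down2k_end <= genome_len &
    (ann$cds_end - ann$cds_start) >= bs
  if (!any(ok)) stop("no usable gene for the element profile")
  if (any(!ok)) message(sum(!ok), " gene(s) skipped in element profile")
  ann <- ann[ok, , drop = FALSE]
  n_samp <- ncol(coverage$rpkm)
  total <- matrix(0, nrow = 2L * nf + n_cds_bins, ncol = n_samp)
  for (i in seq_len(nrow(ann))) {
    up <- slice_means(ann$up2k_start[i], ann$up2k_end[i], nf, bs,
                      coverage$rpkm)
    cds <- slice_means(ann$cds_start[i], ann$cds_end[i], n_cds_bins, bs,
                       coverage$rpkm)
    dn <- slice_means(ann$down2k_start[i], ann$down2k_end[i], nf, bs,
                      coverage$rpkm)
    block <- if (ann$strand[i] == "+") {
      rbind(up, cds, dn)
    } else { # reflect: upstream element read right-to-left, order swapped
      rbind(up[rev(seq_len(nf)), , drop = FALSE],
            cds[rev(seq_len(n_cds_bins)), , drop = FALSE],
            dn[rev(seq_len(nf)), , drop = FALSE])
    }
    total <- total + block
  }
  prof <- total / nrow(ann)
  data.frame(element = rep(c("up2k", "cds", "down2k"),
                           c(nf, n_cds_bins, nf)),
             position = c(seq_len(nf), seq_len(n_cds_bins), seq_len(nf)),
             condition_means(prof, coverage$design),
             check.names = FALSE)
}

#' Distribution of peaks over gene elements
#'
#' Assigns each peak to exactly one element by the location of its midpoint,
#' with priority gene body ("cds") > up2k > down2k > intergenic when the
#' midpoint falls into overlapping element spans of different genes.  A
#' midpoint exactly at a plus-strand TSS lies in the gene body.
#'
#' @param peaks one peak data.frame or a named list of per-sample peak
#'   data.frames (as from [simulate_coverage_and_peaks()]).
#' @param annotation gene annotation data.frame.
#' @param design optional data.frame (`sample`, `condition`) used to label
#'   per-sample results when `peaks` is a list.
#' @return data.frame with `element` and `n_peaks` (plus `sample` and
#'   `condition` when a list is supplied); element counts sum to the number
#'   of peaks.
#' @export
peak_element_distribution <- function(peaks, annotation, design = NULL) {
  ann <- gene_elements(annotation)
  classify <- function(p) {
    validate_regions(p)
    mid <- (p$start + p$end) %/% 2
    in_any <- function(lo, hi) {
      if (nrow(ann) == 0 || length(mid) == 0) return(rep(FALSE, length(mid)))
      ir <- IRanges::IRanges(lo + 1L, hi)
      IRanges::countOverlaps(IRanges::IRanges(mid + 1L, width = 1L), ir) > 0
    }
    el <- rep("intergenic", length(mid))
    el[in_any(pmin(ann$down2k_start, ann$down2k_end),
              pmax(ann$down2k_start, ann$down2k_end))] <- "down2k"
    el[in_any(pmin(ann$up2k_start, ann$up2k_end),
              pmax(ann$up2k_start, ann$up2k_end))] <- "up2k"
    el[in_any(ann$start, ann$end)] <- "cds"
    factor(el, levels = c("cds", "up2k", "down2k", "intergenic"))
  }
  if (is.data.frame(peaks)) {
    tab <- table(classify(peaks))
    return(data.frame(element = names(tab), n_peaks = as.integer(tab),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(names(peaks), function(s) {
    tab <- table(classify(peaks[[s]]))
    data.frame(sample = s, element = names(tab), n_peaks = as.integer(tab),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(design)) {
    out$condition <- design$condition[match(out$sample, design$sample)]
  }
  rownames(out) <- NULL
  out
}
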