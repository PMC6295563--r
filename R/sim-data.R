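condition_labels <- function(config) {
  rep(c("control", "treated"), each = config$n_replicates)
}

sample_ids <- function(config) {
  paste0(condition_labels(config), "_", rep(seq_len(config$n_replicates), 2))
}

# NB counts for one feature class (genes or miRNAs).
sim_nb_block <- function(n, ids, config, stream) {
  set.seed(child_seed(config$seed, stream))
  rel <- rlnorm(n, meanlog = 0, sdlog = 1)
  baseline <- config$mean_library_size * rel / sum(rel)
  n_de <- floor(config$frac_de_genes * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
  lfc <- numeric(n)
  if (n_de > 0) {
    lfc[de_idx] <- runif(n_de, config$de_log2fc_range[1],
                         config$de_log2fc_range[2]) *
      sample(c(-1, 1), n_de, replace = TRUE)
  }
  sf <- exp(runif(2 * config$n_replicates, log(0.7), log(1.4)))
  cond <- condition_labels(config)
  mu <- outer(baseline, sf)
  mu[, cond == "treated"] <- mu[, cond == "treated"] * 2^lfc
  counts <- matrix(rnbinom(length(mu), mu = mu,
                           size = 1 / max(config$nb_dispersion, 1e-8)),
                   nrow = n, dimnames = list(ids, sample_ids(config)))
  list(counts = count_matrix(counts, cond),
       de_ids = ids[de_idx], de_log2fc = lfc[de_idx], size_factors = sf)
}

#' Simulate gene and miRNA count matrices with ground truth
#'
#' Counts are drawn NB(mean = baseline x size factor x 2^log2FC-if-treated,
#' dispersion = `nb_dispersion`).  Baselines follow a log-normal abundance
#' profile scaled to `mean_library_size`; per-sample size factors are drawn
#' log-uniform in \[0.7, 1.4\].  A fraction `frac_de_genes` of genes (and the
#' same fraction of miRNAs) receives a planted log2 fold change with
#' |log2FC| in `de_log2fc_range` and random sign.  The first
#' `n_anticorrelated_genes` planted DE genes are earmarked for an opposite-
#' sign mark shift; their shifted-region coordinates are filled in later by
#' [simulate_coverage_and_peaks()], and their true miRNA-target pairs by
#' [simulate_target_predictions()].
#'
#' @param config a [sim_config()].
#' @return list with `genes` and `mirnas` ([count_matrix()] objects) and
#'   `truth`, a list recording every planted effect: `de_genes` /
#'   `de_mirnas` (data.frames id + true log2fc), `anticorrelated`
#'   (gene id, expression sign, mark sign, mark), the true per-sample
#'   `size_factors`, and placeholders for `true_targets` and
#'   `shifted_regions`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))
  mirna_ids <- sprintf("mir_%04d", seq_len(config$n_mirnas))
  g <- sim_nb_block(config$n_genes, gene_ids, config, "gene_counts")
  m <- sim_nb_block(config$n_mirnas, mirna_ids, config, "mirna_counts")

  set.seed(child_seed(config$seed, "anticorrelated"))
  n_anti <- config$n_anticorrelated_genes
  anti <- data.frame(gene_id = character(), expr_sign = integer(),
                     mark_sign = integer(), mark = character(),
                     stringsAsFactors = FALSE)
  if (n_anti > 0) {
    pick <- sample(seq_along(g$de_ids), n_anti)
    expr_sign <- as.integer(sign(g$de_log2fc[pick]))
    anti <- data.frame(
      gene_id = g$de_ids[pick],
      expr_sign = expr_sign,
      mark_sign = -expr_sign,
      mark = rep(c("medip", "h3k27me3"), length.out = n_anti),
      stringsAsFactors = FALSE)
    anti <- anti[order(anti$gene_id), , drop = FALSE]
    rownames(anti) <- NULL
  }
  list(genes = g$counts,
       mirnas = m$counts,
       truth = list(
         de_genes = data.frame(gene_id = g$de_ids, log2fc = g$de_log2fc,
                               stringsAsFactors = FALSE),
         de_mirnas = data.frame(mirna_id = m$de_ids, log2fc = m$de_log2fc,
                                stringsAsFactors = FALSE),
         anticorrelated = anti,
         size_factors = list(genes = g$size_factors, mirnas = m$size_factors),
         true_targets = NULL,
         shifted_regions = NULL))
}

#' Simulate a non-overlapping gene annotation
#'
#' Places `n_genes` gene bodies on the single synthetic chromosome without
#' overlap, with bin-aligned coordinates, random strand, and a CDS extent
#' trimmed inside the body.  Exposes the gene elements used by the coverage
#' profiles: on the coding strand, `Up2k = [TSS - 2000, TSS)` and
#' `Down2k = (TTS, TTS + 2000]` (equivalently `[TTS, TTS + 2000)` past the
#' body end in half-open coordinates).
#'
#' @param config a [sim_config()].
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `cds_start`, `cds_end` (0-based half-open), sorted by `start`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "annotation"))
  bs <- config$bin_size
  n <- config$n_genes
  len_bins <- sample(seq(config$gene_length_range[1] %/% bs,
                         config$gene_length_range[2] %/% bs),
                     n, replace = TRUE)
  lens <- len_bins * bs
  min_gap <- 4000 # leaves room for flanks between neighbours
  needed <- sum(lens) + (n + 1) * min_gap
  if (needed > config$genome_length) {
    stop("configuration error: genome too short for ", n,
         " non-overlapping gene bodies")
  }
  extra_bins <- (config$genome_length - needed) %/% bs
  w <- runif(n + 1)
  gaps <- min_gap + floor(extra_bins * w / sum(w)) * bs
  starts <- cumsum(gaps)[seq_len(n)] + c(0, cumsum(lens))[seq_len(n)]
  ends <- starts + lens
  cds_trim_l <- pmin(sample(0:4, n, replace = TRUE), len_bins - 2) * bs
  cds_trim_r <- pmin(sample(0:4, n, replace = TRUE),
                     len_bins - cds_trim_l %/% bs - 1) * bs
  data.frame(gene_id = sprintf("gene_%04d", seq_len(n)),
             chrom = "chrS",
             start = as.integer(starts),
             end = as.integer(ends),
             strand = sample(c("+", "-"), n, replace = TRUE),
             cds_start = as.integer(starts + cds_trim_l),
             cds_end = as.integer(ends - cds_trim_r),
             stringsAsFactors = FALSE)
}

#' Gene anchors and 2-kb flank elements
#'
#' Strand-aware TSS/TTS and Up2k/Down2k extents for an annotation: a
#' plus-strand gene body `[5000, 8000)` has `Up2k = [3000, 5000)` and
#' `Down2k = [8000, 10000)`; for a minus-strand gene the two are reflected.
#'
#' @param annotation annotation data.frame.
#' @param flank flank width in bases (default 2000).
#' @return the annotation with `tss`, `tts`, `up2k_start`, `up2k_end`,
#'   `down2k_start`, `down2k_end` columns appended.
#' @export
gene_elements <- function(annotation, flank = 2000L) {
  plus <- annotation$strand == "+"
  annotation$tss <- ifelse(plus, annotation$start, annotation$end)
  annotation$tts <- ifelse(plus, annotation$end, annotation$start)
  annotation$up2k_start <- ifelse(plus, annotation$start - flank,
                                  annotation$end)
  annotation$up2k_end <- annotation$up2k_start + flank
  annotation$down2k_start <- ifelse(plus, annotation$end,
                                    annotation$start - flank)
  annotation$down2k_end <- annotation$down2k_start + flank
  annotation
}

# Place k disjoint regions of `width` bases inside the given gaps
# (data.frame start/end), bin-aligned, at least `margin` from gap edges.
place_in_gaps <- function(gaps, k, width, bin_size, margin) {
  usable <- gaps[gaps$end - gaps$start >= width + 2 * margin, , drop = FALSE]
  if (nrow(usable) < k) stop("not enough intergenic room for planted regions")
  rows <- sample.int(nrow(usable), k)
  start <- vapply(rows, function(i) {
    lo <- usable$start[i] + margin
    hi <- usable$end[i] - margin - width
    lo + (sample.int((hi - lo) %/% bin_size + 1, 1) - 1) * bin_size
  }, numeric(1))
  data.frame(start = as.integer(start), end = as.integer(start + width))
}

#' Simulate binned mark coverage, read starts, and per-sample peaks
#'
#' Background bins draw Poisson(`background_lambda` x size factor) reads;
#' bins inside an enriched region are multiplied by `shift_fold`.  Stable
#' enriched regions are enriched in both conditions; shifted regions are
#' enriched in one condition only (`hyper` = enriched in treated).  One
#' shifted region is planted inside the body of each ground-truth
#' anticorrelated gene assigned to this mark, with direction opposite to the
#' gene's expression change; the remaining shifted and stable regions land in
#' intergenic gaps.  Read start positions are drawn uniformly within each
#' bin, and per-sample peaks are emitted as maximal runs of bins whose 3-bin
#' sliding-window read count exceeds a Poisson background threshold
#' (tail probability 1e-8), bridging single-bin gaps and discarding
#' single-bin runs.
#'
#' @param config a [sim_config()].
#' @param annotation from [simulate_annotation()].
#' @param truth ground-truth list from [simulate_counts()].
#' @param mark `"medip"` or `"h3k27me3"`; selects the anticorrelated genes
#'   handled by this mark and decorrelates the random stream between marks.
#' @return list: `coverage` (class `binned_coverage`: `chrom`, `bin_size`,
#'   `counts` bins x samples, `design`), `peaks` (named list of region
#'   data.frames per sample), `reads` (named list of read-start vectors per
#'   sample), and `truth` with `shifted_regions` for this mark appended.
#' @export
simulate_coverage_and_peaks <- function(config, annotation, truth,
                                        mark = "medip") {
  stopifnot(inherits(config, "sim_config"))
  if (max(annotation$end) > config$genome_length) {
    stop("input error: annotation exceeds the configured genome length")
  }
  set.seed(child_seed(config$seed, paste0("coverage_", mark)))
  bs <- config$bin_size
  n_bins <- as.integer(config$genome_length %/% bs)
  n_samp <- 2L * config$n_replicates
  cond <- condition_labels(config)
  width <- config$region_bins * bs

  anti <- truth$anticorrelated
  anti <- anti[anti$mark == mark, , drop = FALSE]
  n_anti <- nrow(anti)
  n_shift_free <- config$n_shifted_regions %/% 2 - n_anti
  n_shift_free <- max(n_shift_free, 0L)
  n_stable <- config$n_enriched_regions %/% 2
  # regions planted inside anticorrelated gene bodies, centred, bin-aligned
  reg_anti <- NULL
  if (n_anti > 0) {
    ai <- match(anti$gene_id, annotation$gene_id)
    centre <- ((annotation$start[ai] + annotation$end[ai]) %/% 2) %/% bs * bs
    reg_anti <- data.frame(start = as.integer(centre - width %/% 2),
                           end = as.integer(centre - width %/% 2 + width),
                           direction = ifelse(anti$mark_sign > 0, "hyper",
                                              "hypo"),
                           gene_id = anti$gene_id,
                           stringsAsFactors = FALSE)
  }
  gaps <- data.frame(start = c(0, annotation$end),
                     end = c(annotation$start, config$genome_length))
  free <- place_in_gaps(gaps, n_shift_free + n_stable, width, bs,
                        margin = 2200)
  reg_free_shift <- reg_free_stable <- NULL
  if (n_shift_free > 0) {
    reg_free_shift <- data.frame(
      start = free$start[seq_len(n_shift_free)],
      end = free$end[seq_len(n_shift_free)],
      direction = sample(c("hyper", "hypo"), n_shift_free, replace = TRUE),
      gene_id = NA_character_, stringsAsFactors = FALSE)
  }
  if (n_stable > 0) {
    idx <- n_shift_free + seq_len(n_stable)
    reg_free_stable <- data.frame(start = free$start[idx], end = free$end[idx],
                                  direction = "stable",
                                  gene_id = NA_character_,
                                  stringsAsFactors = FALSE)
  }
  regions <- rbind(reg_anti, reg_free_shift, reg_free_stable)
  if (is.null(regions)) {
    regions <- data.frame(start = integer(), end = integer(),
                          direction = character(), gene_id = character(),
                          stringsAsFactors = FALSE)
  }
  regions$chrom <- rep("chrS", nrow(regions))

  sf <- exp(runif(n_samp, log(0.7), log(1.4)))
  lam_bg <- config$background_lambda
  # per-condition enrichment factor per bin
  factor_for <- function(condition) {
    f <- rep(1, n_bins)
    for (i in seq_len(nrow(regions))) {
      bins <- (regions$start[i] %/% bs + 1):(regions$end[i] %/% bs)
      enr <- switch(regions$direction[i],
                    stable = TRUE,
                    hyper = condition == "treated",
                    hypo = condition == "control")
      if (enr) f[bins] <- config$shift_fold
    }
    f
  }
  f_control <- factor_for("control")
  f_treated <- factor_for("treated")

  counts <- matrix(0L, nrow = n_bins, ncol = n_samp,
                   dimnames = list(NULL, sample_ids(config)))
  reads <- vector("list", n_samp)
  names(reads) <- sample_ids(config)
  for (j in seq_len(n_samp)) {
    lam <- lam_bg * sf[j] * (if (cond[j] == "control") f_control else f_treated)
    cj <- rpois(n_bins, lam)
    counts[, j] <- cj
    nz <- which(cj > 0)
    reads[[j]] <- as.integer(rep((nz - 1) * bs, cj[nz]) +
                               sample.int(bs, sum(cj[nz]), replace = TRUE) - 1)
  }
  coverage <- structure(list(chrom = "chrS", bin_size = bs, counts = counts,
                             design = data.frame(sample = sample_ids(config),
                                                 condition = cond,
                                                 stringsAsFactors = FALSE)),
                        class = "binned_coverage")
  peaks <- lapply(seq_len(n_samp), function(j) {
    call_sample_peaks(counts[, j], lam_bg * sf[j], bs)
  })
  names(peaks) <- sample_ids(config)

  shifted <- regions[regions$direction %in% c("hyper", "hypo"), , drop = FALSE]
  shifted <- shifted[, c("chrom", "start", "end", "direction", "gene_id")]
  shifted$mark <- if (nrow(shifted)) mark else character(0)
  rownames(shifted) <- NULL
  truth$shifted_regions <- rbind(truth$shifted_regions, shifted)
  list(coverage = coverage, peaks = peaks, reads = reads, truth = truth)
}

# Threshold runs of enriched bins into peak intervals (generator-side peak
# emission; real peak callers are an input boundary, not re-implemented).
call_sample_peaks <- function(bin_counts, lambda_bg, bin_size,
                              tail_p = 1e-8, window = 3L, max_gap = 1L,
                              min_bins = 2L) {
  n <- length(bin_counts)
  win <- bin_counts +
    c(0L, bin_counts[-n]) + c(bin_counts[-1], 0L) # centred 3-bin sum
  thr <- qpois(1 - tail_p, window * lambda_bg) + 1
  enriched <- win >= thr
  r <- rle(enriched)
  # bridge short interior gaps
  if (max_gap > 0 && length(r$lengths) > 2) {
    interior <- which(!r$values & r$lengths <= max_gap &
                        seq_along(r$values) > 1 &
                        seq_along(r$values) < length(r$values))
    r$values[interior] <- TRUE
    enriched <- inverse.rle(r)
    r <- rle(enriched)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_bins
  data.frame(chrom = rep("chrS", sum(keep)),
             start = as.integer((starts[keep] - 1) * bin_size),
             end = as.integer(ends[keep] * bin_size),
             stringsAsFactors = FALSE)
}

#' Simulate a miRNA target-prediction table
#'
#' Builds the true (miRNA, gene) target pairs from the ground truth --- each
#' planted DE miRNA is paired with planted DE genes of opposite expression
#' sign --- and appends sign-concordant decoy pairs, so that the
#' anticorrelation filter should retain exactly the true pairs.  Every row
#' carries a predicted site class sampled from `site_class_probs`.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth list from [simulate_counts()]; updated
#'   `true_targets` is returned alongside the table.
#' @param targets_per_mirna how many true target genes to draw per DE miRNA
#'   (capped by availability).
#' @return list: `predictions` (data.frame `mirna_id`, `gene_id`,
#'   `site_class`) and `truth` with `true_targets` filled in.
#' @export
simulate_target_predictions <- function(config, truth, targets_per_mirna = 5L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "targets"))
  dg <- truth$de_genes
  dm <- truth$de_mirnas
  true_pairs <- NULL
  if (nrow(dg) > 0 && nrow(dm) > 0) {
    true_pairs <- do.call(rbind, lapply(seq_len(nrow(dm)), function(i) {
      opp <- dg$gene_id[sign(dg$log2fc) != sign(dm$log2fc[i])]
      if (length(opp) == 0) return(NULL)
      k <- min(targets_per_mirna, length(opp))
      data.frame(mirna_id = dm$mirna_id[i],
                 gene_id = sort(sample(opp, k)),
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(true_pairs)) {
    true_pairs <- data.frame(mirna_id = character(), gene_id = character(),
                             stringsAsFactors = FALSE)
  }
  decoys <- NULL
  if (config$n_decoy_pairs > 0) {
    all_genes <- sprintf("gene_%04d", seq_len(config$n_genes))
    all_mirnas <- sprintf("mir_%04d", seq_len(config$n_mirnas))
    cand <- data.frame(
      mirna_id = sample(all_mirnas, 4 * config$n_decoy_pairs, replace = TRUE),
      gene_id = sample(all_genes, 4 * config$n_decoy_pairs, replace = TRUE),
      stringsAsFactors = FALSE)
    # decoys must not reproduce a true anticorrelated DE pair
    g_lfc <- setNames(dg$log2fc, dg$gene_id)[cand$gene_id]
    m_lfc <- setNames(dm$log2fc, dm$mirna_id)[cand$mirna_id]
    disc <- is.na(g_lfc) | is.na(m_lfc) | sign(g_lfc) == sign(m_lfc)
    key <- paste(cand$mirna_id, cand$gene_id)
    dup <- duplicated(key) | key %in% paste(true_pairs$mirna_id,
                                            true_pairs$gene_id)
    decoys <- head(cand[disc & !dup, , drop = FALSE], config$n_decoy_pairs)
  }
  tab <- rbind(true_pairs, decoys)
  tab$site_class <- sample(names(config$site_class_probs), nrow(tab),
                           replace = TRUE, prob = config$site_class_probs)
  tab <- tab[order(tab$mirna_id, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  truth$true_targets <- true_pairs
  list(predictions = tab, truth = truth)
}

#' @export
print.binned_coverage <- function(x, ...) {
  cat(sprintf("binned_coverage: %s, %d bins of %d bp, %d samples\n",
              x$chrom, nrow(x$counts), x$bin_size, ncol(x$counts)))
  invisible(x)
}
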