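#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median, over features with
#' a positive geometric mean, of the ratio of the feature's count in that
#' sample to the feature's geometric mean across samples.  Factors are
#' returned unmodified (no rescaling).  Multiplying one sample's counts by a
#' constant `c` multiplies its factor relative to the other samples by `c`
#' exactly when all features are positive (the geometric-mean reference
#' absorbs `c^(1/m)` across the `m` samples).
#'
#' @param counts a [count_matrix()] or a numeric matrix of counts.
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' estimate_size_factors(m)   # (1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (all(m == 0)) stop("cannot normalize an all-zero count matrix")
  geomeans <- exp(rowMeans(log(m)))
  usable <- is.finite(geomeans) & geomeans > 0
  if (!any(usable)) {
    stop("no feature has positive counts in every sample; cannot normalize")
  }
  sf <- apply(m, 2, function(col) median(col[usable] / geomeans[usable]))
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("degenerate size factors; check the count matrix")
  }
  sf
}

#' Transcripts-per-million normalisation
#'
#' Scales each sample column so it sums to one million.  This is the miRNA
#' normalisation used throughout: read counts without a length term.
#'
#' @param counts a [count_matrix()] or numeric matrix.
#' @return matrix of the same shape; each column sums to 1e6.
#' @export
tpm_normalize <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  totals <- colSums(m)
  if (any(totals <= 0)) stop("zero column total; cannot TPM-normalize")
  sweep(m, 2, totals, "/") * 1e6
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.  Thin validated wrapper around [stats::p.adjust()].
#'
#' @param pvalues numeric vector in \[0, 1\] (NAs propagated).
#' @return adjusted p-values, elementwise >= input and <= 1.
#' @export
bh_adjust <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

# Row means / unbiased row variances restricted to a column subset.
row_mean_var <- function(m, cols) {
  n <- length(cols)
  mu <- rowMeans(m[, cols, drop = FALSE])
  v <- if (n > 1) {
    rowSums((m[, cols, drop = FALSE] - mu)^2) / (n - 1)
  } else {
    rep(NA_real_, nrow(m))
  }
  list(mean = mu, var = v)
}

#' Negative-binomial two-group differential test
#'
#' A negative-binomial Wald test for two-group count data, in the style of the
#' first-generation DESeq model: counts are normalised by median-of-ratios
#' size factors; a per-feature dispersion is estimated by the method of
#' moments within each condition, `max(0, (s^2 - m) / m^2)`, taking the
#' maximum over conditions and flooring at 1e-8; gene-wise estimates are then
#' shrunk conservatively toward a mean-dispersion trend `alpha(m) = a0 + a1/m`
#' (least squares on positive gene-wise estimates) by taking the maximum of
#' the gene-wise and trend values.  The log2 fold change is
#' `log2((meanT + pseudocount) / (meanC + pseudocount))` on normalised means,
#' and a two-sided p-value comes from a Wald statistic on that log ratio with
#' a delta-method variance under the NB mean-variance relation
#' `Var = mu + alpha * mu^2`.
#'
#' @param counts a [count_matrix()]; needs >= 2 replicates per condition.
#' @param size_factors per-sample positive normalisation factors; defaults to
#'   [estimate_size_factors()] on `counts`.
#' @param pseudocount added to both normalised means in the fold change
#'   (default 0.5; the value also stabilises the Wald denominator).
#' @param treated,control the condition labels being contrasted.
#' @return data.frame with one row per feature: `feature_id`,
#'   `baseMean_control`, `baseMean_treated`, `log2fc`, `pvalue`, `padj`.
#' @examples
#' cm <- count_matrix(cbind(c1 = c(10), c2 = c(10), c3 = c(10),
#'                          t1 = c(40), t2 = c(40), t3 = c(40)),
#'                    rep(c("control", "treated"), each = 3))
#' nb_test(cm, size_factors = rep(1, 6))$log2fc  # log2(40.5/10.5)
#' @export
nb_test <- function(counts, size_factors = NULL, pseudocount = 0.5,
                    treated = "treated", control = "control") {
  cm <- as_count_matrix(counts)
  cond <- cm$design$condition
  if (sum(cond == control) < 2L || sum(cond == treated) < 2L) {
    stop("unsupported design: need >= 2 replicates per condition ",
         "for dispersion estimation")
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(cm)
  if (length(size_factors) != ncol(cm$counts) || any(size_factors <= 0)) {
    stop("size_factors must be positive, one per sample")
  }
  norm <- sweep(cm$counts, 2, size_factors, "/")

  ic <- which(cond == control)
  it <- which(cond == treated)
  mvC <- row_mean_var(norm, ic)
  mvT <- row_mean_var(norm, it)

  mom <- function(mv) {
    a <- (mv$var - mv$mean) / mv$mean^2
    a[!is.finite(a)] <- 0
    pmax(a, 0)
  }
  alpha_gene <- pmax(mom(mvC), mom(mvT), 1e-8)

  base_mean <- rowMeans(norm)
  fit_ok <- alpha_gene > 1e-8 & base_mean > 0
  alpha <- alpha_gene
  if (sum(fit_ok) >= 10) {
    fit <- lm(alpha_gene[fit_ok] ~ I(1 / base_mean[fit_ok]))
    trend <- pmax(coef(fit)[1] + coef(fit)[2] / base_mean, 0)
    trend[!is.finite(trend)] <- 0
    alpha <- pmax(alpha_gene, trend)
  }

  mC <- mvC$mean
  mT <- mvT$mean
  log2fc <- log2((mT + pseudocount) / (mC + pseudocount))

  # delta method: Var(norm count_ij) = mu/s_j + alpha * mu^2
  var_mean <- function(mu, idx) {
    outer_term <- outer(mu, 1 / size_factors[idx]) # mu/s_j
    (rowSums(outer_term) + length(idx) * alpha * mu^2) / length(idx)^2
  }
  vC <- var_mean(mC, ic)
  vT <- var_mean(mT, it)
  var_log2 <- (vC / (mC + pseudocount)^2 + vT / (mT + pseudocount)^2) / log(2)^2

  z <- ifelse(var_log2 > 0, log2fc / sqrt(var_log2), 0)
  pvalue <- 2 * pnorm(-abs(z))
  pvalue[mC == mT] <- 1 # identical means: no evidence by construction
  data.frame(feature_id = rownames(cm$counts),
             baseMean_control = mC,
             baseMean_treated = mT,
             log2fc = log2fc,
             pvalue = pvalue,
             padj = bh_adjust(pvalue),
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' A gene is called when its BH-adjusted p-value is below `fdr` (default 5%
#' FDR).  Direction is annotated from the sign of the fold change.
#'
#' @param results data.frame from [nb_test()].
#' @param fdr false-discovery-rate threshold (strict `<`).
#' @return the called subset, with a `direction` column (`"up"`/`"down"`).
#' @export
call_de_genes <- function(results, fdr = 0.05) {
  called <- results[!is.na(results$padj) & results$padj < fdr, , drop = FALSE]
  called$direction <- ifelse(called$log2fc > 0, "up", "down")
  rownames(called) <- NULL
  called
}

#' Call differentially expressed miRNAs
#'
#' A miRNA is called when `padj < fdr` and `|log2fc| > min_abs_log2fc` (both
#' strict).  The default magnitude threshold of 1 follows the reported
#' DE-miRNA tables; a stricter cutoff of 2 can be requested.
#'
#' @inheritParams call_de_genes
#' @param min_abs_log2fc minimum |log2 fold change| (strict `>`).
#' @return the called subset with a `direction` column.
#' @export
call_de_mirnas <- function(results, fdr = 0.05, min_abs_log2fc = 1.0) {
  keep <- !is.na(results$padj) & results$padj < fdr &
    abs(results$log2fc) > min_abs_log2fc
  called <- results[keep, , drop = FALSE]
  called$direction <- ifelse(called$log2fc > 0, "up", "down")
  rownames(called) <- NULL
  called
}

#' Expressed-gene filter
#'
#' Keeps genes whose condition-mean abundance (FPKM) is at least `min_fpkm`
#' (inclusive) in at least one condition (`scope = "any"`) or in every
#' condition (`scope = "all"`).
#'
#' @param expr data.frame with `gene_id` and one `mean_<condition>` column per
#'   condition (or any set of numeric abundance columns).
#' @param min_fpkm inclusive abundance threshold, default 3.
#' @param scope `"any"` (default) or `"all"`.
#' @return the retained subset of `expr` (idempotent).
#' @export
expressed_filter <- function(expr, min_fpkm = 3.0, scope = c("any", "all")) {
  scope <- match.arg(scope)
  num <- vapply(expr, is.numeric, logical(1))
  ab <- as.matrix(expr[, num, drop = FALSE])
  if (ncol(ab) == 0) stop("no abundance columns found")
  if (any(ab < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  keep <- if (scope == "any") {
    apply(ab >= min_fpkm, 1, any)
  } else {
    apply(ab >= min_fpkm, 1, all)
  }
  out <- expr[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' FPKM from counts and feature lengths
#'
#' `count / (length/1e3) / (library_size/1e6)` per sample, with per-condition
#' means appended.  Used to realise the expressed-gene filter and quintile
#' abundances on count data where no external abundance table is supplied.
#'
#' @param counts a [count_matrix()].
#' @param lengths feature lengths in bases, named by or ordered as the
#'   count-matrix rows.
#' @return data.frame: `gene_id`, one column per sample, and
#'   `mean_<condition>` columns.
#' @export
fpkm_table <- function(counts, lengths) {
  cm <- as_count_matrix(counts)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(cm$counts)]
  if (length(lengths) != nrow(cm$counts) || anyNA(lengths) ||
      any(lengths <= 0)) {
    stop("lengths must be positive, one per feature")
  }
  lib <- colSums(cm$counts)
  if (any(lib <= 0)) stop("zero library size")
  fpkm <- cm$counts / (lengths / 1e3)
  fpkm <- sweep(fpkm, 2, lib / 1e6, "/")
  out <- data.frame(gene_id = rownames(cm$counts), fpkm,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (cnd in unique(cm$design$condition)) {
    cols <- cm$design$sample[cm$design$condition == cnd]
    out[[paste0("mean_", cnd)]] <- rowMeans(fpkm[, cols, drop = FALSE])
  }
  rownames(out) <- NULL
  out
}
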