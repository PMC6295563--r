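# Deterministic child seeds: one root seed, per-component streams derived
# from fixed labels so adding a component never reshuffles the others.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 16807) %% 2147483647)
}

#' Configuration of the synthetic multi-omics generator
#'
#' Collects every parameter of the synthetic study: a two-condition
#' (control / treated) design with `n_replicates` per condition, NB gene and
#' miRNA counts with spiked differential expression, a single synthetic
#' chromosome with binned mark coverage, spiked enriched regions of which a
#' subset shifts between conditions, and a planted set of genes whose
#' expression change is opposite in sign to a planted mark change.
#'
#' Defaults emulate the emulated study design: triplicates per condition,
#' 100-bp coverage bins on a 10-Mb chromosome, NB dispersion 0.05, planted
#' expression effects of |log2FC| in \[3, 4\], and 8-fold mark shifts.
#'
#' @param seed root seed; all component streams derive from it, so an
#'   identical config yields byte-identical outputs.
#' @param n_genes,n_mirnas numbers of features.
#' @param n_replicates replicates per condition.
#' @param genome_length single synthetic chromosome length in bases.
#' @param bin_size coverage bin width in bases; must divide `genome_length`.
#' @param frac_de_genes proportion of genes (and of miRNAs) planted as
#'   differentially expressed.
#' @param de_log2fc_range interval the planted |log2FC| is drawn from
#'   (sign random).
#' @param nb_dispersion NB dispersion of simulated counts.
#' @param background_lambda mean background reads per coverage bin at size
#'   factor 1.
#' @param n_enriched_regions planted mark-enriched regions per mark.
#' @param n_shifted_regions how many of those differ between conditions.
#' @param shift_fold enrichment factor of enriched bins over background.
#' @param n_anticorrelated_genes planted DE genes overlapping exactly one
#'   shifted region of opposite sign (split evenly across the marks by
#'   [simulate_coverage_and_peaks()]).
#' @param mean_library_size expected reads per count library.
#' @param gene_length_range gene body lengths, drawn in bin multiples.
#' @param region_bins width of a planted enriched region, in bins.
#' @param n_decoy_pairs concordant decoy rows added by
#'   [simulate_target_predictions()].
#' @param site_class_probs sampling proportions of predicted site classes.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       n_mirnas = 200L,
                       n_replicates = 3L,
                       genome_length = 1e7,
                       bin_size = 100L,
                       frac_de_genes = 0.1,
                       de_log2fc_range = c(3, 4),
                       nb_dispersion = 0.05,
                       background_lambda = 5,
                       n_enriched_regions = 100L,
                       n_shifted_regions = 40L,
                       shift_fold = 8,
                       n_anticorrelated_genes = 20L,
                       mean_library_size = 2e5,
                       gene_length_range = c(2000L, 6000L),
                       region_bins = 10L,
                       n_decoy_pairs = 200L,
                       site_class_probs = c("3'UTR" = 0.7, "CDS" = 0.2,
                                            "5'UTR" = 0.1)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas),
              n_replicates = as.integer(n_replicates),
              genome_length = as.numeric(genome_length),
              bin_size = as.integer(bin_size),
              frac_de_genes = frac_de_genes,
              de_log2fc_range = de_log2fc_range,
              nb_dispersion = nb_dispersion,
              background_lambda = background_lambda,
              n_enriched_regions = as.integer(n_enriched_regions),
              n_shifted_regions = as.integer(n_shifted_regions),
              shift_fold = shift_fold,
              n_anticorrelated_genes = as.integer(n_anticorrelated_genes),
              mean_library_size = mean_library_size,
              gene_length_range = as.integer(gene_length_range),
              region_bins = as.integer(region_bins),
              n_decoy_pairs = as.integer(n_decoy_pairs),
              site_class_probs = site_class_probs)
  with(cfg, {
    if (n_genes <= 0 || n_mirnas <= 0 || n_replicates <= 0) {
      stop("configuration error: dimensions must be positive")
    }
    if (nb_dispersion <= 0) {
      stop("configuration error: nb_dispersion must be positive")
    }
    if (shift_fold <= 0 || background_lambda <= 0 || mean_library_size <= 0) {
      stop("configuration error: rates must be positive")
    }
    if (frac_de_genes < 0 || frac_de_genes > 1) {
      stop("configuration error: frac_de_genes must lie in [0, 1]")
    }
    if (genome_length %% bin_size != 0) {
      stop("configuration error: bin_size must divide genome_length")
    }
    if (n_shifted_regions > n_enriched_regions) {
      stop("configuration error: n_shifted_regions > n_enriched_regions")
    }
    if (n_anticorrelated_genes > floor(frac_de_genes * n_genes)) {
      stop("configuration error: more anticorrelated genes than DE genes")
    }
    if (n_anticorrelated_genes > n_shifted_regions) {
      stop("configuration error: more anticorrelated genes than shifted regions")
    }
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: seed %d, %d genes / %d miRNAs, %d+%d reps, ",
                     "%.0f bp genome (%d-bp bins)\n"),
              x$seed, x$n_genes, x$n_mirnas, x$n_replicates, x$n_replicates,
              x$genome_length, x$bin_size))
  invisible(x)
}
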