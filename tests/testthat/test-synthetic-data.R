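test_that("config invariants are enforced", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(nb_dispersion = 0), "positive")
  expect_error(sim_config(bin_size = 33), "divide")
  expect_error(sim_config(n_shifted_regions = 10, n_enriched_regions = 5),
               "n_shifted_regions")
  expect_error(sim_config(n_anticorrelated_genes = 500), "anticorrelated")
  expect_error(simulate_annotation(small_config(genome_length = 1e5)),
               "genome too short")
})

test_that("count simulation is deterministic and honours a null config", {
  cfg <- small_config()
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$genes$counts, b$genes$counts)
  expect_identical(a$mirnas$counts, b$mirnas$counts)
  expect_identical(a$truth, b$truth)

  null_cfg <- small_config(frac_de_genes = 0, n_anticorrelated_genes = 0L)
  n <- simulate_counts(null_cfg)
  expect_equal(nrow(n$truth$de_genes), 0)
  expect_equal(nrow(n$truth$de_mirnas), 0)
  expect_equal(nrow(n$truth$anticorrelated), 0)
})

test_that("ground truth records every planted effect consistently", {
  cfg <- small_config()
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  expect_equal(nrow(tr$de_genes), floor(cfg$frac_de_genes * cfg$n_genes))
  expect_true(all(abs(tr$de_genes$log2fc) >= cfg$de_log2fc_range[1]))
  expect_true(all(abs(tr$de_genes$log2fc) <= cfg$de_log2fc_range[2]))
  expect_true(all(tr$anticorrelated$gene_id %in% tr$de_genes$gene_id))
  expect_equal(tr$anticorrelated$mark_sign, -tr$anticorrelated$expr_sign)
  # planted treated/control mean ratio shows up in the raw counts
  de_up <- tr$de_genes$gene_id[tr$de_genes$log2fc > 0]
  cond <- sim$genes$design$condition
  ratio <- rowMeans(sim$genes$counts[de_up, cond == "treated"]) /
    pmax(rowMeans(sim$genes$counts[de_up, cond == "control"]), 0.5)
  expect_gt(median(log2(ratio)), 2)
})

test_that("near-zero dispersion approaches the Poisson variance/mean limit", {
  cfg <- sim_config(seed = 3, n_genes = 2000L, n_mirnas = 10L,
                    frac_de_genes = 0, n_anticorrelated_genes = 0L,
                    nb_dispersion = 1e-8, mean_library_size = 4e5)
  sim <- simulate_counts(cfg)
  cond <- sim$genes$design$condition
  sf <- sim$truth$size_factors$genes[cond == "control"]
  cc <- sweep(sim$genes$counts[, cond == "control"], 2, sf, "/")
  m <- rowMeans(cc)
  v <- apply(cc, 1, var)
  keep <- m >= 20
  ratio <- v[keep] / m[keep]
  # oracle: the same ratio distribution from true Poisson draws under the
  # same size factors
  set.seed(1234)
  pc <- sapply(sf, function(s) rpois(sum(keep), m[keep] * s) / s)
  pr <- apply(pc, 1, var) / rowMeans(pc)
  expect_lt(abs(mean(ratio) - mean(pr)), 0.1)
  expect_lt(abs(median(ratio) - median(pr)), 0.1)
})

test_that("simulated gene bodies are pairwise disjoint with correct flanks", {
  cfg <- small_config()
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), cfg$n_genes)
  # brute-force O(n^2) overlap scan
  for (i in seq_len(nrow(ann) - 1)) {
    overlaps <- ann$start < ann$end[i] & ann$end > ann$start[i]
    expect_equal(sum(overlaps), 1L) # only itself
  }
  el <- gene_elements(data.frame(gene_id = c("p", "m"), chrom = "c",
                                 start = 5000, end = 8000,
                                 strand = c("+", "-"),
                                 cds_start = 5000, cds_end = 8000))
  expect_equal(el$up2k_start[1], 3000)   # plus: [3000, 5000)
  expect_equal(el$up2k_end[1], 5000)
  expect_equal(el$down2k_start[1], 8000) # plus: [8000, 10000)
  expect_equal(el$up2k_start[2], 8000)   # minus: [8000, 10000)
  expect_equal(el$up2k_end[2], 10000)
  expect_equal(el$down2k_start[2], 3000)
})

test_that("coverage and peaks are mutually consistent with the planting", {
  cfg <- small_config(seed = 101)
  sim <- simulate_counts(cfg)
  ann <- simulate_annotation(cfg)
  cp <- simulate_coverage_and_peaks(cfg, ann, sim$truth, mark = "medip")
  expect_equal(nrow(cp$coverage$counts),
               as.integer(cfg$genome_length / cfg$bin_size))

  # every planted shifted region is covered by a peak in every replicate of
  # its enriched condition
  sh <- cp$truth$shifted_regions
  expect_gt(nrow(sh), 0)
  for (r in seq_len(nrow(sh))) {
    cond <- if (sh$direction[r] == "hyper") "treated" else "control"
    for (s in which(cp$coverage$design$condition == cond)) {
      p <- cp$peaks[[s]]
      expect_true(any(p$start <= sh$start[r] & p$end >= sh$end[r]),
                  label = sprintf("region %d covered in sample %d", r, s))
    }
  }
  # anticorrelated genes for this mark overlap exactly one shifted region
  anti <- cp$truth$anticorrelated
  anti <- anti[anti$mark == "medip", ]
  for (g in anti$gene_id) {
    gi <- ann[ann$gene_id == g, ]
    hits <- sum(sh$start < gi$end & sh$end > gi$start)
    expect_equal(hits, 1L)
  }
})

test_that("a signal-free configuration yields empty peak sets", {
  cfg <- small_config(seed = 5, n_enriched_regions = 0L,
                      n_shifted_regions = 0L, n_anticorrelated_genes = 0L)
  sim <- simulate_counts(cfg)
  ann <- simulate_annotation(cfg)
  cp <- simulate_coverage_and_peaks(cfg, ann, sim$truth)
  expect_true(all(vapply(cp$peaks, nrow, integer(1)) == 0))
  expect_equal(nrow(cp$truth$shifted_regions), 0)
})

test_that("RPKM-normalised coverage is invariant to library size in
           expectation", {
  cfg1 <- small_config(seed = 17, background_lambda = 5)
  cfg2 <- small_config(seed = 17, background_lambda = 10) # doubled depth
  sim <- simulate_counts(cfg1)
  ann <- simulate_annotation(cfg1)
  c1 <- rpkm_bins(simulate_coverage_and_peaks(cfg1, ann, sim$truth)$coverage)
  c2 <- rpkm_bins(simulate_coverage_and_peaks(cfg2, ann, sim$truth)$coverage)
  m1 <- mean(c1$rpkm)
  m2 <- mean(c2$rpkm)
  expect_lt(abs(m1 - m2) / m1, 0.02) # equal in expectation, MC error only
})

test_that("target predictions contain the truth plus concordant decoys", {
  cfg <- small_config(n_decoy_pairs = 0L)
  sim <- simulate_counts(cfg)
  tp <- simulate_target_predictions(cfg, sim$truth)
  expect_equal(tp$predictions[, c("mirna_id", "gene_id")],
               tp$truth$true_targets[
                 order(tp$truth$true_targets$mirna_id,
                       tp$truth$true_targets$gene_id), ],
               ignore_attr = TRUE)
  # with a fixed seed, regeneration is identical
  tp2 <- simulate_target_predictions(cfg, sim$truth)
  expect_identical(tp$predictions, tp2$predictions)

  # decoys never pair a DE miRNA with an opposite-sign DE gene
  cfg3 <- small_config(n_decoy_pairs = 150L)
  tp3 <- simulate_target_predictions(cfg3, sim$truth)
  truth_keys <- paste(tp$truth$true_targets$mirna_id,
                      tp$truth$true_targets$gene_id)
  decoys <- tp3$predictions[!(paste(tp3$predictions$mirna_id,
                                    tp3$predictions$gene_id) %in% truth_keys), ]
  g <- setNames(sim$truth$de_genes$log2fc, sim$truth$de_genes$gene_id)
  m <- setNames(sim$truth$de_mirnas$log2fc, sim$truth$de_mirnas$mirna_id)
  bad <- !is.na(g[decoys$gene_id]) & !is.na(m[decoys$mirna_id]) &
    sign(g[decoys$gene_id]) != sign(m[decoys$mirna_id])
  expect_equal(sum(bad), 0L)
})

test_that("site-class frequencies match the requested proportions", {
  cfg <- sim_config(seed = 4, n_genes = 2000L, n_mirnas = 500L,
                    frac_de_genes = 0.5, n_anticorrelated_genes = 0L,
                    n_decoy_pairs = 8000L, genome_length = 4e7)
  sim <- simulate_counts(cfg)
  tp <- simulate_target_predictions(cfg, sim$truth, targets_per_mirna = 4L)
  n <- nrow(tp$predictions)
  expect_gt(n, 5000)
  freq <- table(tp$predictions$site_class) / n
  for (cls in names(cfg$site_class_probs)) {
    p <- cfg$site_class_probs[[cls]]
    half_ci <- 4 * sqrt(p * (1 - p) / n)
    expect_lt(abs(freq[[cls]] - p), half_ci)
  }
})
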