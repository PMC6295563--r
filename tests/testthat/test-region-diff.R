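test_that("peak union merges overlaps and keeps gapped intervals apart", {
  a <- data.frame(chrom = "c", start = 10, end = 100)
  b <- data.frame(chrom = "c", start = 50, end = 150)
  expect_equal(merge_peaks(list(a, b)),
               data.frame(chrom = "c", start = 10L, end = 150L))
  d <- data.frame(chrom = "c", start = c(0, 200), end = c(100, 260))
  m <- merge_peaks(d)
  expect_equal(nrow(m), 2)
  expect_equal(sum(m$end - m$start), 160) # disjoint: lengths conserved
  expect_error(merge_peaks(data.frame(chrom = "c", start = 5, end = 5)),
               "malformed")
})

test_that("peak union equals the per-base boolean oracle on random sets", {
  set.seed(31)
  for (i in 1:8) {
    sets <- lapply(1:3, function(j) random_regions(200, 20000))
    got <- merge_peaks(sets)
    all_r <- do.call(rbind, sets)
    want <- bruteforce_union(all_r$start, all_r$end, 21000)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("peak union is idempotent, commutative, and associative", {
  set.seed(37)
  a <- random_regions(50, 10000)
  b <- random_regions(50, 10000)
  c_ <- random_regions(50, 10000)
  u <- merge_peaks(list(a, b, c_))
  expect_equal(merge_peaks(u), u)
  expect_equal(merge_peaks(list(c_, a, b)), u)
  expect_equal(merge_peaks(list(merge_peaks(list(a, b)), c_)), u)
})

test_that("read counting deduplicates start positions and is half-open", {
  regions <- data.frame(chrom = "c", start = 0, end = 100)
  cm <- count_reads_in_regions(regions,
                               list(s1 = c(10, 10, 20), s2 = c(100, 99)),
                               condition = c("control", "treated"))
  expect_equal(unname(cm$counts[1, ]), c(2, 1)) # dup start once; end excluded
})

test_that("read counting matches a brute-force membership scan", {
  set.seed(41)
  for (i in 1:10) {
    regions <- merge_peaks(random_regions(20, 5000))
    reads <- lapply(1:4, function(j) sample.int(6000, 400, replace = TRUE) - 1)
    names(reads) <- sprintf("s%d", 1:4)
    cm <- count_reads_in_regions(regions, reads,
                                 rep(c("control", "treated"), each = 2))
    for (j in 1:4) {
      pos <- unique(reads[[j]])
      want <- vapply(seq_len(nrow(regions)), function(r) {
        sum(pos >= regions$start[r] & pos < regions$end[r])
      }, numeric(1))
      expect_equal(unname(cm$counts[, j]), want)
    }
    # dedup never counts more than the deduplicated read total
    expect_true(all(colSums(cm$counts) <=
                      vapply(reads, function(r) length(unique(r)), 1)))
  }
  expect_error(
    count_reads_in_regions(data.frame(chrom = "c", start = c(0, 50),
                                      end = c(100, 150)),
                           list(s = 1), "control"),
    "overlap")
})

test_that("DMR calling applies strict thresholds and direction flips with
           condition labels", {
  set.seed(43)
  mu <- outer(c(500, 80, 80), rep(1, 6))
  mu[1, 4:6] <- mu[1, 4:6] * 9 # planted hyper region
  counts <- matrix(rpois(18, mu), nrow = 3,
                   dimnames = list(c("c:0-100", "c:100-200", "c:200-300"),
                                   NULL))
  cm <- count_matrix(counts, rep(c("control", "treated"), each = 3))
  calls <- call_dmrs(cm, size_factors = rep(1, 6), mark = "medip")
  expect_equal(calls$start, 0L)
  expect_equal(calls$direction, "hyper")
  expect_equal(calls$mark, "medip")
  expect_true(abs(calls$log2fc) > 2 && calls$padj < 0.01)

  sw <- count_matrix(counts, rep(c("treated", "control"), each = 3))
  calls_sw <- call_dmrs(sw, size_factors = rep(1, 6))
  expect_equal(calls_sw$start, calls$start)
  expect_equal(calls_sw$direction, "hypo")

  # |log2fc| must exceed 2 strictly: deterministic counts landing just
  # below the cutoff are rejected even at a vanishing p-value
  low <- count_matrix(matrix(c(100, 100, 100, 399, 399, 399), nrow = 1,
                             dimnames = list("c:0-100", NULL)),
                      rep(c("control", "treated"), each = 3))
  expect_lt(abs(nb_test(low, size_factors = rep(1, 6))$log2fc), 2)
  expect_equal(nrow(call_dmrs(low, size_factors = rep(1, 6))), 0)
  hi <- count_matrix(matrix(c(100, 100, 100, 410, 410, 410), nrow = 1,
                            dimnames = list("c:0-100", NULL)),
                     rep(c("control", "treated"), each = 3))
  expect_equal(call_dmrs(hi, size_factors = rep(1, 6))$direction, "hyper")
})

test_that("region-to-gene assignment picks the nearest TSS within the
           2-kb-extended span", {
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "c",
                    start = c(10000, 20000), end = c(14000, 24000),
                    strand = c("+", "-"),
                    cds_start = c(10500, 20500), cds_end = c(13500, 23500))
  calls <- data.frame(chrom = "c",
                      start = c(11000, 16900, 30000),
                      end = c(11200, 17100, 30100),
                      log2fc = c(3, -3, 4), pvalue = 0, padj = 0,
                      direction = c("hyper", "hypo", "hyper"),
                      mark = "medip")
  got <- assign_regions_to_genes(calls, ann)
  expect_equal(got$gene_id[1], "gA") # inside gA's body
  # region 2 at 16900-17100: outside both extended spans (gA ends 16000,
  # gB starts 18000) -> unassigned
  expect_true(is.na(got$gene_id[2]))
  expect_true(is.na(got$gene_id[3]))

  # equidistant between two TSSs -> lexicographic tie-break
  ann2 <- data.frame(gene_id = c("gB", "gA"), chrom = "c",
                     start = c(1000, 5000), end = c(2000, 6000),
                     strand = "+", cds_start = c(1000, 5000),
                     cds_end = c(2000, 6000))
  mid <- data.frame(chrom = "c", start = 2950, end = 3050,
                    log2fc = 3, pvalue = 0, padj = 0,
                    direction = "hyper", mark = "medip")
  # distances: to gB TSS(1000) = 1950; to gA TSS(5000) = 1951 -> gB wins;
  # shift so both distances are 1950 to force the tie
  mid2 <- data.frame(chrom = "c", start = 2951, end = 3050,
                     log2fc = 3, pvalue = 0, padj = 0,
                     direction = "hyper", mark = "medip")
  expect_equal(assign_regions_to_genes(mid2, ann2)$gene_id, "gA")
})

test_that("region-to-gene assignment matches a brute-force all-pairs scan", {
  set.seed(47)
  cfg <- small_config()
  ann <- simulate_annotation(cfg)
  for (i in 1:5) {
    calls <- random_regions(60, cfg$genome_length - 1000)
    calls$log2fc <- rnorm(60, 0, 3)
    calls$pvalue <- 0
    calls$padj <- 0
    calls$direction <- "hyper"
    calls$mark <- "m"
    got <- assign_regions_to_genes(calls, ann)
    tss <- ifelse(ann$strand == "+", ann$start, ann$end)
    for (r in seq_len(nrow(calls))) {
      ov <- which(pmax(ann$start - 2000, 0) < calls$end[r] &
                    ann$end + 2000 > calls$start[r])
      if (length(ov) == 0) {
        expect_true(is.na(got$gene_id[r]))
      } else {
        d <- pmax(calls$start[r] - tss[ov], tss[ov] - (calls$end[r] - 1), 0)
        best <- ov[order(d, ann$gene_id[ov])][1]
        expect_equal(got$gene_id[r], ann$gene_id[best])
      }
    }
  }
})

test_that("per-gene mark summary takes the strongest region", {
  calls <- data.frame(gene_id = c("g1", "g1", "g2", NA),
                      log2fc = c(2.5, -3.5, 4, 9), mark = "medip")
  s <- summarize_gene_marks(calls)
  expect_equal(s$mark_log2fc[s$gene_id == "g1"], -3.5)
  expect_equal(s$direction, c("hypo", "hyper"))
  expect_equal(nrow(s), 2) # NA-assigned region dropped
  s2 <- summarize_gene_marks(calls, summary = "mean")
  expect_equal(s2$mark_log2fc[s2$gene_id == "g1"], -0.5)
})
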