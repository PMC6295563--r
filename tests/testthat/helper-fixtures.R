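# Shared helpers: small configs and brute-force oracles used across files.

small_config <- function(seed = 11, ...) {
  args <- list(seed = seed, n_genes = 200L, n_mirnas = 60L,
               genome_length = 2e6, n_enriched_regions = 30L,
               n_shifted_regions = 16L, n_anticorrelated_genes = 8L,
               n_decoy_pairs = 80L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# per-base boolean union of half-open intervals on one chromosome
bruteforce_union <- function(starts, ends, genome_len) {
  covered <- logical(genome_len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  r <- rle(covered)
  pos <- cumsum(r$lengths)
  keep <- r$values
  data.frame(start = (pos - r$lengths)[keep], end = pos[keep])
}

# hand-rolled BH step-up (independent of stats::p.adjust)
bruteforce_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

random_regions <- function(n, genome_len, max_w = 500) {
  s <- sample.int(genome_len - max_w, n)
  data.frame(chrom = "chrS", start = s,
             end = s + sample.int(max_w, n, replace = TRUE))
}
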