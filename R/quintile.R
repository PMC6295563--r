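#' Assign genes to expression quintiles
#'
#' Genes are sorted by ascending abundance (ties broken by lexicographic gene
#' id, so the assignment is deterministic and invariant to input order); the
#' gene at 0-based sorted position `k` of `n` receives rank
#' `floor(5k/n) + 1`.  Rank 1 is the bottom 20% (lowest expression), rank 5
#' the top 20%.  Rank sizes differ by at most one when `n` is not divisible
#' by five.
#'
#' @param abundances data.frame with `gene_id` and `abundance` columns, or a
#'   named numeric vector of non-negative abundances.
#' @return data.frame `gene_id`, `abundance`, `rank` (1..5), sorted by
#'   ascending abundance.
#' @examples
#' assign_quintiles(setNames(1:10, sprintf("g%02d", 1:10)))$rank
#' @export
assign_quintiles <- function(abundances) {
  if (is.numeric(abundances)) {
    abundances <- data.frame(gene_id = names(abundances),
                             abundance = as.numeric(abundances),
                             stringsAsFactors = FALSE)
  }
  if (!all(c("gene_id", "abundance") %in% names(abundances))) {
    stop("need gene_id and abundance columns")
  }
  n <- nrow(abundances)
  if (n < 5) stop("quintile assignment needs at least 5 genes")
  if (anyDuplicated(abundances$gene_id)) stop("duplicate gene ids")
  if (any(abundances$abundance < 0)) stop("abundances must be non-negative")
  ord <- order(abundances$abundance, abundances$gene_id)
  out <- abundances[ord, c("gene_id", "abundance"), drop = FALSE]
  out$rank <- floor(5 * (seq_len(n) - 1) / n) + 1L
  rownames(out) <- NULL
  out
}

#' Rank transitions between conditions
#'
#' Pairs each gene's control-condition quintile with its treated-condition
#' quintile.
#'
#' @param control,treated outputs of [assign_quintiles()] over the same gene
#'   universe.
#' @return data.frame `gene_id`, `rank_control`, `rank_treated`,
#'   `jump = rank_treated - rank_control`, sorted by gene id.
#' @export
rank_transitions <- function(control, treated) {
  if (!setequal(control$gene_id, treated$gene_id)) {
    stop("control and treated must cover the same gene set")
  }
  rc <- setNames(control$rank, control$gene_id)
  rt <- setNames(treated$rank, treated$gene_id)
  ids <- sort(control$gene_id)
  data.frame(gene_id = ids,
             rank_control = as.integer(rc[ids]),
             rank_treated = as.integer(rt[ids]),
             jump = as.integer(rt[ids]) - as.integer(rc[ids]),
             stringsAsFactors = FALSE)
}

#' 5x5 quintile transition matrix
#'
#' Cell (i, j) counts the genes in control rank i and treated rank j; the
#' grand total equals the number of genes, and row sums equal the control
#' rank sizes.
#'
#' @inheritParams rank_transitions
#' @return integer 5x5 matrix, rows = control rank, columns = treated rank.
#' @export
transition_matrix <- function(control, treated) {
  tr <- rank_transitions(control, treated)
  m <- table(factor(tr$rank_control, levels = 1:5),
             factor(tr$rank_treated, levels = 1:5))
  m <- unclass(m)
  dimnames(m) <- list(control = 1:5, treated = 1:5)
  m
}

#' Genes with a specific rank transition
#'
#' Extracts the genes that moved from `from_rank` in the control condition to
#' `to_rank` in the treated condition, e.g. the extreme movers from the
#' bottom quintile into the upper quintiles.
#'
#' @param transitions data.frame from [rank_transitions()].
#' @param from_rank,to_rank quintile ranks in 1..5.
#' @return character vector of gene ids, sorted.
#' @export
extreme_movers <- function(transitions, from_rank, to_rank) {
  if (!(from_rank %in% 1:5) || !(to_rank %in% 1:5)) {
    stop("ranks must lie in 1..5")
  }
  sort(transitions$gene_id[transitions$rank_control == from_rank &
                             transitions$rank_treated == to_rank])
}
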