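#' Count matrix with sample design
#'
#' Bundles an integer count matrix (features x samples) with the two-group
#' design (condition label and replicate index per sample).  This is the
#' substrate of every differential test in the package: gene counts, miRNA
#' counts, and region read counts all use the same container.
#'
#' @param counts numeric matrix of non-negative integers, features in rows.
#'   Row names are feature ids; column names are sample ids (generated as
#'   `<condition>_<replicate>` when absent).
#' @param condition character vector, one label per column, typically
#'   `"control"` / `"treated"`.
#' @param replicate optional integer replicate index per column; defaults to
#'   1..k within each condition.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `design` (data.frame with `sample`, `condition`,
#'   `replicate`).
#' @examples
#' m <- matrix(rpois(12, 10), nrow = 2,
#'             dimnames = list(c("g1", "g2"), NULL))
#' cm <- count_matrix(m, rep(c("control", "treated"), each = 3))
#' cm$design
#' @export
count_matrix <- function(counts, condition, replicate = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("counts must be numeric")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (length(condition) != ncol(counts)) {
    stop("condition must have one label per sample column")
  }
  condition <- as.character(condition)
  if (any(table(condition) < 1L) || length(unique(condition)) < 1L) {
    stop("each condition needs at least one sample")
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("feature_%05d", seq_len(nrow(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate feature ids")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0(condition, "_", replicate)
  }
  storage.mode(counts) <- "double"
  structure(
    list(counts = counts,
         design = data.frame(sample = colnames(counts),
                             condition = condition,
                             replicate = as.integer(replicate),
                             stringsAsFactors = FALSE)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", names(table(x$design$condition)),
                            table(x$design$condition)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Internal: accept a count_matrix or a bare matrix + condition vector.
as_count_matrix <- function(x, condition = NULL) {
  if (inherits(x, "count_matrix")) return(x)
  if (is.null(condition)) stop("condition labels required for a bare matrix")
  count_matrix(x, condition)
}
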