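# Tabular interchange: TSV with header, UTF-8, '.' decimal, deterministic
# row order decided by the producing function.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read a BED file
#'
#' Parses BED3+ into a region data.frame with 0-based half-open coordinates.
#' Malformed lines (fewer than three fields, non-numeric or negative
#' coordinates, `start >= end`) raise an error naming the line number.
#'
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end` (plus `name`, `score`,
#'   `strand` when present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_line <- function(i) {
    f <- fields[[i]]
    if (length(f) < 3) stop("BED parse error at line ", i,
                            ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) stop("BED parse error at line ", i,
                                   ": non-numeric coordinate")
    if (s < 0 || s >= e) stop("BED parse error at line ", i,
                              ": require 0 <= start < end")
    c(f, rep(NA_character_, 6 - min(length(f), 6)))[1:6]
  }
  m <- t(vapply(seq_along(fields), parse_line, character(6)))
  out <- data.frame(chrom = m[, 1],
                    start = as.integer(as.numeric(m[, 2])),
                    end = as.integer(as.numeric(m[, 3])),
                    stringsAsFactors = FALSE)
  if (any(!is.na(m[, 4]))) out$name <- m[, 4]
  if (any(!is.na(m[, 5]))) out$score <- suppressWarnings(as.numeric(m[, 5]))
  if (any(!is.na(m[, 6]))) out$strand <- m[, 6]
  out
}

#' Write regions as BED3
#'
#' Canonical three-column tab-separated output, no header; a
#' `write_bed(read_bed(f))` round trip on canonical BED3 input is
#' byte-identical.
#'
#' @param regions region data.frame (`chrom`, `start`, `end`).
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  validate_regions(regions)
  writeLines(sprintf("%s\t%d\t%d", regions$chrom,
                     as.integer(regions$start), as.integer(regions$end)),
             path)
  invisible(path)
}

#' Read a BED12 gene annotation
#'
#' Uses name as the gene id, strand from column 6, and thickStart/thickEnd
#' as the CDS extent.
#'
#' @param path file path.
#' @return annotation data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `cds_start`, `cds_end`).
#' @export
read_annotation_bed12 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 12)
  if (length(bad)) {
    stop("BED12 parse error at line ", bad[1], ": fewer than 12 fields")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  out <- data.frame(gene_id = m[, 4],
                    chrom = m[, 1],
                    start = as.integer(m[, 2]),
                    end = as.integer(m[, 3]),
                    strand = m[, 6],
                    cds_start = as.integer(m[, 7]),
                    cds_end = as.integer(m[, 8]),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 |
                 out$start >= out$end | !(out$strand %in% c("+", "-")))
  if (length(bad)) stop("BED12 parse error at line ", bad[1])
  out
}

#' Write a gene annotation as BED12
#'
#' @param annotation annotation data.frame.
#' @param path output path.
#' @export
write_annotation_bed12 <- function(annotation, path) {
  a <- annotation
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d,\t0,",
                     a$chrom, as.integer(a$start), as.integer(a$end),
                     a$gene_id, a$strand, as.integer(a$cds_start),
                     as.integer(a$cds_end), as.integer(a$end - a$start)),
             path)
  invisible(path)
}

#' Write a count matrix as TSV
#'
#' First column `feature_id`, then one column per sample named
#' `<condition>_<replicate>`.
#'
#' @param cm a [count_matrix()].
#' @param path output path.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a count matrix from TSV
#'
#' Validates integer counts and unique feature ids.  When `design` is NULL
#' the condition and replicate of each sample are parsed from headers of the
#' form `<condition>_<replicate>`.
#'
#' @param path file path.
#' @param design optional data.frame `sample`, `condition` (and optionally
#'   `replicate`); all samples must be present in the file.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, design = NULL) {
  df <- read_tsv(path)
  if (names(df)[1] != "feature_id") stop("parse error: first column must be feature_id")
  if (anyDuplicated(df$feature_id)) stop("parse error: duplicate feature id")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(m != round(m)) || any(m < 0)) {
    stop("parse error: counts must be non-negative integers")
  }
  rownames(m) <- df$feature_id
  if (is.null(design)) {
    parts <- regmatches(colnames(m), regexec("^(.*)_([0-9]+)$", colnames(m)))
    if (any(vapply(parts, length, integer(1)) != 3)) {
      stop("parse error: cannot infer design from sample headers")
    }
    condition <- vapply(parts, `[`, character(1), 2)
    replicate <- as.integer(vapply(parts, `[`, character(1), 3))
  } else {
    missing <- setdiff(design$sample, colnames(m))
    if (length(missing)) stop("parse error: missing sample ", missing[1])
    m <- m[, design$sample, drop = FALSE]
    condition <- design$condition
    replicate <- if ("replicate" %in% names(design)) design$replicate else NULL
  }
  count_matrix(m, condition, replicate)
}

#' Write binned coverage as a 4-column bedGraph-like TSV
#'
#' One file per sample: `chrom`, `start`, `end`, `count` over 0-based
#' half-open bins (zero-count bins included so the binning is explicit).
#'
#' @param coverage a `binned_coverage`.
#' @param dir output directory; files are named `<sample>.coverage.tsv`.
#' @return invisible vector of file paths.
#' @export
write_coverage <- function(coverage, dir) {
  bs <- coverage$bin_size
  starts <- (seq_len(nrow(coverage$counts)) - 1L) * bs
  paths <- vapply(colnames(coverage$counts), function(s) {
    p <- file.path(dir, paste0(s, ".coverage.tsv"))
    write_tsv(data.frame(chrom = coverage$chrom, start = starts,
                         end = starts + bs, count = coverage$counts[, s]), p)
    p
  }, character(1))
  invisible(paths)
}

#' Read binned coverage from per-sample TSV files
#'
#' @param paths named character vector of file paths (names = sample ids).
#' @param condition condition label per sample.
#' @return a `binned_coverage`.
#' @export
read_coverage <- function(paths, condition) {
  mats <- lapply(paths, read_tsv)
  bs <- unique(mats[[1]]$end - mats[[1]]$start)
  if (length(bs) != 1) stop("parse error: irregular bin size")
  counts <- vapply(mats, function(df) as.integer(df$count),
                   integer(nrow(mats[[1]])))
  colnames(counts) <- names(paths)
  structure(list(chrom = mats[[1]]$chrom[1], bin_size = as.integer(bs),
                 counts = counts,
                 design = data.frame(sample = names(paths),
                                     condition = condition,
                                     stringsAsFactors = FALSE)),
            class = "binned_coverage")
}
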