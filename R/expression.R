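# Metatranscriptome-to-MAG linkage: best-hit assignment, read-support
# confirmation, binary expression/prevalence matrices, coxL~pckA correlation.

#' Filter transcript hits and keep the best hit per transcript
#'
#' Applies the blastp-style acceptance thresholds (E-value at most
#' `max_evalue`, percent identity at least `min_identity`), then keeps, per
#' transcript within each sample, the single best hit: highest bit score,
#' ties broken by lowest E-value, remaining ties by lexicographically
#' smallest `protein_id`. The result is deterministic and stable under
#' duplicated input rows.
#'
#' @param hits data.frame with `transcript_id`, `sample_id`, `protein_id`,
#'   `mag_id`, `bit_score`, `e_value`, `identity` and `function_id` (gene
#'   symbol or KO of the matched protein).
#' @param max_evalue Maximum accepted E-value (default `1e-10`).
#' @param min_identity Minimum accepted percent identity (default 55).
#' @return data.frame of assignments, one row per assigned
#'   (sample, transcript); transcripts with no passing hit are absent. The
#'   fraction of transcripts assigned is attached as attribute
#'   `alignment_rate` — a QC metric, not a filter.
#' @export
filter_and_assign <- function(hits, max_evalue = 1e-10, min_identity = 55) {
  need <- c("transcript_id", "sample_id", "protein_id", "mag_id",
            "bit_score", "e_value", "identity", "function_id")
  missing_cols <- setdiff(need, names(hits))
  if (length(missing_cols)) {
    stop("hit table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(hits$e_value < 0)) stop("negative E-value")
  hits <- unique(hits[, need])
  n_transcripts <- length(unique(paste(hits$sample_id, hits$transcript_id)))
  pass <- hits$e_value <= max_evalue & hits$identity >= min_identity
  hits <- hits[pass, , drop = FALSE]
  if (nrow(hits) == 0L) {
    hits <- hits[0L, , drop = FALSE]
    attr(hits, "alignment_rate") <- if (n_transcripts) 0 else NA_real_
    return(hits)
  }
  # best first within (sample, transcript)
  ord <- order(hits$sample_id, hits$transcript_id,
               -hits$bit_score, hits$e_value, hits$protein_id,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  best <- !duplicated(hits[, c("sample_id", "transcript_id")])
  out <- hits[best, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alignment_rate") <-
    length(unique(paste(out$sample_id, out$transcript_id))) / n_transcripts
  out
}

#' Confirm assignments by metatranscriptome read support
#'
#' An assignment is confirmed in a sample when the mapped-read count for its
#' (function, MAG) in that sample reaches `min_reads` (default 5). The read
#' threshold is applied per (gene, sample), not pooled across samples.
#'
#' @param assignments Output of [filter_and_assign()].
#' @param read_support data.frame `function_id`, `mag_id`, `sample_id`,
#'   `count` of mapped reads; pairs absent from the table count as 0.
#' @param min_reads Minimum read count (default 5).
#' @return `assignments` restricted to confirmed rows, with a `reads`
#'   column.
#' @export
confirm_by_reads <- function(assignments, read_support, min_reads = 5) {
  need <- c("function_id", "mag_id", "sample_id", "count")
  missing_cols <- setdiff(need, names(read_support))
  if (length(missing_cols)) {
    stop("read-support table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cnt <- read_support$count
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt))) {
    stop("read counts must be non-negative integers")
  }
  key <- function(f, m, s) paste(f, m, s, sep = "\r")
  support <- stats::setNames(cnt, key(read_support$function_id,
                                      read_support$mag_id,
                                      read_support$sample_id))
  got <- support[key(assignments$function_id, assignments$mag_id,
                     assignments$sample_id)]
  got[is.na(got)] <- 0
  out <- assignments[got >= min_reads, , drop = FALSE]
  out$reads <- unname(got[got >= min_reads])
  rownames(out) <- NULL
  out
}

#' Build the binary expression matrix
#'
#' Transcripts with the same function and MAG affiliation are merged: each
#' row is one (function, MAG) pair, each column one sample, and a cell is 1
#' when at least one assigned (and, if read confirmation was applied,
#' confirmed) transcript supports that pair in that sample.
#'
#' @param assignments Output of [filter_and_assign()] or
#'   [confirm_by_reads()].
#' @param samples Sample universe for the columns; defaults to the samples
#'   seen in `assignments`. Supply the full design explicitly so that
#'   samples with no assignment appear as all-zero columns.
#' @return Object of class `expression_matrix`: binary matrix with rows
#'   named `"<function>|<mag>"`, plus a `rows` data.frame mapping row names
#'   to `function_id`/`mag_id`.
#' @export
build_expression_matrix <- function(assignments, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(assignments$sample_id))
  samples <- as.character(samples)
  rows <- unique(assignments[, c("function_id", "mag_id")])
  rows <- rows[order(rows$function_id, rows$mag_id, method = "radix"), ,
               drop = FALSE]
  rownames(rows) <- NULL
  mat <- matrix(0L, nrow = nrow(rows), ncol = length(samples),
                dimnames = list(paste(rows$function_id, rows$mag_id,
                                      sep = "|"),
                                samples))
  if (nrow(assignments)) {
    ri <- match(paste(assignments$function_id, assignments$mag_id, sep = "|"),
                rownames(mat))
    ci <- match(as.character(assignments$sample_id), samples)
    if (anyNA(ci)) stop("assignment references a sample outside `samples`")
    mat[cbind(ri, ci)] <- 1L
  }
  structure(list(matrix = mat, rows = rows), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$matrix), " (function, MAG) rows x ",
      ncol(x$matrix), " samples; ", sum(x$matrix), " expressed cells\n",
      sep = "")
  invisible(x)
}

#' Row prevalence and the prevalent-expression flag
#'
#' Prevalence is the fraction of samples in which a (function, MAG) row is
#' expressed; rows at or above the cutoff (default 0.90, i.e. expression in
#' at least 90% of samples) are flagged as prevalently expressed.
#'
#' @param x An `expression_matrix`.
#' @param cutoff Prevalence cutoff in (0, 1] (default 0.9).
#' @return data.frame `function_id`, `mag_id`, `n_expressed`, `n_samples`,
#'   `prevalence`, `prevalent`.
#' @export
prevalence_flags <- function(x, cutoff = 0.9) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!(cutoff > 0 && cutoff <= 1)) stop("cutoff must be in (0, 1]")
  n_exp <- rowSums(x$matrix)
  n <- ncol(x$matrix)
  m <- nrow(x$rows)
  data.frame(x$rows,
             n_expressed = as.integer(n_exp),
             n_samples = rep(n, m),
             prevalence = if (n) n_exp / n else rep(NA_real_, m),
             prevalent = if (n) n_exp / n >= cutoff else rep(FALSE, m),
             stringsAsFactors = FALSE)
}

#' Spearman correlation between two expression rows
#'
#' Rank correlation (midranks for ties) between two rows across shared
#' samples, with the p-value from the large-sample t approximation
#' (`stats::cor.test(..., method = "spearman", exact = FALSE)`). Intended
#' for continuous abundance rows (e.g. coxL vs pckA expression levels);
#' binary 0/1 rows are accepted but degenerate for ranking.
#'
#' @param x An `expression_matrix`, or a numeric matrix with named rows.
#' @param row_a,row_b Row names (for an `expression_matrix`,
#'   `"<function>|<mag>"`).
#' @param samples Optional subset of sample columns.
#' @return List with `rho`, `p_value`, `n`.
#' @export
correlate_functions <- function(x, row_a, row_b, samples = NULL) {
  mat <- if (inherits(x, "expression_matrix")) x$matrix else as.matrix(x)
  for (r in c(row_a, row_b)) {
    if (!r %in% rownames(mat)) stop("row not found: ", r)
  }
  if (!is.null(samples)) mat <- mat[, as.character(samples), drop = FALSE]
  a <- mat[row_a, ]
  b <- mat[row_b, ]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("need at least 3 shared samples with values")
  ct <- suppressWarnings(
    stats::cor.test(a[ok], b[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
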