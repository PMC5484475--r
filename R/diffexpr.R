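#' Two-sided rank-sum test
#'
#' Unpaired Mann-Whitney / Wilcoxon rank-sum test between two independent
#' groups: the exact null distribution is enumerated when the combined size
#' is at most 12 and there are no ties, otherwise the normal approximation
#' with tie and continuity correction is used. The histological-grade groups
#' compared here are independent and of unequal size, which is why the
#' unpaired test is the default; a paired signed-rank mode is available for
#' equal-size paired designs.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param paired use the paired signed-rank test (requires equal lengths).
#' @return the two-sided p-value.
#' @export
ranksum_test <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  if (paired && length(a) != length(b))
    stop("paired mode requires equal-length groups")
  pooled <- c(a, b)
  if (stats::var(pooled) == 0) return(1)
  if (paired) {
    res <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    return(unname(res$p.value))
  }
  exact <- (length(a) + length(b)) <= 12L && !anyDuplicated(pooled)
  p <- if (exact) {
    stats::wilcox.test(a, b, exact = TRUE)$p.value
  } else {
    suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }
  if (is.nan(p)) p <- 1  # zero rank variance (all values tied)
  unname(min(p, 1))
}

#' Fold change between group means
#'
#' Ratio of linear-scale group means, group B over group A; values above 1
#' mean higher in B.
#'
#' @param a,b numeric vectors of linear-scale intensities.
#' @return mean(b)/mean(a), or `NA` when mean(a) <= 0 (undefined).
#' @export
fold_change <- function(a, b) {
  if (mean(a) <= 0) return(NA_real_)
  mean(b) / mean(a)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q for the i-th smallest p is
#' min over j >= i of (m * p_(j) / j), clipped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_qvalues <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Count of significant p-values
#'
#' @param p numeric vector of p-values.
#' @param alpha significance level; the comparison is strict (p < alpha).
#' @return integer count.
#' @export
count_significant <- function(p, alpha = 0.05) {
  sum(p < alpha)
}

#' Differential protein expression between two grade groups
#'
#' Per-analyte two-sided rank-sum p-values between the samples of two groups,
#' fold changes as ratios of linear-scale group means (second group over
#' first), and Benjamini-Hochberg q-values. Rank tests are computed on the
#' supplied values directly (ranks are invariant to the log2 transform);
#' fold changes are computed on the linear scale, un-logging first when the
#' matrix is log2-staged.
#'
#' @param matrix an [analyte_matrix()] (stage `"log2"` or a linear stage).
#' @param groups factor (or vector) over the matrix rows with exactly two
#'   used levels; the first level is group A, the second group B.
#' @return data.frame of class `diff_expr_table` with columns `analyte`,
#'   `fold_change`, `p_value`, `q_value`, sorted by ascending p.
#' @export
diff_expr <- function(matrix, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (length(groups) != nrow(matrix))
    stop("groups length must match sample count")
  v <- unclass(matrix)
  lin <- if (identical(stage(matrix), "log2")) 2^v else v
  ia <- groups == levels(groups)[1L]
  ib <- groups == levels(groups)[2L]
  p <- apply(v, 2L, function(col) ranksum_test(col[ia], col[ib]))
  fc <- vapply(seq_len(ncol(v)),
               function(j) fold_change(lin[ia, j], lin[ib, j]), numeric(1))
  out <- data.frame(analyte = colnames(v), fold_change = fc, p_value = p,
                    q_value = bh_qvalues(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(out$p_value, out$analyte), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- levels(groups)
  class(out) <- c("diff_expr_table", "data.frame")
  out
}

#' Write a differential-expression table as TSV
#'
#' Columns mirror the published table layout: protein name, fold change,
#' rank-test p-value, q-value.
#'
#' @param table a `diff_expr_table` from [diff_expr()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diff_expr <- function(table, path) {
  out <- data.frame(`Protein Names` = table$analyte,
                    Foldchange = table$fold_change,
                    `Wilcoxon p-values` = table$p_value,
                    QvaluesAll = table$q_value,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
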