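#' Aggregate replicate spot intensities with the 15% CV rule
#'
#' Triplicate spots are averaged when their coefficient of variation (sample
#' SD / mean) is at most `cv_threshold`; otherwise the replicate farthest
#' from the median is dropped and the remaining two are averaged. Pairs are
#' always averaged. A non-positive triplicate mean makes the CV undefined and
#' is treated as exceeding the threshold.
#'
#' @param replicates numeric vector of 2 or 3 finite intensities.
#' @param cv_threshold CV cut-off as a fraction (default 0.15).
#' @return list with `mean` (aggregated intensity), `n_used` (2 or 3) and
#'   `cv` (the replicate CV before the rule, `NA` when undefined).
#' @export
aggregate_replicates <- function(replicates, cv_threshold = 0.15) {
  x <- replicates[!is.na(replicates)]
  if (length(x) < 2L) stop("need at least 2 recorded replicates")
  if (!all(is.finite(x))) stop("replicate intensities must be finite")
  if (length(x) == 2L) {
    cv <- if (mean(x) > 0) stats::sd(x) / mean(x) else NA_real_
    return(list(mean = mean(x), n_used = 2L, cv = cv))
  }
  m <- mean(x)
  cv <- if (m > 0) stats::sd(x) / m else NA_real_
  if (!is.na(cv) && cv <= cv_threshold)
    return(list(mean = m, n_used = 3L, cv = cv))
  drop <- which.max(abs(x - stats::median(x)))
  list(mean = mean(x[-drop]), n_used = 2L, cv = cv)
}

#' Aggregate a raw dataset into a samples-by-analytes matrix
#'
#' Applies [aggregate_replicates()] to every (sample, antibody) cell and
#' assembles the quality-control report: the distribution of replicate CVs
#' and the fraction of cells aggregated from 3 versus 2 replicates.
#'
#' @param raw a [raw_dataset()].
#' @param cv_threshold replicate CV cut-off (fraction).
#' @return list with `matrix` (an [analyte_matrix()], stage `"aggregated"`)
#'   and `qc` (a `qc_report`).
#' @export
aggregate_dataset <- function(raw, cv_threshold = 0.15) {
  ns <- length(raw$samples); na <- length(raw$antibodies)
  vals <- matrix(NA_real_, ns, na, dimnames = list(raw$samples, raw$antibodies))
  n_used <- matrix(NA_integer_, ns, na)
  n_rec <- matrix(NA_integer_, ns, na)
  cvs <- matrix(NA_real_, ns, na)
  for (i in seq_len(ns)) {
    for (j in seq_len(na)) {
      reps <- raw$intensities[i, j, ]
      reps <- reps[!is.na(reps)]
      if (length(reps) < 2L) {
        # single spot: no CV rule applicable, keep the value as-is
        vals[i, j] <- reps
        n_used[i, j] <- 1L
        n_rec[i, j] <- 1L
        next
      }
      agg <- aggregate_replicates(reps, cv_threshold)
      vals[i, j] <- agg$mean
      n_used[i, j] <- agg$n_used
      n_rec[i, j] <- length(reps)
      cvs[i, j] <- agg$cv
    }
  }
  qc <- structure(list(
    replicate_cv = cvs,
    mean_replicate_cv = mean(cvs, na.rm = TRUE),
    sd_replicate_cv = stats::sd(as.vector(cvs), na.rm = TRUE),
    frac_from_3 = mean(n_used == 3L, na.rm = TRUE),
    frac_from_2 = mean(n_used == 2L, na.rm = TRUE),
    frac_from_1 = mean(n_used == 1L, na.rm = TRUE),
    n_used = n_used,
    discarded_analytes = character(0),
    outlier_samples = character(0),
    n_floored = NA_integer_), class = "qc_report")
  list(matrix = analyte_matrix(vals, "aggregated"), qc = qc)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Quality control report\n")
  cat(sprintf("  mean replicate CV: %.1f%% (+/- %.1f%%)\n",
              100 * x$mean_replicate_cv, 100 * x$sd_replicate_cv))
  cat(sprintf("  cells aggregated from 3 replicates: %.1f%%, from 2: %.1f%%\n",
              100 * x$frac_from_3, 100 * x$frac_from_2 + 100 * x$frac_from_1))
  cat(sprintf("  analytes discarded below LOD: %d\n",
              length(x$discarded_analytes)))
  if (length(x$outlier_samples))
    cat("  flagged outlier samples:",
        paste(x$outlier_samples, collapse = ", "), "\n")
  if (!is.na(x$n_floored))
    cat(sprintf("  cells floored before log2: %d\n", x$n_floored))
  invisible(x)
}

#' Limit of detection from PBS negative-control spots
#'
#' LOD = mean(PBS) + 2 * sample SD(PBS).
#'
#' @param pbs numeric vector of at least 2 PBS spot intensities (one sample's
#'   spots, or all samples pooled).
#' @return the LOD value.
#' @export
compute_lod <- function(pbs) {
  pbs <- pbs[!is.na(pbs)]
  if (length(pbs) < 2L)
    stop("need >= 2 PBS intensities to estimate an LOD; ",
         "skip LOD filtering when no negative controls are available")
  mean(pbs) + 2 * stats::sd(pbs)
}

#' Discard analytes below the limit of detection
#'
#' An analyte is discarded when its aggregated mean intensity falls below the
#' LOD in strictly more than `sample_fraction` of the samples.
#'
#' @param matrix aggregated-stage [analyte_matrix()].
#' @param lod a single pooled LOD, or a named per-sample vector of LODs.
#' @param sample_fraction fraction of samples that must be below LOD before
#'   an analyte is discarded (default 0.70; the comparison is strict).
#' @return list with `matrix` (retained analytes) and `discarded` (character
#'   vector of discarded analyte identifiers).
#' @export
lod_filter <- function(matrix, lod, sample_fraction = 0.70) {
  stopifnot(stage(matrix) == "aggregated")
  if (length(lod) > 1L) {
    if (is.null(names(lod)) || !all(rownames(matrix) %in% names(lod)))
      stop("per-sample LOD vector must be named for every sample")
    lod <- lod[rownames(matrix)]
  }
  below <- colMeans(unclass(matrix) < lod)
  discarded <- colnames(matrix)[below > sample_fraction]
  keep <- setdiff(colnames(matrix), discarded)
  list(matrix = retag(unclass(matrix)[, keep, drop = FALSE], "aggregated"),
       discarded = discarded)
}

#' Flag outlier samples in principal-component space
#'
#' PCA on log2-transformed aggregated intensities; a sample is flagged when
#' its Euclidean distance from the centroid in the space of the first three
#' components exceeds `z_cut` robust standard deviations (median/MAD scaled)
#' of the sample distances. Flags are advisory: removal requires an explicit
#' request (see `drop_samples` in [preprocess()]).
#'
#' @param matrix aggregated-stage [analyte_matrix()] (linear scale).
#' @param z_cut robust z cut-off (default 3.0).
#' @param log_floor values at or below 0 are replaced by this before log2.
#' @return character vector of flagged sample identifiers (possibly empty).
#' @export
flag_outliers <- function(matrix, z_cut = 3.0, log_floor = 1) {
  if (nrow(matrix) < 3L) stop("need >= 3 samples to flag outliers")
  lv <- unclass(matrix)
  lv[lv <= 0] <- log_floor
  lv <- log2(lv)
  keep <- apply(lv, 2L, function(col) stats::sd(col) > 0)
  if (!any(keep)) {
    warning("constant matrix: no principal components, nothing flagged")
    return(character(0))
  }
  pc <- stats::prcomp(lv[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(3L, ncol(pc$x))
  d <- sqrt(rowSums(pc$x[, seq_len(k), drop = FALSE]^2))
  s <- stats::mad(d)
  if (s == 0) return(character(0))
  rownames(matrix)[(d - stats::median(d)) / s > z_cut]
}

#' Select low-CV reference analytes for semiglobal normalization
#'
#' Per-analyte CVs are computed across samples on linear-scale aggregated
#' intensities; the lowest-CV fraction (rounded half-up) is returned. Ties at
#' the boundary break by analyte identifier order.
#'
#' @param matrix linear-scale [analyte_matrix()] (stage `"aggregated"`).
#' @param fraction fraction of analytes to select, in (0, 1] (default 0.15;
#'   e.g. 290 analytes yield 44 references).
#' @return character vector of reference analyte identifiers.
#' @export
select_reference_analytes <- function(matrix, fraction = 0.15) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  v <- unclass(matrix)
  cv <- apply(v, 2L, function(col) stats::sd(col) / mean(col))
  k <- floor(fraction * ncol(v) + 0.5)  # round half-up
  ord <- order(cv, colnames(v))
  colnames(v)[ord[seq_len(k)]]
}

#' Semiglobal normalization
#'
#' For each sample i, the scale factor is N_i = S_i / mu, where S_i is the
#' sum of the reference-analyte intensities of sample i and mu is the mean of
#' the S_i over samples. Every intensity of sample i is divided by N_i, which
#' equalizes the reference sums across samples (each becomes mu) and removes
#' array-to-array scale differences.
#'
#' @param matrix linear-scale [analyte_matrix()].
#' @param reference character vector of reference analyte identifiers, a
#'   subset of the matrix columns (see [select_reference_analytes()]).
#' @return list with `matrix` (stage `"normalized"`) and `norm`, a
#'   `normalization_result` holding `reference_analytes`, `S`, `mu` and `N`.
#' @export
semiglobal_normalize <- function(matrix, reference) {
  if (!all(reference %in% colnames(matrix)))
    stop("reference analytes not all present in matrix")
  v <- unclass(matrix)
  S <- rowSums(v[, reference, drop = FALSE])
  if (any(S <= 0))
    stop("non-positive reference-analyte sum; normalization undefined for sample(s): ",
         paste(rownames(matrix)[S <= 0], collapse = ", "))
  mu <- mean(S)
  N <- S / mu
  out <- v / N
  norm <- structure(list(reference_analytes = reference, S = S, mu = mu, N = N),
                    class = "normalization_result")
  list(matrix = retag(out, "normalized"), norm = norm)
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("semiglobal normalization: %d reference analytes, mu = %.4g\n",
              length(x$reference_analytes), x$mu))
  cat(sprintf("  N_i range: [%.4f, %.4f], mean %.6f\n",
              min(x$N), max(x$N), mean(x$N)))
  invisible(x)
}

#' Log2 transform with a positivity floor
#'
#' @param matrix normalized-stage [analyte_matrix()].
#' @param floor small positive value substituted for cells at or below 0
#'   before taking log2 (default 1, i.e. such cells map to 0).
#' @return list with `matrix` (stage `"log2"`) and `n_floored`, the number of
#'   substituted cells.
#' @export
log2_transform <- function(matrix, floor = 1) {
  stopifnot(floor > 0)
  v <- unclass(matrix)
  n_floored <- sum(v <= 0)
  v[v <= 0] <- floor
  list(matrix = retag(log2(v), "log2"), n_floored = n_floored)
}

#' Full preprocessing of a raw antibody-array dataset
#'
#' Runs the stages in fixed order: replicate aggregation (15% CV rule) ->
#' LOD filter against PBS negative controls -> PCA outlier flagging (on log2
#' of aggregated data) -> low-CV reference-analyte selection -> semiglobal
#' normalization -> log2 transform. LOD uses per-sample PBS statistics when
#' every sample has its own control spots, otherwise a pooled LOD; it is
#' skipped with a warning when no PBS spots exist. Outlier flags are
#' advisory: samples are only dropped when listed in `drop_samples` or when
#' `drop_outliers = TRUE`.
#'
#' @param raw a [raw_dataset()].
#' @param cv_threshold replicate CV cut-off (default 0.15).
#' @param lod_sample_fraction LOD filter sample fraction (default 0.70).
#' @param ref_fraction reference-analyte fraction (default 0.15).
#' @param log_floor floor used before log2 (default 1).
#' @param outlier_z robust z cut-off for outlier flagging (default 3.0).
#' @param drop_outliers drop all flagged samples (explicit opt-in).
#' @param drop_samples character vector of sample identifiers to drop after
#'   flagging (explicit confirmation of a visual/PCA review).
#' @return object of class `grade_preprocess`: list with `log2` and `linear`
#'   (normalized) matrices, `qc` report, `norm` result, `discarded` analytes,
#'   `outliers` flagged, and the parameters used.
#' @export
preprocess <- function(raw, cv_threshold = 0.15, lod_sample_fraction = 0.70,
                       ref_fraction = 0.15, log_floor = 1, outlier_z = 3.0,
                       drop_outliers = FALSE, drop_samples = NULL) {
  agg <- aggregate_dataset(raw, cv_threshold)
  mat <- agg$matrix
  qc <- agg$qc

  discarded <- character(0)
  if (length(raw$pbs) && sum(lengths(raw$pbs)) >= 2L) {
    per_sample <- all(rownames(mat) %in% names(raw$pbs)) &&
      all(lengths(raw$pbs[rownames(mat)]) >= 2L)
    lod <- if (per_sample) {
      vapply(raw$pbs[rownames(mat)], compute_lod, numeric(1))
    } else {
      compute_lod(unlist(raw$pbs, use.names = FALSE))
    }
    lf <- lod_filter(mat, lod, lod_sample_fraction)
    mat <- lf$matrix
    discarded <- lf$discarded
  } else {
    warning("no PBS negative-control spots: LOD filtering skipped")
    lod <- NULL
  }
  qc$discarded_analytes <- discarded

  outliers <- flag_outliers(mat, z_cut = outlier_z, log_floor = log_floor)
  qc$outlier_samples <- outliers
  to_drop <- unique(c(if (isTRUE(drop_outliers)) outliers, drop_samples))
  if (length(to_drop)) {
    unknown <- setdiff(to_drop, rownames(mat))
    if (length(unknown)) stop("drop_samples not in dataset: ",
                              paste(unknown, collapse = ", "))
    mat <- retag(unclass(mat)[setdiff(rownames(mat), to_drop), , drop = FALSE],
                 "aggregated")
  }

  reference <- select_reference_analytes(mat, ref_fraction)
  norm <- semiglobal_normalize(mat, reference)
  lg <- log2_transform(norm$matrix, floor = log_floor)
  qc$n_floored <- lg$n_floored

  structure(list(
    log2 = lg$matrix, linear = norm$matrix, qc = qc, norm = norm$norm,
    discarded = discarded, outliers = outliers, dropped = to_drop,
    params = list(cv_threshold = cv_threshold,
                  lod_sample_fraction = lod_sample_fraction,
                  ref_fraction = ref_fraction, log_floor = log_floor,
                  outlier_z = outlier_z)),
    class = "grade_preprocess")
}

#' @export
print.grade_preprocess <- function(x, ...) {
  cat("Preprocessed antibody-array dataset\n")
  cat(sprintf("  %d samples x %d analytes retained (%d analytes below LOD",
              nrow(x$log2), ncol(x$log2), length(x$discarded)))
  cat(sprintf(", %d sample(s) dropped)\n", length(x$dropped)))
  cat(sprintf("  %d reference analytes; normalization factors in [%.3f, %.3f]\n",
              length(x$norm$reference_analytes), min(x$norm$N), max(x$norm$N)))
  print(x$qc)
  invisible(x)
}
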