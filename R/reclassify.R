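#' Three-way class call from a symmetric grey zone
#' @noRd
call_with_grey <- function(score, cut) {
  ifelse(is.na(score), NA_character_,
         ifelse(score >= cut, "grade1_like",
                ifelse(score <= -cut, "grade3_like", "grade2_grey")))
}

new_reclass_outcome <- function(calls, model, params, log = NULL) {
  structure(list(calls = calls, model = model, params = params, log = log),
            class = "reclass_outcome")
}

#' Frozen-model grading with a decision-value grey zone (model 1)
#'
#' A single linear SVM (cost 1) is trained on the complete grade 1 + grade 3
#' anchor set restricted to a condensed signature, then frozen and applied
#' to the test samples (typically the grade 2 tumors). Test decision values
#' d call the sample grade-1-like when d >= `grey`, grade-3-like when
#' d <= -`grey`, and leave it in the indeterminate grey zone otherwise
#' (boundaries inclusive towards the anchor classes).
#'
#' @param train_X anchor samples x features matrix (grades 1 and 3).
#' @param train_y anchor labels; the level named by `positive` (default the
#'   first) maps to positive decision values (grade 1 by convention).
#' @param signature character vector of features to restrict the model to.
#' @param test_X samples x features matrix to be graded.
#' @param grey half-width of the grey zone on the decision-value axis
#'   (default 0.5).
#' @param C SVM cost (default 1).
#' @param positive label of the positive (grade 1) class.
#' @return object of class `reclass_outcome`; `$calls` is a data.frame with
#'   `sample`, `score` (decision value) and `class` in
#'   \{grade1_like, grade2_grey, grade3_like\}. The fitted `linear_svm` is
#'   kept in `$model`.
#' @export
frozen_classify <- function(train_X, train_y, signature, test_X, grey = 0.5,
                            C = 1, positive = NULL) {
  if (!length(signature)) stop("signature must not be empty")
  if (!all(signature %in% colnames(train_X)) ||
      !all(signature %in% colnames(test_X)))
    stop("signature features missing from training or test matrix")
  fit <- train_linear_svm(as.matrix(train_X)[, signature, drop = FALSE],
                          train_y, C = C, positive = positive)
  d <- predict(fit, as.matrix(test_X))
  calls <- data.frame(
    sample = rownames(test_X) %||% as.character(seq_len(nrow(test_X))),
    score = d, class = call_with_grey(d, grey),
    stringsAsFactors = FALSE, row.names = NULL)
  new_reclass_outcome(calls, fit,
                      params = list(type = "frozen", grey = grey, C = C))
}

#' Bootstrap grading by signed classification tallies (models 2 and 3)
#'
#' Per iteration, a training set is drawn with replacement from the grade 1
#' and grade 3 anchors (group sizes preserved); the test set is every grade 2
#' sample plus the out-of-bag anchors. A condensed signature is either
#' derived by backward elimination on the draw (`signature_mode =
#' "per_iteration"`, model 2) or supplied fixed (model 3, typically the
#' consensus panel of a model-2 run), and a frozen SVM trained on the draw
#' calls each test sample grade 1 or grade 3 by decision-value sign. After
#' `n_iter` iterations each sample's score is the signed percentage
#' 100 * (grade-1 calls - grade-3 calls) / times tested, in -100..100, and
#' the three-way class call applies the `tally_cut` grey zone (default
#' |score| < 70 stays indeterminate). Anchors are tested only out-of-bag, so
#' their scores come from models that never trained on them.
#'
#' @param X samples x features matrix (normalized log2 intensities).
#' @param grades integer vector (1, 2 or 3) over the rows of `X`.
#' @param n_iter bootstrap iterations (default 100).
#' @param signature_mode `"per_iteration"`, or a character vector of feature
#'   identifiers used as a fixed panel.
#' @param panel_size condensed signature size for per-iteration elimination
#'   (default 20).
#' @param tally_cut grey-zone cut on the signed percentage scale (default 70).
#' @param seed master seed; per-iteration seeds are derived deterministically
#'   from it, so earlier iterations are unaffected by `n_iter`.
#' @param C SVM cost (default 1).
#' @return object of class `reclass_outcome`; `$calls` has one row per
#'   sample of `X` with `score`, `class`, `times_tested`, `calls_grade1`,
#'   `calls_grade3` and the true `grade`; `$log` records each iteration's
#'   training draw and signature.
#' @export
bootstrap_reclassify <- function(X, grades, n_iter = 100,
                                 signature_mode = "per_iteration",
                                 panel_size = 20, tally_cut = 70,
                                 seed = 1, C = 1) {
  X <- as.matrix(X)
  grades <- as.integer(grades)
  stopifnot(length(grades) == nrow(X), all(grades %in% 1:3))
  if (n_iter < 1L) stop("n_iter must be >= 1")
  per_iteration <- identical(signature_mode, "per_iteration")
  if (!per_iteration) {
    if (!is.character(signature_mode) || !all(signature_mode %in% colnames(X)))
      stop("fixed signature must name features of X")
  }
  i1 <- which(grades == 1L)
  i3 <- which(grades == 3L)
  i2 <- which(grades == 2L)
  if (length(i1) < 2L || length(i3) < 2L)
    stop("need >= 2 samples in each anchor grade")
  sn <- rownames(X) %||% as.character(seq_len(nrow(X)))
  n <- nrow(X)
  tested <- n_g1 <- n_g3 <- integer(n)
  log <- vector("list", n_iter)

  for (it in seq_len(n_iter)) {
    set.seed((seed + 48271 * it) %% 2147483647L)
    draw <- c(sample(i1, length(i1), replace = TRUE),
              sample(i3, length(i3), replace = TRUE))
    y <- factor(ifelse(grades[draw] == 1L, "grade1", "grade3"),
                levels = c("grade1", "grade3"))
    test_idx <- c(i2, setdiff(c(i1, i3), unique(draw)))
    sig <- if (per_iteration) {
      backward_eliminate(X[draw, , drop = FALSE], y, panel_size = panel_size,
                         C = C, kl_every = 0,
                         positive = "grade1")$condensed_signature
    } else signature_mode
    fit <- train_linear_svm(X[draw, sig, drop = FALSE], y, C = C,
                            positive = "grade1")
    d <- predict(fit, X[test_idx, , drop = FALSE])
    tested[test_idx] <- tested[test_idx] + 1L
    n_g1[test_idx] <- n_g1[test_idx] + (d > 0)
    n_g3[test_idx] <- n_g3[test_idx] + (d < 0)
    log[[it]] <- list(seed = (seed + 48271 * it) %% 2147483647L,
                      train = sn[draw], signature = sig,
                      tested = sn[test_idx], decision = unname(d))
  }
  score <- ifelse(tested > 0L, 100 * (n_g1 - n_g3) / tested, NA_real_)
  never <- sn[tested == 0L]
  if (length(never))
    warning("samples never tested (always in-bag): ",
            paste(never, collapse = ", "))
  calls <- data.frame(sample = sn, grade = grades, score = score,
                      class = call_with_grey(score, tally_cut),
                      times_tested = tested, calls_grade1 = n_g1,
                      calls_grade3 = n_g3, stringsAsFactors = FALSE,
                      row.names = NULL)
  new_reclass_outcome(
    calls, model = NULL,
    params = list(type = if (per_iteration) "bootstrap_per_iteration"
                  else "bootstrap_fixed_panel",
                  n_iter = n_iter, panel_size = panel_size,
                  tally_cut = tally_cut, seed = seed, C = C,
                  signature = if (per_iteration) NULL else signature_mode),
    log = log)
}

#' @export
print.reclass_outcome <- function(x, ...) {
  cat(sprintf("re-classification outcome (%s)\n", x$params$type))
  tab <- table(factor(x$calls$class,
                      levels = c("grade1_like", "grade2_grey", "grade3_like")))
  cat(sprintf("  grade-1-like: %d, grey zone: %d, grade-3-like: %d (of %d)\n",
              tab[1L], tab[2L], tab[3L], nrow(x$calls)))
  invisible(x)
}

#' @export
summary.reclass_outcome <- function(object, ...) {
  calls <- object$calls
  if ("grade" %in% names(calls)) {
    tab <- table(true_grade = calls$grade, call = calls$class)
  } else {
    tab <- table(call = calls$class)
  }
  out <- list(params = object$params, table = tab, calls = calls)
  class(out) <- "summary.reclass_outcome"
  out
}

#' @export
print.summary.reclass_outcome <- function(x, ...) {
  cat(sprintf("re-classification (%s)\n", x$params$type))
  print(x$table)
  invisible(x)
}

#' Plot re-classification scores with the grey-zone cut-offs
#'
#' Dot plot of the per-sample score (decision value for the frozen model,
#' signed tally percentage for the bootstrap models) with dashed lines at
#' the symmetric grey-zone boundaries.
#'
#' @param x a `reclass_outcome`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.reclass_outcome <- function(x, ...) {
  calls <- x$calls
  cut <- if (x$params$type == "frozen") x$params$grey else x$params$tally_cut
  graphics::plot(seq_len(nrow(calls)), calls$score, pch = 16,
                 xlab = "Sample", ylab = "Score (positive = grade-1-like)",
                 ...)
  graphics::abline(h = c(-cut, cut), lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Per-class counts of an outcome's calls
#'
#' @param x a `reclass_outcome`.
#' @param samples optional sample subset (e.g. only the grade 2 tumors).
#' @return named integer vector over grade1_like / grade2_grey / grade3_like.
#' @export
class_counts <- function(x, samples = NULL) {
  calls <- x$calls
  if (!is.null(samples)) calls <- calls[calls$sample %in% samples, ]
  tab <- table(factor(calls$class,
                      levels = c("grade1_like", "grade2_grey", "grade3_like")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Agreement between two re-classification outcomes
#'
#' @param a,b `reclass_outcome` objects over the same sample set.
#' @return list with `overlap` (number of samples with identical calls),
#'   `n`, and `table`, the 3x3 contingency of calls (rows = `a`).
#' @export
compare_models <- function(a, b) {
  ca <- a$calls
  cb <- b$calls
  if (!setequal(ca$sample, cb$sample))
    stop("outcomes cover different sample sets")
  cb <- cb[match(ca$sample, cb$sample), ]
  lv <- c("grade1_like", "grade2_grey", "grade3_like")
  tab <- table(a = factor(ca$class, lv), b = factor(cb$class, lv))
  list(overlap = sum(ca$class == cb$class, na.rm = TRUE), n = nrow(ca),
       table = tab)
}
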