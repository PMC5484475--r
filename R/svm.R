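#' Train a linear soft-margin SVM
#'
#' Minimizes 0.5*||w||^2 + C * sum(hinge) via libsvm (e1071) with a linear
#' kernel and fixed solver tolerance, then extracts the primal weight vector
#' and bias so that decision values d(x) = w.x + b are positive for the
#' `positive` class. Features are not standardized: the classifier operates
#' on normalized log2 intensities directly (per-fold z-scoring can be
#' enabled with `standardize = TRUE`).
#'
#' @param X numeric matrix, samples in rows, features in columns.
#' @param y two-class factor (or vector coercible to one) over the rows.
#' @param C cost of constraints violation (default 1).
#' @param positive the class mapped to positive decision values; defaults to
#'   the first factor level. In grade comparisons grade 1 is listed first, so
#'   positive decision values read "grade-1-like".
#' @param standardize z-score each feature using training statistics.
#' @param tolerance libsvm termination tolerance (default 1e-6 so that
#'   decision values are reproducible across runs).
#' @return object of class `linear_svm`: list with `w` (named weights), `b`,
#'   `features`, `C`, `positive`, `levels`, and the standardization
#'   statistics when requested.
#' @export
train_linear_svm <- function(X, y, C = 1, positive = NULL,
                             standardize = FALSE, tolerance = 1e-6) {
  X <- as.matrix(X)
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) != 2L)
    stop("need exactly two classes; got: ", paste(levels(y), collapse = ", "))
  if (is.null(positive)) positive <- levels(y)[1L]
  if (!positive %in% levels(y)) stop("positive class not among labels")
  center <- scale_ <- NULL
  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, stats::sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  }
  fit <- e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm signs the decision for the first label it encountered
  first <- levels(y)[fit$labels[1L]]
  if (!identical(first, positive)) {
    w <- -w
    b <- -b
  }
  names(w) <- colnames(X)
  structure(list(w = w, b = b, features = colnames(X), C = C,
                 positive = positive, levels = levels(y),
                 center = center, scale = scale_),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("linear SVM (C = %g): %d features, positive class '%s'\n",
              x$C, length(x$w), x$positive))
  invisible(x)
}

#' @export
coef.linear_svm <- function(object, ...) c(bias = object$b, object$w)

#' Decision values and class predictions from a linear SVM
#'
#' @param object a [train_linear_svm()] model.
#' @param newdata matrix whose columns include the model's features.
#' @param type `"decision"` for signed decision values (distance-scaled
#'   scores from the hyperplane), `"class"` for hard labels by sign.
#' @param ... unused.
#' @return numeric decision values, or a character vector of class labels.
#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("decision", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  if (!is.null(object$center))
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  d <- drop(X %*% object$w + object$b)
  if (type == "decision") return(d)
  neg <- setdiff(object$levels, object$positive)
  ifelse(d > 0, object$positive, neg)
}

#' Leave-one-out cross-validated decision values
#'
#' For each sample i a model is trained on all other samples and the held-out
#' sample's decision value is recorded, so every score comes from a model
#' that never saw the sample. Folds whose training labels collapse to one
#' class yield `NA` with a warning.
#'
#' @inheritParams train_linear_svm
#' @param features optional character vector restricting the feature set
#'   (e.g. a condensed signature); default uses all columns (unfiltered
#'   data).
#' @return object of class `loocv_result`: data.frame with columns `sample`,
#'   `decision`, `label`, plus attributes `positive` and `C`.
#' @export
loocv_decisions <- function(X, y, C = 1, positive = NULL, features = NULL,
                            standardize = FALSE) {
  X <- as.matrix(X)
  y <- factor(y)
  y <- droplevels(y)
  if (any(table(y) < 2L)) stop("need >= 2 samples per class for LOOCV")
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  if (is.null(positive)) positive <- levels(y)[1L]
  n <- nrow(X)
  d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    yi <- droplevels(y[-i])
    if (nlevels(yi) < 2L) {
      warning(sprintf("fold %d collapses to a single class; decision set NA", i))
      next
    }
    fit <- train_linear_svm(X[-i, , drop = FALSE], yi, C = C,
                            positive = positive, standardize = standardize)
    d[i] <- predict(fit, X[i, , drop = FALSE])
  }
  out <- data.frame(sample = rownames(X) %||% as.character(seq_len(n)),
                    decision = d, label = as.character(y),
                    stringsAsFactors = FALSE)
  structure(out, positive = positive, C = C,
            class = c("loocv_result", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.loocv_result <- function(x, ...) {
  pos <- attr(x, "positive")
  auc <- roc_auc(x$decision, x$label, positive = pos)
  cat(sprintf("LOOCV decisions: %d samples, positive class '%s', AUC = %.3f\n",
              nrow(x), pos, auc))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: the fraction of
#' (positive, negative) pairs in which the positive sample scores higher,
#' ties counted one half (midrank form).
#'
#' @param scores numeric scores (e.g. LOOCV decision values); `NA` scores are
#'   dropped with their labels.
#' @param labels class labels, same length as `scores`.
#' @param positive the label counted as positive; defaults to the first
#'   level of `factor(labels)`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  keep <- !is.na(scores)
  scores <- scores[keep]
  labels <- factor(labels[keep])
  if (is.null(positive)) positive <- levels(labels)[1L]
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Kullback-Leibler classification error of decision values
#'
#' Decision values are mapped to probabilities through the logistic sigmoid
#' p = 1/(1 + exp(-d)) and scored against the 0/1 targets with the mean
#' cross-entropy -(1/n) * sum(t*log(p) + (1-t)*log(1-p)), the K-L divergence
#' of the predicted from the empirical label distribution up to the entropy
#' of degenerate targets. Probabilities are clipped to [1e-12, 1-1e-12].
#'
#' @param decisions numeric decision values.
#' @param targets 0/1 (or logical) targets, 1 meaning the positive class.
#' @return nonnegative mean error in nats.
#' @export
kl_error <- function(decisions, targets) {
  t <- as.numeric(targets)
  stopifnot(length(decisions) == length(t), all(t %in% c(0, 1)))
  p <- 1 / (1 + exp(-decisions))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}
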