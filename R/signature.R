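#' SVM-based backward elimination of antibodies
#'
#' Recursive feature elimination: a linear SVM (cost `C`) is trained on all
#' remaining features using the full training set, the feature with the
#' smallest squared weight is removed (ties break to the lexicographically
#' first identifier), and the process repeats until `panel_size` features
#' remain. The condensed signature is the surviving panel. Along the way the
#' Kullback-Leibler classification error of leave-one-out decision values on
#' the remaining features can be recorded, producing the error-versus-
#' eliminations curve used to judge the signature.
#'
#' @inheritParams train_linear_svm
#' @param panel_size number of features to retain (default 20, the condensed
#'   signature size).
#' @param kl_every record the LOOCV K-L error every this many eliminations
#'   (1 = every step); 0 disables the curve, which makes bootstrap runs much
#'   cheaper.
#' @param criterion `"weight"` removes the smallest-|w| feature (default);
#'   `"greedy_kl"` instead removes the feature whose removal minimizes the
#'   training-set K-L error (one SVM fit per candidate per step), provided
#'   for sensitivity analysis.
#' @return object of class `elimination_trace`: `removal_order` (first
#'   eliminated first), `kl_steps` and `kl_curve` (eliminations performed
#'   and the K-L error after them), `condensed_signature` (survivors, in
#'   column order), and `rank_from_end` (named integer vector: survivors 0,
#'   last-eliminated 1, ...; smaller means more important).
#' @export
backward_eliminate <- function(X, y, panel_size = 20, C = 1, kl_every = 1,
                               positive = NULL,
                               criterion = c("weight", "greedy_kl")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("need exactly two classes")
  if (panel_size < 1L || panel_size >= ncol(X))
    stop("panel_size must be in [1, number of features - 1]")
  if (is.null(positive)) positive <- levels(y)[1L]

  remaining <- colnames(X)
  removal_order <- character(0)
  kl_steps <- integer(0)
  kl_curve <- numeric(0)
  n_elim <- ncol(X) - panel_size
  t01 <- as.numeric(y == positive)

  for (step in seq_len(n_elim)) {
    Xr <- X[, remaining, drop = FALSE]
    drop_id <- if (criterion == "weight") {
      fit <- train_linear_svm(Xr, y, C = C, positive = positive)
      w2 <- fit$w^2
      remaining[order(w2, remaining)[1L]]
    } else {
      errs <- vapply(remaining, function(f) {
        keep <- setdiff(remaining, f)
        fit <- train_linear_svm(X[, keep, drop = FALSE], y, C = C,
                                positive = positive)
        kl_error(predict(fit, X[, keep, drop = FALSE]), t01)
      }, numeric(1))
      remaining[order(errs, remaining)[1L]]
    }
    remaining <- setdiff(remaining, drop_id)
    removal_order <- c(removal_order, drop_id)
    if (kl_every > 0 && (step %% kl_every == 0L || step == n_elim)) {
      cv <- loocv_decisions(X[, remaining, drop = FALSE], y, C = C,
                            positive = positive)
      ok <- !is.na(cv$decision)
      kl_steps <- c(kl_steps, step)
      kl_curve <- c(kl_curve, kl_error(cv$decision[ok], t01[ok]))
    }
  }
  rank_from_end <- c(stats::setNames(rev(seq_along(removal_order)),
                                     removal_order),
                     stats::setNames(integer(length(remaining)), remaining))
  structure(list(removal_order = removal_order, kl_steps = kl_steps,
                 kl_curve = kl_curve, condensed_signature = remaining,
                 rank_from_end = rank_from_end, panel_size = panel_size,
                 C = C, criterion = criterion, positive = positive),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("backward elimination: %d features eliminated, %d retained\n",
              length(x$removal_order), length(x$condensed_signature)))
  cat("  condensed signature:",
      paste(utils::head(x$condensed_signature, 8L), collapse = ", "),
      if (length(x$condensed_signature) > 8L) "..." else "", "\n")
  if (length(x$kl_curve))
    cat(sprintf("  K-L error: %.4f at first recording, %.4f at last\n",
                x$kl_curve[1L], x$kl_curve[length(x$kl_curve)]))
  invisible(x)
}

#' Plot the K-L error against the number of eliminated antibodies
#'
#' @param x an [backward_eliminate()] trace with a recorded curve.
#' @param ... passed to [graphics::plot()].
#' @export
plot.elimination_trace <- function(x, ...) {
  if (!length(x$kl_curve)) stop("no K-L curve recorded (kl_every = 0)")
  graphics::plot(x$kl_steps, x$kl_curve, type = "b", pch = 16,
                 xlab = "Eliminated antibodies",
                 ylab = "K-L classification error", ...)
  graphics::abline(v = length(x$removal_order), lty = 2)
  invisible(x)
}

#' Consensus signature across elimination runs
#'
#' Counts how often each analyte appears in the condensed signatures of a
#' collection of elimination runs (e.g. across bootstrap iterations) and
#' returns the `k` most frequent. Ties break to the analyte with the smaller
#' mean removal rank counted from the most-important end (i.e. the one that
#' survived longer on average; survivors rank 0), then to identifier order.
#'
#' @param signatures list of [backward_eliminate()] traces, or of character
#'   vectors (in which case ranks are taken as 0 for every member).
#' @param k panel size (default 20).
#' @return object of class `consensus_panel`: `panel` (the k identifiers),
#'   `counts` (appearances per analyte, all analytes seen), `mean_rank`,
#'   `n_runs`.
#' @export
consensus_signature <- function(signatures, k = 20) {
  if (!length(signatures)) stop("need at least one signature")
  sigs <- lapply(signatures, function(s)
    if (inherits(s, "elimination_trace")) s$condensed_signature else
      as.character(s))
  ranks <- lapply(signatures, function(s)
    if (inherits(s, "elimination_trace")) s$rank_from_end else
      stats::setNames(integer(length(s)), as.character(s)))
  members <- unlist(sigs, use.names = FALSE)
  counts <- sort(table(members), decreasing = TRUE)
  all_ids <- names(counts)
  mean_rank <- vapply(all_ids, function(id) {
    r <- vapply(ranks, function(rk) if (id %in% names(rk)) rk[[id]] else
      NA_real_, numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-as.integer(counts), mean_rank, all_ids)
  if (k > length(all_ids)) {
    warning(sprintf("only %d distinct analytes seen; returning all",
                    length(all_ids)))
    k <- length(all_ids)
  }
  structure(list(panel = all_ids[ord][seq_len(k)],
                 counts = stats::setNames(as.integer(counts), all_ids),
                 mean_rank = mean_rank, n_runs = length(signatures), k = k),
            class = "consensus_panel")
}

#' @export
print.consensus_panel <- function(x, ...) {
  cat(sprintf("consensus panel (%d of %d analytes over %d runs):\n",
              x$k, length(x$counts), x$n_runs))
  sel <- x$counts[x$panel]
  for (i in seq_along(x$panel))
    cat(sprintf("  %2d. %-20s %d/%d\n", i, x$panel[i], sel[i], x$n_runs))
  invisible(x)
}
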