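# Independent brute-force oracles used to validate the package's
# implementations, plus small fixture builders. The oracles deliberately use
# the most direct (slow) formulation of each quantity.

# AUC as the literal all-pairs count, ties counted one half
bf_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# exact two-sided rank-sum p by exhaustive enumeration of group assignments
bf_ranksum_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  m <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(n, m)
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * (n - m) / 2
  # two-sided: probability of a statistic at least as extreme as observed
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# BH as the literal "largest k with p_(k) <= k*alpha/m" rejection rule
bf_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k <- max(c(0L, which(p[ord] <= seq_len(m) * alpha / m)))
  rejected <- logical(m)
  if (k > 0L) rejected[ord[seq_len(k)]] <- TRUE
  rejected
}

# replicate aggregation as a direct restatement of the CV/median rule
bf_aggregate <- function(x, threshold = 0.15) {
  if (length(x) == 2L) return(mean(x))
  m <- mean(x)
  cv_ok <- m > 0 && stats::sd(x) / m <= threshold
  if (cv_ok) return(m)
  mean(x[-which.max(abs(x - stats::median(x)))])
}

# small labelled matrix with two well-separated classes in one feature
make_separated <- function(n_per = 10, p = 5, sep = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(sprintf("s%02d", seq_len(2 * n_per)),
                              paste0("f", seq_len(p))))
  X[seq_len(n_per), 1] <- X[seq_len(n_per), 1] + sep
  list(X = X, y = factor(rep(c("pos", "neg"), each = n_per),
                         levels = c("pos", "neg")))
}

# small synthetic assay for fast end-to-end tests
small_sim <- function(seed = 1, ...) {
  generate_dataset(synthetic_config(
    n_grade1 = 5, n_grade2 = 6, n_grade3 = 8, n_antibodies = 40,
    n_informative = 8, n_below_lod = 2, seed = seed, ...))
}

write_long_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
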