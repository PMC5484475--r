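test_that("1-D two-point problems recover the analytic solution", {
  # x = -1 (neg), +1 (pos), C = 1: margin constraints satisfiable, w = 1,
  # b = 0, decisions d(+-1) = +-1
  X <- matrix(c(1, -1), ncol = 1, dimnames = list(c("p", "n"), "f1"))
  y <- factor(c("pos", "neg"), levels = c("pos", "neg"))
  fit <- train_linear_svm(X, y)
  expect_equal(unname(fit$w), 1, tolerance = 1e-4)
  expect_equal(fit$b, 0, tolerance = 1e-4)
  expect_equal(unname(predict(fit, X)), c(1, -1), tolerance = 1e-4)

  # x = +-0.1, C = 1: hinge active at the optimum, f'(w) = w - 0.2 = 0
  X2 <- matrix(c(0.1, -0.1), ncol = 1, dimnames = list(c("p", "n"), "f1"))
  fit2 <- train_linear_svm(X2, y)
  expect_equal(unname(fit2$w), 0.2, tolerance = 1e-4)
  expect_equal(fit2$b, 0, tolerance = 1e-4)
  expect_equal(unname(predict(fit2, matrix(0.1, 1, 1,
                                           dimnames = list("t", "f1")))),
               0.02, tolerance = 1e-4)
})

hinge_objective <- function(w, b, X, y01, C) {
  margins <- 1 - (2 * y01 - 1) * (X %*% w + b)
  0.5 * sum(w^2) + C * sum(pmax(margins, 0))
}

test_that("the returned weights are a local minimum of the hinge objective", {
  set.seed(12)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(rep(c("pos", "neg"), 10), levels = c("pos", "neg"))
  X[y == "pos", 1] <- X[y == "pos", 1] + 1.5
  fit <- train_linear_svm(X, y, C = 1)
  y01 <- as.numeric(y == "pos")
  f0 <- hinge_objective(fit$w, fit$b, X, y01, 1)
  for (eps in c(1e-3, -1e-3)) {
    for (j in 1:3) {
      w <- fit$w; w[j] <- w[j] + eps
      expect_gte(hinge_objective(w, fit$b, X, y01, 1), f0 - 1e-8)
    }
    expect_gte(hinge_objective(fit$w, fit$b + eps, X, y01, 1), f0 - 1e-8)
  }
})

test_that("label+feature flip symmetry gives a zero bias", {
  X <- matrix(c(-2, -1, 1, 2), ncol = 1, dimnames = list(NULL, "f"))
  y <- factor(c("neg", "neg", "pos", "pos"), levels = c("pos", "neg"))
  fit <- train_linear_svm(X, y)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_error(train_linear_svm(X, factor(rep("pos", 4))), "two classes")
})

test_that("LOOCV scores every sample from a model that excluded it", {
  sep <- make_separated(n_per = 10, sep = 10)
  cv <- loocv_decisions(sep$X, sep$y)
  expect_equal(nrow(cv), 20L)
  expect_true(all(sign(cv$decision[cv$label == "pos"]) == 1))
  expect_true(all(sign(cv$decision[cv$label == "neg"]) == -1))
  # order-free: permuting samples permutes decisions identically
  set.seed(6)
  perm <- sample(20)
  cv2 <- loocv_decisions(sep$X[perm, ], sep$y[perm])
  expect_equal(cv2$decision, cv$decision[perm], tolerance = 1e-5)
})

test_that("AUC equals the all-pairs oracle and is rank-invariant", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c("p", "p", "n", "n"), positive = "p"), 1)
  # positives (0.9, 0.4), negatives (0.6, 0.1): 3 of 4 pairs correct
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c("p", "p", "n", "n"),
                       positive = "p"), 0.75)
  set.seed(14)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    scores <- sample(round(rnorm(n), 1))  # rounding forces occasional ties
    labels <- sample(c("p", "n"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    auc <- roc_auc(scores, labels, positive = "p")
    expect_equal(auc, bf_auc(scores, labels, "p"), tolerance = 1e-12)
    # complement identity under label flip
    expect_equal(roc_auc(scores, labels, positive = "n"), 1 - auc,
                 tolerance = 1e-12)
    # invariance under a strictly increasing transform
    expect_equal(roc_auc(exp(scores / 2), labels, positive = "p"), auc,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("p", 3)), "both classes")
})

test_that("the K-L error matches hand-computed sigmoid cross-entropy", {
  expect_equal(kl_error(c(0, 0, 0), c(1, 0, 1)), log(2), tolerance = 1e-12)
  # d = (2, -2), t = (1, 0): p = sigmoid(2) = 0.8808, error = -ln(0.8808)
  expect_equal(kl_error(c(2, -2), c(1, 0)), -log(1 / (1 + exp(-2))),
               tolerance = 1e-12)
  expect_equal(kl_error(c(2, -2), c(1, 0)), 0.126928, tolerance = 1e-6)
  # limit: confident correct decisions drive the error to 0
  expect_lt(kl_error(c(50, -50), c(1, 0)), 1e-12)
  # strictly decreasing as a correct decision moves away from 0
  errs <- vapply(seq(0, 5, by = 0.5),
                 function(d) kl_error(c(d, -1), c(1, 0)), numeric(1))
  expect_true(all(diff(errs) < 0))
})
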