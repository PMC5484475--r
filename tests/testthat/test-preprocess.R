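test_that("replicate aggregation follows the 15% CV rule", {
  expect_equal(aggregate_replicates(c(100, 100, 100))[c("mean", "n_used")],
               list(mean = 100, n_used = 3L))
  # CV = sd(100,105,110)/105 = 5/105 ~ 4.76% <= 15%: keep all three
  agg <- aggregate_replicates(c(100, 105, 110))
  expect_equal(agg$mean, 105)
  expect_equal(agg$n_used, 3L)
  expect_equal(agg$cv, 5 / 105)
  # CV = sd(100,102,150)/mean ~ 24.1% > 15%: drop 150 (farthest from
  # median 102), keep mean(100, 102) = 101
  agg <- aggregate_replicates(c(100, 102, 150))
  expect_equal(agg$mean, 101)
  expect_equal(agg$n_used, 2L)
  expect_gt(agg$cv, 0.15)
  # duplicates are averaged as-is
  expect_equal(aggregate_replicates(c(90, 110))$mean, 100)
  expect_equal(aggregate_replicates(c(90, 110))$n_used, 2L)
  expect_error(aggregate_replicates(42), "at least 2")
  # non-positive mean: CV undefined, treated as exceeding the threshold
  agg <- aggregate_replicates(c(-10, -12, 40))
  expect_equal(agg$n_used, 2L)
  expect_equal(agg$mean, mean(c(-10, -12)))
})

test_that("aggregation agrees with the brute-force CV/median rule on a grid", {
  grid <- expand.grid(a = c(1, 50, 100), b = c(80, 100, 120),
                      c = c(90, 100, 160, 400))
  for (i in seq_len(nrow(grid))) {
    x <- as.numeric(grid[i, ])
    expect_equal(aggregate_replicates(x)$mean, bf_aggregate(x),
                 info = paste(x, collapse = ","))
  }
})

test_that("the LOD is mean(PBS) + 2 sd(PBS)", {
  expect_equal(compute_lod(c(10, 10, 10)), 10)
  expect_equal(compute_lod(c(8, 10, 12)), 14)
  expect_error(compute_lod(5), "PBS")
})

test_that("the LOD filter uses a strict >70% rule", {
  vals <- matrix(100, 10, 2, dimnames = list(sprintf("s%d", 1:10),
                                             c("keep", "drop")))
  vals[1:7, "keep"] <- 1    # below LOD in exactly 70%: retained
  vals[1:8, "drop"] <- 1    # below LOD in 80%: discarded
  res <- lod_filter(analyte_matrix(vals, "aggregated"), lod = 50)
  expect_identical(res$discarded, "drop")
  expect_identical(colnames(res$matrix), "keep")
})

test_that("PCA outlier flagging spots a wildly rescaled sample", {
  set.seed(5)
  vals <- matrix(2^rnorm(21 * 30, 10, 0.5), 21, 30,
                 dimnames = list(sprintf("s%02d", 1:21), paste0("a", 1:30)))
  vals["s21", ] <- vals["s21", ] * 100
  flags <- flag_outliers(analyte_matrix(vals, "aggregated"))
  expect_true("s21" %in% flags)
  expect_lte(length(flags), 2L)

  const <- matrix(7, 5, 4, dimnames = list(paste0("s", 1:5), paste0("a", 1:4)))
  expect_warning(flags <- flag_outliers(analyte_matrix(const, "aggregated")),
                 "constant")
  expect_length(flags, 0L)
})

test_that("reference-analyte selection rounds half-up and breaks ties by id", {
  set.seed(2)
  vals <- matrix(2^rnorm(8 * 20, 10, 1), 8, 20,
                 dimnames = list(paste0("s", 1:8), sprintf("a%02d", 1:20)))
  expect_length(select_reference_analytes(analyte_matrix(vals, "aggregated"),
                                          0.15), 3L)
  expect_length(select_reference_analytes(
    analyte_matrix(vals[, 1:10], "aggregated"), 0.15), 2L)
  expect_error(select_reference_analytes(analyte_matrix(vals, "aggregated"),
                                         1.2), "fraction")
  # two analytes with identical (lowest) CV; identifier order decides
  tied <- cbind(b_ref = c(10, 11, 10, 11), a_ref = c(10, 11, 10, 11),
                noisy = c(1, 100, 1, 100))
  rownames(tied) <- paste0("s", 1:4)
  sel <- select_reference_analytes(analyte_matrix(tied, "aggregated"),
                                   fraction = 1 / 3)
  expect_identical(sel, "a_ref")
})

test_that("semiglobal normalization equalizes reference sums to mu", {
  vals <- matrix(c(60, 180, 40, 120, 10, 30), 2, 3,
                 dimnames = list(c("s1", "s2"), c("r1", "r2", "x")))
  res <- semiglobal_normalize(analyte_matrix(vals, "aggregated"),
                              reference = c("r1", "r2"))
  # reference sums 100 and 300: mu = 200, N = (0.5, 1.5)
  expect_equal(res$norm$mu, 200)
  expect_equal(unname(res$norm$N), c(0.5, 1.5))
  expect_equal(unname(rowSums(unclass(res$matrix)[, c("r1", "r2")])),
               c(200, 200))
  expect_equal(unname(unclass(res$matrix)[, "x"]), c(20, 20))

  same <- matrix(5, 3, 4, dimnames = list(paste0("s", 1:3), paste0("a", 1:4)))
  res2 <- semiglobal_normalize(analyte_matrix(same, "aggregated"),
                               paste0("a", 1:2))
  expect_equal(unname(res2$norm$N), rep(1, 3))
  expect_equal(unclass(res2$matrix), same, ignore_attr = TRUE)

  neg <- vals; neg[1, 1:2] <- c(-10, 5)
  expect_error(semiglobal_normalize(analyte_matrix(neg, "aggregated"),
                                    c("r1", "r2")), "non-positive")
})

test_that("normalization identities hold on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    vals <- matrix(2^rnorm(12 * 25, 9, 1.2), 12, 25,
                   dimnames = list(sprintf("s%02d", 1:12), paste0("a", 1:25)))
    m <- analyte_matrix(vals, "aggregated")
    ref <- select_reference_analytes(m, 0.2)
    res <- semiglobal_normalize(m, ref)
    S_after <- rowSums(unclass(res$matrix)[, ref])
    expect_lt(max(abs(S_after - res$norm$mu)), 1e-9 * res$norm$mu)
    expect_equal(mean(res$norm$N), 1, tolerance = 1e-12)
    # scale equivariance: rescaling one sample by c > 0 is absorbed exactly
    # by its factor N_i; only the common rescale of mu remains, so the
    # normalized matrices agree after adjusting for mu
    scaled <- vals
    scaled[3, ] <- scaled[3, ] * 17
    res2 <- semiglobal_normalize(analyte_matrix(scaled, "aggregated"), ref)
    expect_equal(unclass(res2$matrix) / res2$norm$mu,
                 unclass(res$matrix) / res$norm$mu, tolerance = 1e-9)
    # in particular the scaled sample's profile shape is untouched
    expect_equal(unclass(res2$matrix)[3, ] / unclass(res2$matrix)[3, 1],
                 unclass(res$matrix)[3, ] / unclass(res$matrix)[3, 1],
                 tolerance = 1e-9)
  }
})

test_that("log2 transform floors non-positive cells and counts them", {
  vals <- matrix(c(8, 1, -5, 2), 2, 2,
                 dimnames = list(c("s1", "s2"), c("a", "b")))
  res <- log2_transform(analyte_matrix(vals, "normalized"), floor = 1)
  expect_equal(unclass(res$matrix), matrix(c(3, 0, 0, 1), 2, 2),
               ignore_attr = TRUE)
  expect_equal(res$n_floored, 1L)
  expect_identical(stage(res$matrix), "log2")
})

test_that("end-to-end preprocessing discards planted analytes and tracks QC", {
  sim <- small_sim(seed = 3)
  pp <- preprocess(sim$raw)
  expect_setequal(pp$discarded, sim$truth$below_lod)
  expect_equal(ncol(pp$log2), 38L)
  expect_length(pp$norm$reference_analytes, 6L)  # 0.15 * 38 rounds to 6
  expect_equal(pp$qc$frac_from_3 + pp$qc$frac_from_2 + pp$qc$frac_from_1, 1)
  expect_identical(stage(pp$log2), "log2")
  # dropping samples is explicit, never automatic
  expect_identical(rownames(pp$log2), sim$raw$samples)
  pp2 <- preprocess(sim$raw, drop_samples = "S01")
  expect_false("S01" %in% rownames(pp2$log2))
  expect_error(preprocess(sim$raw, drop_samples = "nope"), "drop_samples")
})
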