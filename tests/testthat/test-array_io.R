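long_fixture <- function() {
  expand <- expand.grid(replicate = 1:3,
                        antibody = c("IL-6 (2)", "MUC1 (3)", "CD40 (1)"),
                        sample = c("T01", "T02"), stringsAsFactors = FALSE)
  expand$intensity <- seq_len(nrow(expand)) * 10
  expand[c("sample", "antibody", "replicate", "intensity")]
}

test_that("long tables group replicates per (sample, antibody)", {
  df <- long_fixture()
  raw <- read_raw_table(write_long_tsv(df), layout = "long")
  expect_setequal(raw$samples, c("T01", "T02"))
  expect_setequal(raw$antibodies, c("IL-6 (2)", "MUC1 (3)", "CD40 (1)"))
  expect_equal(dim(raw$intensities), c(2L, 3L, 3L))
  expect_false(anyNA(raw$intensities))
  expect_equal(sort(raw$intensities["T01", "IL-6 (2)", ]),
               sort(df$intensity[df$sample == "T01" &
                                   df$antibody == "IL-6 (2)"]))
})

test_that("a missing replicate row leaves a duplicate pair, not an error", {
  df <- long_fixture()[-2L, ]
  raw <- read_raw_table(write_long_tsv(df), layout = "long")
  reps <- raw$intensities["T01", df$antibody[1L], ]
  expect_equal(sum(!is.na(reps)), 2L)
})

test_that("PBS rows are routed to the negative-control pool", {
  df <- rbind(long_fixture(),
              data.frame(sample = rep(c("T01", "T02"), each = 2),
                         antibody = "PBS", replicate = rep(1:2, 2),
                         intensity = c(9, 11, 10, 12)))
  raw <- read_raw_table(write_long_tsv(df), layout = "long")
  expect_false("PBS" %in% raw$antibodies)
  expect_equal(raw$pbs$T01, c(9, 11))
  expect_equal(raw$pbs$T02, c(10, 12))
})

test_that("corrupt tables fail loudly with the offending record", {
  df <- long_fixture()
  dup <- rbind(df, df[1L, ])
  expect_error(read_raw_table(write_long_tsv(dup)), "duplicate record")
  bad <- df
  bad$intensity <- as.character(bad$intensity)
  bad$intensity[5L] <- "n/a"
  expect_error(read_raw_table(write_long_tsv(bad)), "non-numeric")
  expect_error(read_raw_table(write_long_tsv(bad)), bad$antibody[5L],
               fixed = TRUE)
})

test_that("long and wide layouts produce identical datasets", {
  df <- long_fixture()
  wide <- reshape(df, idvar = c("antibody", "replicate"),
                  timevar = "sample", direction = "wide")
  names(wide) <- sub("^intensity\\.", "", names(wide))
  wide <- wide[c("antibody", "replicate", "T01", "T02")]
  a <- read_raw_table(write_long_tsv(df), layout = "long")
  b <- read_raw_table(write_long_tsv(wide), layout = "wide")
  expect_equal(a$intensities[a$samples, a$antibodies, ],
               b$intensities[a$samples, a$antibodies, ])
})

test_that("raw datasets round-trip through the canonical long TSV", {
  sim <- small_sim()
  path <- tempfile(fileext = ".tsv")
  write_raw_table(sim$raw, path)
  back <- read_raw_table(path, layout = "long")
  expect_equal(back$intensities[sim$raw$samples, sim$raw$antibodies, ],
               sim$raw$intensities, tolerance = 1e-12)
  expect_equal(back$pbs[names(sim$raw$pbs)], sim$raw$pbs, tolerance = 1e-12)
})

test_that("matrices round-trip with their stage tag", {
  m <- analyte_matrix(matrix(c(pi, exp(1), 1/3, 2/7, 1e6, -4.25),
                             2, 3, dimnames = list(c("a", "b"),
                                                   c("x", "y", "z"))),
                      stage = "normalized")
  path <- tempfile(fileext = ".tsv")
  write_matrix(m, path)
  back <- read_matrix(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(stage(back), "normalized")

  empty <- analyte_matrix(matrix(numeric(0), 2, 0,
                                 dimnames = list(c("a", "b"), NULL)),
                          stage = "log2")
  write_matrix(empty, path)
  expect_identical(readLines(path)[1:2], c("# stage: log2", "sample"))
})

test_that("invalid datasets and annotations are rejected", {
  arr <- array(NA_real_, c(1, 2, 2),
               dimnames = list("s1", c("a", "b"), NULL))
  arr[1, 1, 1] <- 5
  expect_error(raw_dataset(arr), "no recorded replicate")
  expect_error(sample_annotation(c("s1", "s1"), c(1, 2)), "duplicate")
  expect_error(sample_annotation("s1", 4), "grade")
  ann <- sample_annotation(c("s1", "s2"), c(1, 3))
  expect_error(validate_annotation(ann, c("s1", "s3")), "missing samples")
  expect_true(validate_annotation(ann, c("s1", "s2")))
})
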