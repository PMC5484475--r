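#' Raw antibody microarray dataset
#'
#' Container for background-subtracted spot intensities of an antibody
#' microarray experiment: up to three replicate spots per (sample, antibody)
#' pair, plus the PBS negative-control spot intensities of each sample.
#' Background subtraction means intensities may be negative.
#'
#' @param intensities 3-dimensional numeric array, samples x antibodies x
#'   replicates, with `NA` marking absent replicates. The first two dimensions
#'   must carry unique dimnames (sample and antibody identifiers).
#' @param pbs named list mapping sample identifiers to numeric vectors of PBS
#'   negative-control spot intensities; may be empty.
#' @return An object of class `raw_dataset` with fields `samples`,
#'   `antibodies`, `intensities` and `pbs`.
#' @seealso [read_raw_table()], [aggregate_dataset()]
#' @export
raw_dataset <- function(intensities, pbs = list()) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L)
  dn <- dimnames(intensities)
  if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]]))
    stop("intensities must have sample and antibody dimnames")
  if (anyDuplicated(dn[[1L]])) stop("duplicate sample identifiers")
  if (anyDuplicated(dn[[2L]])) stop("duplicate antibody identifiers")
  n_rep <- apply(!is.na(intensities), c(1L, 2L), sum)
  if (any(n_rep < 1L)) {
    bad <- which(n_rep < 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf("no recorded replicate for sample '%s', antibody '%s'",
                 dn[[1L]][bad[1L]], dn[[2L]][bad[2L]]))
  }
  if (length(pbs) && !all(names(pbs) %in% dn[[1L]]))
    stop("pbs entries refer to unknown samples")
  structure(list(samples = dn[[1L]], antibodies = dn[[2L]],
                 intensities = intensities, pbs = pbs),
            class = "raw_dataset")
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat(sprintf("raw_dataset: %d samples x %d antibodies, up to %d replicate spots\n",
              length(x$samples), length(x$antibodies), dim(x$intensities)[3L]))
  n_pbs <- sum(lengths(x$pbs))
  cat(sprintf("  PBS negative-control spots: %d (in %d samples)\n",
              n_pbs, length(x$pbs)))
  invisible(x)
}

#' Convert a raw dataset to a long-format data frame
#'
#' @param x a [raw_dataset()].
#' @param ... unused.
#' @return data.frame with columns `sample`, `antibody`, `replicate`,
#'   `intensity`; PBS control spots appear with antibody label `"PBS"` and a
#'   running replicate index.
#' @export
as.data.frame.raw_dataset <- function(x, ...) {
  idx <- which(!is.na(x$intensities), arr.ind = TRUE)
  df <- data.frame(
    sample    = x$samples[idx[, 1L]],
    antibody  = x$antibodies[idx[, 2L]],
    replicate = idx[, 3L],
    intensity = x$intensities[idx],
    stringsAsFactors = FALSE)
  if (length(x$pbs)) {
    pbs <- data.frame(
      sample    = rep(names(x$pbs), lengths(x$pbs)),
      antibody  = "PBS",
      replicate = unlist(lapply(lengths(x$pbs), seq_len), use.names = FALSE),
      intensity = unlist(x$pbs, use.names = FALSE),
      stringsAsFactors = FALSE)
    df <- rbind(df, pbs)
  }
  df[order(match(df$sample, x$samples), df$antibody, df$replicate), ,
     drop = FALSE]
}

#' Sample annotation table
#'
#' Validates a clinical annotation table: one row per sample with its
#' Nottingham histological grade (1, 2 or 3) and optional covariates
#' (receptor status, node status, tumor size, age, ...).
#'
#' @param sample character vector of unique sample identifiers.
#' @param grade integer vector of histological grades, each 1, 2 or 3.
#' @param ... optional equal-length covariate vectors (e.g. `ER`, `PgR`).
#' @return data.frame with class `sample_annotation` prepended.
#' @export
sample_annotation <- function(sample, grade, ...) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) stop("duplicate sample identifiers in annotation")
  grade <- as.integer(grade)
  if (length(grade) != length(sample) || !all(grade %in% 1:3))
    stop("grade must be one of 1, 2, 3 for every sample")
  ann <- data.frame(sample = sample, grade = grade, ...,
                    stringsAsFactors = FALSE)
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

#' Check that an annotation covers a dataset
#' @param annotation a [sample_annotation()].
#' @param samples character vector of sample identifiers to be covered.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_annotation <- function(annotation, samples) {
  if (!all(c("sample", "grade") %in% names(annotation)))
    stop("SampleAnnotation invalid: needs 'sample' and 'grade' columns")
  missing <- setdiff(samples, annotation$sample)
  if (length(missing))
    stop("SampleAnnotation missing samples: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Samples-by-analytes matrix with a processing-stage tag
#'
#' @param values numeric matrix, samples in rows, analytes in columns, with
#'   dimnames.
#' @param stage one of `"aggregated"` (replicate means, linear scale),
#'   `"normalized"` (after semiglobal normalization, linear scale) or
#'   `"log2"`.
#' @return the matrix with class `analyte_matrix` and attribute `stage`.
#' @export
analyte_matrix <- function(values, stage = c("aggregated", "normalized", "log2")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("analyte matrix needs sample rownames and analyte colnames")
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (anyNA(values)) stop("analyte matrix must have no missing cells")
  structure(values, stage = stage, class = c("analyte_matrix", class(values)))
}

#' @export
#' @rdname analyte_matrix
#' @param x an `analyte_matrix`.
stage <- function(x) attr(x, "stage")

#' @export
print.analyte_matrix <- function(x, ...) {
  cat(sprintf("analyte_matrix [%s]: %d samples x %d analytes\n",
              stage(x), nrow(x), ncol(x)))
  invisible(x)
}

# retag a plain matrix produced by subsetting/arithmetic
retag <- function(values, stage) {
  structure(as.matrix(values), stage = stage,
            class = c("analyte_matrix", "matrix", "array"))
}

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a raw intensity table
#'
#' Reads replicate-level spot intensities from a delimited text file or an
#' XLSX workbook into a [raw_dataset()]. Two layouts are accepted:
#' \describe{
#'   \item{long}{columns `sample`, `antibody`, `replicate`, `intensity`.}
#'   \item{wide}{an `antibody` column (plus optional `replicate` column) and
#'     one column per sample. Without a `replicate` column each row is taken
#'     as a single recorded replicate, accommodating tables that list one
#'     aggregate signal per antibody and sample.}
#' }
#' Rows whose antibody label matches `pbs_label` are routed to the PBS
#' negative-control pool and do not appear among the antibodies.
#'
#' @param path file to read; `.xlsx` is imported via readxl, anything else as
#'   delimited text (TAB for `.tsv`/`.txt`, comma for `.csv`).
#' @param layout `"long"` or `"wide"`.
#' @param pbs_label regular expression identifying negative-control rows
#'   (default matches the exact label `"PBS"`).
#' @return a [raw_dataset()].
#' @export
read_raw_table <- function(path, layout = c("long", "wide"),
                           pbs_label = "^PBS$") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the readxl package")
    df <- as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, sep = guess_sep(path), header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#")
  }
  if (layout == "wide") df <- wide_to_long(df)
  need <- c("sample", "antibody", "intensity")
  if (!all(need %in% names(df)))
    stop("long layout needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$replicate)) df$replicate <- 1L
  long_to_raw(df, pbs_label)
}

wide_to_long <- function(df) {
  if (!"antibody" %in% names(df))
    stop("wide layout needs an 'antibody' column")
  id_cols <- intersect(c("antibody", "replicate"), names(df))
  sample_cols <- setdiff(names(df), id_cols)
  if (!length(sample_cols)) stop("wide layout has no sample columns")
  long <- data.frame(
    sample    = rep(sample_cols, each = nrow(df)),
    antibody  = rep(df$antibody, times = length(sample_cols)),
    replicate = if ("replicate" %in% id_cols)
                  rep(df$replicate, times = length(sample_cols)) else 1L,
    intensity = unlist(df[sample_cols], use.names = FALSE),
    stringsAsFactors = FALSE)
  long
}

long_to_raw <- function(df, pbs_label) {
  num <- suppressWarnings(as.numeric(df$intensity))
  if (anyNA(num) && !all(is.na(df$intensity[is.na(num)]))) {
    bad <- which(is.na(num) & !is.na(df$intensity))[1L]
    stop(sprintf("non-numeric intensity '%s' at sample '%s', antibody '%s', replicate %s",
                 df$intensity[bad], df$sample[bad], df$antibody[bad],
                 df$replicate[bad]))
  }
  df$intensity <- num
  df <- df[!is.na(df$intensity), , drop = FALSE]
  key <- paste(df$sample, df$antibody, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- df[duplicated(key), ][1L, ]
    stop(sprintf("duplicate record for sample '%s', antibody '%s', replicate %s",
                 bad$sample, bad$antibody, bad$replicate))
  }
  is_pbs <- grepl(pbs_label, df$antibody)
  pbs_df <- df[is_pbs, , drop = FALSE]
  df <- df[!is_pbs, , drop = FALSE]
  if (!nrow(df)) stop("no antibody rows left after routing PBS controls")
  samples <- unique(df$sample)
  antibodies <- unique(df$antibody)
  # replicate indices need not be 1..k; rank them within each pair
  ord <- order(match(df$sample, samples), match(df$antibody, antibodies),
               df$replicate)
  df <- df[ord, , drop = FALSE]
  pair <- paste(df$sample, df$antibody, sep = "\r")
  rep_idx <- stats::ave(seq_along(pair), pair, FUN = seq_along)
  n_rep <- max(rep_idx)
  arr <- array(NA_real_, dim = c(length(samples), length(antibodies), n_rep),
               dimnames = list(samples, antibodies, NULL))
  arr[cbind(match(df$sample, samples), match(df$antibody, antibodies),
            rep_idx)] <- df$intensity
  pbs <- if (nrow(pbs_df)) split(pbs_df$intensity, pbs_df$sample) else list()
  raw_dataset(arr, pbs = pbs[order(match(names(pbs), samples))])
}

#' Write a raw dataset as canonical long-format TSV
#'
#' @param x a [raw_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raw_table <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read an analyte matrix as TSV
#'
#' The processing stage is persisted in a `# stage:` comment on the first
#' line, so `read_matrix(write_matrix(x))` restores values and stage.
#'
#' @param matrix an [analyte_matrix()].
#' @param path file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns an
#'   [analyte_matrix()].
#' @export
write_matrix <- function(matrix, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s", stage(matrix)), con)
  df <- data.frame(sample = rownames(matrix),
                   unclass(matrix)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample", colnames(matrix))
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  stage <- sub("^# stage:\\s*", "", first)
  if (identical(stage, first)) stage <- "aggregated"
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$sample
  analyte_matrix(m, stage)
}
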