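#' Run the full grading pipeline from a configuration
#'
#' Orchestrates an end-to-end run: obtain the raw dataset (from files or the
#' synthetic generator), preprocess it, and execute the requested analyses,
#' writing every result plus a manifest (parameters, seed, input checksums)
#' to `outdir`. Given the same configuration and seed the run is
#' deterministic: all stochastic stages consume only seeds derived from
#' `config$seed`.
#'
#' @param config a named list (or path to a YAML file parsed with the yaml
#'   package) with entries:
#'   \describe{
#'     \item{input}{either `list(raw = <path>, layout = "long"|"wide",
#'       annotation = <path>)` or `list(synthetic = <list of
#'       [synthetic_config()] arguments>)`; exactly one source.}
#'     \item{preprocess}{optional list of [preprocess()] arguments.}
#'     \item{analysis}{character subset of `"loocv_auc"`, `"diffexpr"`,
#'       `"model1"`, `"model2"`, `"model3"` (default: all).}
#'     \item{seed}{integer master seed (default 1).}
#'   }
#' @param outdir output directory, created if absent.
#' @return invisibly, a list with the preprocessed data and every analysis
#'   result that was produced.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  analyses <- config$analysis %||%
    c("loocv_auc", "diffexpr", "model1", "model2", "model3")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  inp <- config$input
  if (is.null(inp) || sum(c(!is.null(inp$raw), !is.null(inp$synthetic))) != 1L)
    stop("config$input must name exactly one source: raw files or synthetic")
  checksums <- list()
  if (!is.null(inp$raw)) {
    if (is.null(inp$annotation))
      stop("SampleAnnotation missing: config$input$annotation is required ",
           "for file input")
    raw <- read_raw_table(inp$raw, layout = inp$layout %||% "long")
    ann_df <- utils::read.delim(inp$annotation, sep = guess_sep(inp$annotation),
                                stringsAsFactors = FALSE)
    if (!all(c("sample", "grade") %in% names(ann_df)))
      stop("SampleAnnotation invalid: needs 'sample' and 'grade' columns in ",
           inp$annotation)
    extra <- ann_df[setdiff(names(ann_df), c("sample", "grade"))]
    annotation <- do.call(sample_annotation,
                          c(list(sample = ann_df$sample, grade = ann_df$grade),
                            extra))
    truth <- NULL
    checksums <- as.list(tools::md5sum(c(inp$raw, inp$annotation)))
  } else {
    sim_args <- inp$synthetic
    if (isTRUE(sim_args) || is.null(sim_args)) sim_args <- list()
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    sim <- generate_dataset(do.call(synthetic_config, sim_args))
    raw <- sim$raw
    annotation <- sim$annotation
    truth <- sim$truth
  }
  validate_annotation(annotation, raw$samples)

  pp <- do.call(preprocess, c(list(raw = raw), config$preprocess))
  ann <- annotation[match(rownames(pp$log2), annotation$sample), ]
  grades <- ann$grade
  X <- unclass(pp$log2)

  write_matrix(pp$log2, file.path(outdir, "normalized_log2.tsv"))
  qc_out <- pp$qc
  qc_out$replicate_cv <- NULL
  qc_out$n_used <- NULL
  jsonlite::write_json(unclass(qc_out), file.path(outdir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  results <- list(preprocess = pp, annotation = annotation, truth = truth)
  pairs <- list(c(1L, 3L), c(1L, 2L), c(2L, 3L))

  if ("loocv_auc" %in% analyses) {
    auc <- lapply(pairs, function(pr) {
      idx <- grades %in% pr
      y <- factor(paste0("grade", grades[idx]),
                  levels = paste0("grade", pr))
      cv <- loocv_decisions(X[idx, , drop = FALSE], y)
      list(comparison = sprintf("grade%d_vs_grade%d", pr[1L], pr[2L]),
           auc = roc_auc(cv$decision, cv$label,
                         positive = paste0("grade", pr[1L])),
           decisions = cv)
    })
    names(auc) <- vapply(auc, `[[`, "", "comparison")
    results$loocv_auc <- auc
    auc_df <- data.frame(comparison = names(auc),
                         auc = vapply(auc, `[[`, 0, "auc"))
    utils::write.table(auc_df, file.path(outdir, "loocv_auc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("diffexpr" %in% analyses) {
    de <- lapply(pairs, function(pr) {
      idx <- grades %in% pr
      diff_expr(retag(X[idx, , drop = FALSE], "log2"),
                factor(grades[idx], levels = pr))
    })
    names(de) <- vapply(pairs, function(pr)
      sprintf("grade%d_vs_grade%d", pr[1L], pr[2L]), "")
    results$diffexpr <- de
    for (nm in names(de))
      write_diff_expr(de[[nm]], file.path(outdir, paste0("diffexpr_", nm, ".tsv")))
  }

  anchors <- grades %in% c(1L, 3L)
  y_anchor <- factor(ifelse(grades[anchors] == 1L, "grade1", "grade3"),
                     levels = c("grade1", "grade3"))
  g2_samples <- rownames(X)[grades == 2L]

  if ("model1" %in% analyses) {
    trace <- backward_eliminate(X[anchors, , drop = FALSE], y_anchor,
                                panel_size = 20, kl_every = 10,
                                positive = "grade1")
    m1 <- frozen_classify(X[anchors, , drop = FALSE], y_anchor,
                          trace$condensed_signature,
                          X[grades == 2L, , drop = FALSE],
                          grey = 0.5, positive = "grade1")
    m1_train <- frozen_classify(X[anchors, , drop = FALSE], y_anchor,
                                trace$condensed_signature,
                                X[anchors, , drop = FALSE],
                                grey = 0.5, positive = "grade1")
    results$model1 <- list(trace = trace, grade2 = m1, anchors = m1_train)
    utils::write.table(m1$calls, file.path(outdir, "model1_grade2.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (any(c("model2", "model3") %in% analyses)) {
    m2 <- bootstrap_reclassify(X, grades, n_iter = config$n_iter %||% 100,
                               signature_mode = "per_iteration",
                               panel_size = 20, tally_cut = 70, seed = seed)
    results$model2 <- m2
    utils::write.table(m2$calls, file.path(outdir, "model2_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if ("model3" %in% analyses) {
      consensus <- consensus_signature(
        lapply(m2$log, `[[`, "signature"), k = 20)
      m3 <- bootstrap_reclassify(X, grades, n_iter = config$n_iter %||% 100,
                                 signature_mode = consensus$panel,
                                 tally_cut = 70, seed = seed + 1)
      results$consensus <- consensus
      results$model3 <- m3
      utils::write.table(m3$calls, file.path(outdir, "model3_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(consensus$panel, file.path(outdir, "consensus_panel.txt"))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("abgrade")),
    seed = seed, analyses = analyses,
    preprocess_params = results$preprocess$params,
    input = if (!is.null(inp$raw)) list(files = checksums)
            else list(synthetic = unclass(
              results$truth$config %||% synthetic_config(seed = seed))),
    outputs = as.list(tools::md5sum(
      list.files(outdir, full.names = TRUE, pattern = "\\.(tsv|txt)$"))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
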