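#' Configuration for the synthetic antibody-array generator
#'
#' Defaults emulate the study conditions of the assay the pipeline targets:
#' 9/17/24 samples of histological grade 1/2/3, 293 antibodies spotted in
#' triplicate, multiplicative replicate noise with a 7% CV, per-array
#' log-normal scale factors, PBS negative-control spots, a small set of
#' grade-discriminating analytes (mostly up in grade 3, a few up in
#' grade 1), a few analytes planted below the limit of detection, and a
#' grade 2 cohort mixing grade-1-like, grade-3-like and intermediate
#' profiles.
#'
#' @param n_grade1,n_grade2,n_grade3 samples per grade (9, 17, 24).
#' @param n_antibodies total antibody clones (293).
#' @param n_replicates replicate spots per antibody (3).
#' @param n_informative grade-discriminating analytes (20).
#' @param delta log2 mean shift of informative analytes between grade 1 and
#'   grade 3 (1.5).
#' @param frac_down fraction of informative analytes higher in grade 1
#'   (0.1; the Mucin-1-like minority direction).
#' @param replicate_cv coefficient of variation of replicate spots (0.07).
#' @param array_scale_sd SD of the per-sample log-normal scale factor (0.2).
#' @param pbs_mean,pbs_sd mean and SD of PBS control-spot intensities
#'   (30, 10), giving a nominal LOD of 50.
#' @param n_pbs_spots PBS spots per sample (8).
#' @param n_below_lod analytes forced below the LOD in >70% of samples (3).
#' @param grade2_weights mixture weights (grade-1-like, grade-3-like,
#'   intermediate) for grade 2 tumors, summing to 1 (0.2, 0.6, 0.2).
#' @param seed generator seed.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_grade1 = 9, n_grade2 = 17, n_grade3 = 24,
                             n_antibodies = 293, n_replicates = 3,
                             n_informative = 20, delta = 1.5,
                             frac_down = 0.1, replicate_cv = 0.07,
                             array_scale_sd = 0.2, pbs_mean = 30,
                             pbs_sd = 10, n_pbs_spots = 8, n_below_lod = 3,
                             grade2_weights = c(0.2, 0.6, 0.2), seed = 1) {
  cfg <- list(n_grade1 = n_grade1, n_grade2 = n_grade2, n_grade3 = n_grade3,
              n_antibodies = n_antibodies, n_replicates = n_replicates,
              n_informative = n_informative, delta = delta,
              frac_down = frac_down, replicate_cv = replicate_cv,
              array_scale_sd = array_scale_sd, pbs_mean = pbs_mean,
              pbs_sd = pbs_sd, n_pbs_spots = n_pbs_spots,
              n_below_lod = n_below_lod, grade2_weights = grade2_weights,
              seed = seed)
  counts <- c(n_grade1, n_grade2, n_grade3, n_antibodies, n_replicates,
              n_pbs_spots)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("sample/antibody/replicate counts must be positive integers")
  if (n_grade1 < 2 || n_grade3 < 2)
    stop("anchor grades need >= 2 samples")
  if (n_informative + n_below_lod > n_antibodies)
    stop("informative + below-LOD analytes exceed antibody count")
  if (abs(sum(grade2_weights) - 1) > 1e-8 || length(grade2_weights) != 3L ||
      any(grade2_weights < 0))
    stop("grade2_weights must be 3 nonnegative values summing to 1")
  if (any(c(replicate_cv, array_scale_sd, pbs_sd) < 0))
    stop("noise parameters must be >= 0")
  if (delta < 0 || frac_down < 0 || frac_down > 1)
    stop("delta must be >= 0 and frac_down in [0, 1]")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic raw antibody-array dataset with ground truth
#'
#' Per analyte a, a baseline log2 mean mu_a ~ Normal(10, 1.5) (truncated
#' below at 7, i.e. about 2.5 log2 units above the nominal LOD) and a
#' biological SD sigma_a ~ Uniform(0.2, 0.6) are drawn. Sample i of grade g
#' expresses analyte a at log2 level mu_a + direction_a * delta * g_effect +
#' Normal(0, sigma_a), with g_effect 0 for grade 1, 1 for grade 3, and for
#' grade 2 the value 0, 1 or 0.5 drawn from the configured mixture. Linear
#' intensities are 2^level times the sample's log-normal array scale factor
#' times multiplicative log-normal replicate noise with the configured CV.
#' The below-LOD analytes are overwritten with intensities well under the
#' nominal LOD (pbs_mean + 2 pbs_sd) in more than 70% of samples. PBS spots
#' are Normal(pbs_mean, pbs_sd) truncated at 0.
#'
#' @param config a [synthetic_config()].
#' @return list with `raw` (a [raw_dataset()]), `annotation` (a
#'   [sample_annotation()]) and `truth`, a `synthetic_truth` object holding
#'   the true grades and grade 2 mixture components, informative analyte
#'   identifiers and directions, planted below-LOD analytes, per-sample
#'   scale factors, and the per-analyte baselines.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  na <- config$n_antibodies
  ns <- config$n_grade1 + config$n_grade2 + config$n_grade3
  antibodies <- sprintf("Ab%03d", seq_len(na))
  samples <- sprintf("S%02d", seq_len(ns))
  grade <- rep(1:3, c(config$n_grade1, config$n_grade2, config$n_grade3))

  # baselines truncated well above the nominal LOD so that only the planted
  # below-LOD analytes sit near the detection limit
  mu <- pmax(stats::rnorm(na, 10, 1.5), 7)
  sigma <- stats::runif(na, 0.2, 0.6)
  informative <- sample(antibodies, config$n_informative)
  n_down <- round(config$frac_down * config$n_informative)
  direction <- stats::setNames(rep(0, na), antibodies)
  direction[informative] <- 1
  if (n_down > 0) direction[sample(informative, n_down)] <- -1
  below_lod <- sample(setdiff(antibodies, informative), config$n_below_lod)

  # grade-2 mixture component: effect 0 (grade-1-like), 1 (grade-3-like), 0.5
  g_effect <- numeric(ns)
  component <- rep(NA_character_, ns)
  g_effect[grade == 3] <- 1
  i2 <- which(grade == 2)
  comp <- sample(c("grade1_like", "grade3_like", "intermediate"), length(i2),
                 replace = TRUE, prob = config$grade2_weights)
  component[i2] <- comp
  g_effect[i2] <- c(grade1_like = 0, grade3_like = 1, intermediate = 0.5)[comp]

  scale_i <- exp(stats::rnorm(ns, 0, config$array_scale_sd))
  sdlog_rep <- sqrt(log(1 + config$replicate_cv^2))
  lod_nominal <- config$pbs_mean + 2 * config$pbs_sd

  level <- matrix(mu, ns, na, byrow = TRUE) +
    outer(g_effect, direction * config$delta) +
    matrix(stats::rnorm(ns * na, 0, rep(sigma, each = ns)), ns, na)
  linear <- 2^level * scale_i

  # plant the below-LOD analytes: faint signal in >70% of the samples
  n_low <- ceiling(0.8 * ns)
  for (ab in below_lod) {
    j <- match(ab, antibodies)
    low_samples <- sample(ns, n_low)
    linear[low_samples, j] <- stats::runif(n_low, 0.1, 0.5) * lod_nominal
    linear[-low_samples, j] <- stats::runif(ns - n_low, 1.5, 3) * lod_nominal
  }

  reps <- array(NA_real_, dim = c(ns, na, config$n_replicates),
                dimnames = list(samples, antibodies, NULL))
  for (r in seq_len(config$n_replicates)) {
    noise <- matrix(stats::rlnorm(ns * na, -sdlog_rep^2 / 2, sdlog_rep), ns, na)
    reps[, , r] <- linear * noise
  }
  pbs <- lapply(seq_len(ns), function(i)
    pmax(stats::rnorm(config$n_pbs_spots, config$pbs_mean, config$pbs_sd), 0))
  names(pbs) <- samples

  truth <- structure(list(
    grade = stats::setNames(grade, samples),
    component = stats::setNames(component, samples),
    informative = sort(informative),
    direction = direction[informative],
    below_lod = sort(below_lod),
    scale = stats::setNames(scale_i, samples),
    baseline_mean = stats::setNames(mu, antibodies),
    baseline_sd = stats::setNames(sigma, antibodies),
    config = config), class = "synthetic_truth")

  list(raw = raw_dataset(reps, pbs = pbs),
       annotation = sample_annotation(samples, grade),
       truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic truth: %d samples, %d informative analytes (%d up in grade 1), %d below LOD\n",
              length(x$grade), length(x$informative),
              sum(x$direction < 0), length(x$below_lod)))
  invisible(x)
}

#' Overlap of a signature with the informative truth set
#'
#' @param signature character vector of analyte identifiers.
#' @param truth a `synthetic_truth` object (or a character vector of
#'   informative analytes).
#' @return |signature intersect informative| / min(|signature|, |informative|);
#'   0 when either set is empty.
#' @export
truth_overlap <- function(signature, truth) {
  informative <- if (inherits(truth, "synthetic_truth")) truth$informative
                 else as.character(truth)
  if (!length(signature) || !length(informative)) return(0)
  length(intersect(signature, informative)) /
    min(length(signature), length(informative))
}
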