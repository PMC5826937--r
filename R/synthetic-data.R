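#' Configuration for the synthetic storage experiment
#'
#' Describes a pooled-plasma storage time course: aliquots frozen at
#' regular intervals (default 11 time points, day 0 to 30 in steps of 3,
#' 10 replicate aliquots each), repeated QC injections of the pooled
#' sample, and a QC dilution series at known relative concentrations.
#' Feature classes: `increasing`/`decreasing` features drift linearly in
#' log2 intensity with storage day; `erratic` features jump between days
#' with no net trend; `stable` features do not move; `background`
#' features do not respond to dilution of the QC sample; `noisy_qc`
#' features show inflated technical variance in the QC replicates.
#'
#' @param n_features Total number of features.
#' @param n_timepoints Number of storage time points.
#' @param day_step Days between consecutive time points.
#' @param n_replicates Replicate aliquots per time point.
#' @param n_increasing,n_decreasing,n_erratic Number of features in each
#'   time-responsive class.
#' @param slope_range Length-2 numeric: range (low, high) of the absolute
#'   per-day change of log2 mean intensity for trending features.
#' @param replicate_noise_cv Fractional coefficient of variation of the
#'   multiplicative (lognormal) measurement noise.
#' @param qc_n_injections Number of undiluted QC replicate injections.
#' @param qc_dilution_factors Relative concentrations of the QC dilution
#'   series.
#' @param qc_dilution_replicates Injections per dilution level.
#' @param frac_background_features Fraction of features that do not
#'   respond to dilution (background noise).
#' @param frac_noisy_qc_features Fraction of features whose QC replicate
#'   CV is inflated beyond the 30% filter threshold.
#' @param missing_rate Fraction of study-sample cells set to missing.
#' @param missing_mechanism `"mcar"` (default) or `"low_intensity"`
#'   (missingness preferentially hits low-intensity cells).
#' @param seed Integer seed fixing all randomness of the generator.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_features = 1500,
                             n_timepoints = 11,
                             day_step = 3,
                             n_replicates = 10,
                             n_increasing = 30,
                             n_decreasing = 30,
                             n_erratic = 30,
                             slope_range = c(0.02, 0.08),
                             replicate_noise_cv = 0.2,
                             qc_n_injections = 10,
                             qc_dilution_factors = c(1, 0.2, 0.1, 0.02),
                             qc_dilution_replicates = 3,
                             frac_background_features = 0.2,
                             frac_noisy_qc_features = 0.1,
                             missing_rate = 0.05,
                             missing_mechanism = c("mcar", "low_intensity"),
                             seed = 42) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(n_features = n_features, n_timepoints = n_timepoints,
              day_step = day_step, n_replicates = n_replicates,
              n_increasing = n_increasing, n_decreasing = n_decreasing,
              n_erratic = n_erratic, slope_range = slope_range,
              replicate_noise_cv = replicate_noise_cv,
              qc_n_injections = qc_n_injections,
              qc_dilution_factors = qc_dilution_factors,
              qc_dilution_replicates = qc_dilution_replicates,
              frac_background_features = frac_background_features,
              frac_noisy_qc_features = frac_noisy_qc_features,
              missing_rate = missing_rate,
              missing_mechanism = missing_mechanism,
              seed = as.integer(seed))
  fracs <- c(frac_background_features, frac_noisy_qc_features, missing_rate)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]")
  if (length(slope_range) != 2 || slope_range[1] > slope_range[2])
    stop("slope_range must be (low, high) with low <= high")
  if (slope_range[1] < 0)
    stop("slope_range is the absolute per-day trend and must be >= 0")
  n_special <- n_increasing + n_decreasing + n_erratic
  n_bg <- round(frac_background_features * n_features)
  n_noisy <- round(frac_noisy_qc_features * n_features)
  if (n_special > n_features)
    stop("n_increasing + n_decreasing + n_erratic (", n_special,
         ") exceeds n_features (", n_features, ")")
  if (n_special + n_bg + n_noisy > n_features)
    stop("trending + erratic + background + noisy_qc classes exceed ",
         "n_features; lower the class counts or fractions")
  if (n_timepoints < 2 || n_replicates < 2)
    stop("need at least 2 time points and 2 replicates")
  class(cfg) <- "synthetic_config"
  cfg
}

# Evaluate expr with a private RNG stream; the caller's RNG state is
# untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# lognormal sigma (log2 scale) for a given fractional CV
cv_to_log2_sd <- function(cv) sqrt(log(1 + cv^2)) / log(2)

#' Generate a synthetic storage-time-course experiment
#'
#' Draws a complete feature table (study, QC and QC-dilution samples)
#' from the generative model
#' \deqn{\log_2 I_{fs} = b_f + s_f d_s + e_{f,d_s} + u_{f,r_s} +
#'   \epsilon_{fs},}
#' where \eqn{b_f} is the feature baseline, \eqn{s_f} the per-day log2
#' slope (zero except for trending features), \eqn{e_{f,d}} i.i.d.
#' day-level shifts for erratic features, \eqn{u_{f,r}} a small
#' persistent replicate offset (so pairing by replicate is meaningful),
#' and \eqn{\epsilon} Gaussian noise on the log2 scale matched to the
#' requested multiplicative CV. QC injections sit at the pooled mean;
#' dilution-series intensities scale proportionally with the dilution
#' factor except for background features, which ignore it.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `table` (a [feature_table()]) and `truth`,
#'   a data frame with per-feature `class`
#'   (`increasing`/`decreasing`/`erratic`/`stable`/`background`/`noisy_qc`),
#'   `slope` (log2 units per day) and `baseline` (log2 mean intensity at
#'   day 0).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, generate_experiment_impl(config))
}

generate_experiment_impl <- function(cfg) {
  p <- cfg$n_features
  days <- seq(0, by = cfg$day_step, length.out = cfg$n_timepoints)
  n_rep <- cfg$n_replicates

  ## feature identities: rt_mz naming as produced by deconvolution software
  rt <- round(stats::runif(p, 0.3, 8.5), 2)
  mz <- round(stats::runif(p, 80, 1000), 4)
  feature_id <- make.unique(sprintf("%.2f_%.4f", rt, mz), sep = "b")

  ## class assignment
  n_bg <- round(cfg$frac_background_features * p)
  n_noisy <- round(cfg$frac_noisy_qc_features * p)
  cls <- rep("stable", p)
  pool <- sample.int(p)
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  cls[take(cfg$n_increasing)] <- "increasing"
  cls[take(cfg$n_decreasing)] <- "decreasing"
  cls[take(cfg$n_erratic)] <- "erratic"
  cls[take(n_bg)] <- "background"
  cls[take(n_noisy)] <- "noisy_qc"

  baseline <- stats::runif(p, 10, 20)     # log2 intensity, ~1e3 .. 1e6
  slope <- numeric(p)
  inc <- cls == "increasing"
  dec <- cls == "decreasing"
  slope[inc] <- stats::runif(sum(inc), cfg$slope_range[1], cfg$slope_range[2])
  slope[dec] <- -stats::runif(sum(dec), cfg$slope_range[1], cfg$slope_range[2])

  sd_noise <- cv_to_log2_sd(cfg$replicate_noise_cv)
  sd_rep <- 0.5 * sd_noise      # persistent replicate (aliquot) offset
  sd_erratic <- 0.5             # log2 units; comparable to a mid-range trend

  ## study samples ------------------------------------------------------
  grid <- expand.grid(replicate = seq_len(n_rep), day = days)
  grid <- grid[order(grid$day, grid$replicate), ]
  n_study <- nrow(grid)
  study_id <- sprintf("S_d%02d_r%02d", grid$day, grid$replicate)

  rep_offset <- matrix(stats::rnorm(p * n_rep, 0, sd_rep), nrow = p)
  day_shift <- matrix(0, nrow = p, ncol = length(days))
  err <- cls == "erratic"
  day_shift[err, ] <- stats::rnorm(sum(err) * length(days), 0, sd_erratic)

  log2_study <- matrix(0, nrow = n_study, ncol = p)
  for (i in seq_len(n_study)) {
    d_idx <- match(grid$day[i], days)
    log2_study[i, ] <- baseline + slope * grid$day[i] +
      day_shift[, d_idx] + rep_offset[, grid$replicate[i]]
  }
  log2_study <- log2_study +
    matrix(stats::rnorm(n_study * p, 0, sd_noise), nrow = n_study)

  ## QC samples: pooled mean of the study aliquots ----------------------
  qc_mean <- baseline + slope * mean(days)
  sd_qc <- rep(sd_noise, p)
  sd_qc[cls == "noisy_qc"] <- cv_to_log2_sd(0.6)
  n_qc <- cfg$qc_n_injections
  qc_id <- sprintf("QC_%02d", seq_len(n_qc))
  log2_qc <- matrix(rep(qc_mean, each = n_qc), nrow = n_qc) +
    matrix(stats::rnorm(n_qc * p, 0, rep(sd_qc, each = n_qc)), nrow = n_qc)

  ## QC dilution series -------------------------------------------------
  dil <- rep(cfg$qc_dilution_factors, each = cfg$qc_dilution_replicates)
  n_dil <- length(dil)
  dil_id <- sprintf("QCD_f%03d_r%02d", round(1000 * dil),
                    rep(seq_len(cfg$qc_dilution_replicates),
                        times = length(cfg$qc_dilution_factors)))
  responds <- cls != "background"
  log2_dil <- matrix(rep(qc_mean, each = n_dil), nrow = n_dil)
  log2_dil[, responds] <- log2_dil[, responds] + log2(dil)
  log2_dil <- log2_dil +
    matrix(stats::rnorm(n_dil * p, 0, sd_noise), nrow = n_dil)

  ints <- rbind(2^log2_study, 2^log2_qc, 2^log2_dil)

  ## missingness among study samples ------------------------------------
  if (cfg$missing_rate > 0) {
    n_cells <- n_study * p
    if (cfg$missing_mechanism == "mcar") {
      miss <- which(stats::runif(n_cells) < cfg$missing_rate)
    } else {
      # low-intensity-biased: probability proportional to the rank of
      # -intensity, scaled so the expected rate matches missing_rate
      r <- rank(ints[seq_len(n_study), ])
      pr <- 2 * cfg$missing_rate * (1 - (r - 0.5) / n_cells)
      miss <- which(stats::runif(n_cells) < pmin(pr, 1))
    }
    study_block <- ints[seq_len(n_study), ]
    study_block[miss] <- NA_real_
    ints[seq_len(n_study), ] <- study_block
  }

  samples <- data.frame(
    sample_id = c(study_id, qc_id, dil_id),
    role = c(rep("study", n_study), rep("qc", n_qc),
             rep("qc_dilution", n_dil)),
    storage_day = c(grid$day, rep(NA_integer_, n_qc + n_dil)),
    replicate = c(grid$replicate, rep(NA_integer_, n_qc + n_dil)),
    dilution_factor = c(rep(NA_real_, n_study + n_qc), dil),
    mode = "pos",
    stringsAsFactors = FALSE)
  features <- data.frame(feature_id = feature_id, rt_min = rt, mz = mz,
                         mode = "pos", stringsAsFactors = FALSE)
  rownames(ints) <- samples$sample_id
  colnames(ints) <- feature_id

  truth <- data.frame(feature_id = feature_id, class = cls, slope = slope,
                      baseline = baseline, stringsAsFactors = FALSE)
  list(table = feature_table(ints, samples, features), truth = truth)
}

#' Precision and recall of a selected feature set against ground truth
#'
#' The target set is the union of the `increasing` and `decreasing`
#' classes, i.e. the features that genuinely trend with storage time.
#'
#' @param selected_features Character vector of selected feature ids.
#' @param truth Truth data frame from [generate_experiment()].
#' @return List with `precision` (`NA` when nothing was selected) and
#'   `recall`.
#' @export
score_recovery <- function(selected_features, truth) {
  if (!all(selected_features %in% truth$feature_id))
    stop("selected features not present in truth")
  trending <- truth$feature_id[truth$class %in% c("increasing", "decreasing")]
  hits <- length(intersect(selected_features, trending))
  precision <- if (length(selected_features) == 0) NA_real_ else
    hits / length(unique(selected_features))
  recall <- if (length(trending) == 0) NA_real_ else hits / length(trending)
  list(precision = precision, recall = recall)
}

#' Write a synthetic experiment to disk
#'
#' Writes the feature-table trio plus `truth.tsv` (feature_id, class,
#' slope, baseline).
#'
#' @param experiment List from [generate_experiment()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_experiment <- function(experiment, dir) {
  write_feature_table(experiment$table, dir)
  utils::write.table(experiment$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
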