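#' Pipeline configuration
#'
#' Gathers every tunable of the end-to-end stability analysis. Either an
#' input directory holding a feature-table trio (see
#' [read_feature_table()]) or a [synthetic_config()] must be supplied.
#'
#' @param input Directory with `intensities.csv`, `samples.csv`,
#'   `features.csv`, or `NULL` when `synthetic` is given.
#' @param synthetic A [synthetic_config()], or `NULL` when `input` is
#'   given.
#' @param r2_threshold,cv_threshold,max_missing QC filter thresholds.
#' @param knn_k,glog_a Preprocessing parameters.
#' @param alpha Elastic-net mixing parameter, or a grid to screen
#'   (length > 1 triggers [select_alpha()]).
#' @param folds `"loo"` or an integer fold count for lambda selection.
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @param split_fraction Training fraction of the day-stratified split.
#' @param meba_nu Prior df for the moderated Hotelling statistic
#'   (`NULL` = k - 1).
#' @param seed Seed governing every stochastic step.
#' @param outdir Output directory for the tabular artifacts, or `NULL`
#'   to skip writing.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            r2_threshold = 0.5, cv_threshold = 30,
                            max_missing = 0.20, knn_k = 10, glog_a = 1,
                            alpha = 0.5, folds = "loo",
                            lambda_rule = c("1se", "min"),
                            split_fraction = 0.75, meba_nu = NULL,
                            seed = 1, outdir = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  if (is.null(input) && is.null(synthetic))
    stop("supply either an input directory or a synthetic_config")
  stopifnot(r2_threshold >= 0, r2_threshold <= 1,
            cv_threshold >= 0, max_missing >= 0, max_missing <= 1,
            split_fraction > 0, split_fraction < 1,
            all(alpha >= 0 & alpha <= 1))
  structure(list(input = input, synthetic = synthetic,
                 r2_threshold = r2_threshold, cv_threshold = cv_threshold,
                 max_missing = max_missing, knn_k = knn_k,
                 glog_a = glog_a, alpha = alpha, folds = folds,
                 lambda_rule = lambda_rule,
                 split_fraction = split_fraction, meba_nu = meba_nu,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Per-day mean profile matrix for a heat map
#'
#' Entry `(f, d)` is the mean autoscaled intensity of feature `f` over
#' the replicates at day `d`; rows are ordered as in `selected`
#' (coefficient-rank order), columns by ascending day.
#'
#' @param matrix Samples x features matrix (or `preprocessed_matrix`).
#' @param selected Feature ids, in display order.
#' @param day Storage day per sample row.
#' @return A `length(selected)` x `n_days` matrix.
#' @export
heatmap_matrix <- function(matrix, selected, day) {
  if (inherits(matrix, "preprocessed_matrix")) matrix <- matrix$values
  if (!all(selected %in% colnames(matrix)))
    stop("selected features absent from the matrix")
  days <- sort(unique(day))
  out <- sapply(days, function(d)
    colMeans(matrix[day == d, selected, drop = FALSE]))
  out <- base::matrix(out, nrow = length(selected),
                      dimnames = list(selected, as.character(days)))
  out
}

#' PCA scores of the samples over a feature subset
#'
#' Column-centres the submatrix and takes the singular value
#' decomposition; scores are `U %*% diag(d)` and explained-variance
#' fractions `d^2 / sum(d^2)`.
#'
#' @param matrix Samples x features matrix restricted to the features of
#'   interest (>= 2 samples, >= 2 features).
#' @return List with `scores` (samples x 2), `explained_variance`
#'   (descending fractions, all components).
#' @export
pca_scores <- function(matrix) {
  if (inherits(matrix, "preprocessed_matrix")) matrix <- matrix$values
  if (nrow(matrix) < 2 || ncol(matrix) < 2)
    stop("need >= 2 samples and >= 2 features")
  centered <- sweep(matrix, 2, colMeans(matrix))
  sv <- svd(centered)
  if (max(sv$d) == 0) stop("rank-0 matrix: no principal components")
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- rownames(matrix)
  list(scores = scores[, 1:2, drop = FALSE],
       explained_variance = sv$d^2 / sum(sv$d^2))
}

#' Run the full stability analysis
#'
#' Executes the complete chain: load or simulate the feature table, recode
#' zeros as missing, apply the QC filter cascade, preprocess the study
#' samples (impute, constant-sum, glog, autoscale), screen features by
#' repeated-measures ANOVA, paired t-tests versus day 0 and the moderated
#' Hotelling T-squared ranking, split the study samples by day, select
#' alpha/lambda by cross-validation on the training set, fit the final
#' penalised Poisson model, evaluate predictions on training and test
#' sets, and rank the selected features. All randomness derives from
#' `config$seed`; re-running an identical config reproduces every
#' artifact byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return List of class `stability_report`; see the elements written by
#'   [write_stability_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$synthetic)) {
    sim <- generate_experiment(config$synthetic)
    table <- sim$table
    truth <- sim$truth
  } else {
    table <- read_feature_table(config$input)
  }

  filt <- apply_qc_filters(table, config$r2_threshold, config$cv_threshold,
                           config$max_missing)
  stopifnot(ncol(filt$table$intensities) ==
              utils::tail(filt$counts$retained, 1))

  study <- ft_study_matrix(filt$table)
  prep <- preprocess_matrix(study$values, k = config$knn_k,
                            glog_a = config$glog_a)

  anova_res <- rm_anova(prep, study$day, study$replicate)
  pairwise_res <- paired_t_vs_day0(prep, study$day, study$replicate)
  meba_res <- rank_features_t2(prep, study$day, study$replicate,
                               nu = config$meba_nu)

  split <- split_train_test(filt$table, fraction = config$split_fraction,
                            seed = config$seed)
  sample_ids <- rownames(prep$values)
  tr <- sample_ids %in% split$train
  Xtr <- prep$values[tr, , drop = FALSE]
  ctr <- colMeans(Xtr)
  Xtr <- sweep(Xtr, 2, ctr)
  Xte <- sweep(prep$values[!tr, , drop = FALSE], 2, ctr)
  ytr <- study$day[tr]
  yte <- study$day[!tr]

  if (length(config$alpha) > 1) {
    sel <- select_alpha(Xtr, ytr, alpha_grid = config$alpha,
                        folds = config$folds, seed = config$seed)
    alpha <- sel$best_alpha
    cv <- sel$cv_results[[as.character(alpha)]]
  } else {
    alpha <- config$alpha
    cv <- cross_validate_lambda(Xtr, ytr, alpha, folds = config$folds,
                                seed = config$seed)
  }
  lambda <- if (config$lambda_rule == "1se") cv$lambda_1se else cv$lambda_min
  model <- fit_elastic_net_poisson(Xtr, ytr, alpha, lambda)

  pred_tr <- predict_storage_days(model, Xtr)
  pred_te <- predict_storage_days(model, Xte)
  eval_tr <- evaluate_predictions(ytr, pred_tr)
  eval_te <- evaluate_predictions(yte, pred_te)
  ranked <- rank_selected_features(model)

  heat <- if (nrow(ranked)) heatmap_matrix(prep, ranked$feature_id,
                                           study$day) else NULL
  pca <- if (nrow(ranked) >= 2)
    pca_scores(prep$values[, ranked$feature_id, drop = FALSE]) else NULL

  predictions <- data.frame(
    sample_id = sample_ids,
    actual_day = study$day,
    predicted_day = NA_real_,
    split = ifelse(tr, "train", "test"),
    stringsAsFactors = FALSE)
  predictions$predicted_day[tr] <- pred_tr
  predictions$predicted_day[!tr] <- pred_te

  report <- structure(list(
    config = config,
    filter = filt,
    preprocessed = prep,
    design = study[c("day", "replicate")],
    anova = anova_res,
    pairwise = pairwise_res,
    meba = meba_res,
    split = split,
    cv = cv,
    model = model,
    predictions = predictions,
    evaluation = list(train = eval_tr, test = eval_te),
    selected_features = ranked,
    heatmap = heat,
    pca = pca,
    truth = truth), class = "stability_report")

  if (!is.null(config$outdir))
    write_stability_report(report, config$outdir)
  report
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability_report\n")
  print(x$filter$counts, row.names = FALSE)
  cat(sprintf("  model: alpha = %g, lambda = %.5g, %d features selected\n",
              x$model$alpha, x$model$lambda, nrow(x$selected_features)))
  cat(sprintf("  train: RMSE %.3f, R2 %.3f | test: RMSEP %.3f, R2 %.3f\n",
              x$evaluation$train$rmse, x$evaluation$train$r2,
              x$evaluation$test$rmse, x$evaluation$test$r2))
  invisible(x)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Write the tabular artifacts of a stability report
#'
#' Writes `filter_report.tsv`, `preprocessed.csv`, `provenance.json`,
#' `anova.tsv`, `pairwise.tsv`, `pairwise_counts.tsv`, `meba.tsv`,
#' `cv_curve.tsv`, `model.json`, `predictions.tsv`,
#' `selected_features.tsv`, `heatmap.tsv`, `pca_scores.tsv` and, for
#' synthetic runs, `truth.tsv`. Deterministic: identical reports give
#' byte-identical files.
#'
#' @param report A `stability_report`.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_stability_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pth <- function(f) file.path(dir, f)

  write_filter_report(report$filter, pth("filter_report.tsv"))
  vals <- data.frame(sample_id = rownames(report$preprocessed$values),
                     report$preprocessed$values, check.names = FALSE)
  utils::write.csv(vals, pth("preprocessed.csv"), row.names = FALSE)
  prov <- report$preprocessed$provenance
  jsonlite::write_json(
    list(knn_k = prov$knn_k, glog_a = prov$glog_a,
         normalization = prov$normalization,
         center = unname(prov$center), scale = unname(prov$scale),
         seed = report$config$seed),
    pth("provenance.json"), auto_unbox = TRUE, digits = NA)
  write_tsv(report$anova, pth("anova.tsv"))
  write_tsv(report$pairwise$tests, pth("pairwise.tsv"))
  write_tsv(report$pairwise$counts, pth("pairwise_counts.tsv"))
  write_tsv(report$meba, pth("meba.tsv"))
  write_tsv(data.frame(lambda = report$cv$lambda, cvm = report$cv$cvm,
                       cvse = report$cv$cvse), pth("cv_curve.tsv"))
  beta_nz <- report$model$beta[report$model$beta != 0]
  jsonlite::write_json(
    list(alpha = report$model$alpha, lambda = report$model$lambda,
         lambda_min = report$cv$lambda_min,
         lambda_1se = report$cv$lambda_1se,
         lambda_rule = report$config$lambda_rule,
         intercept = report$model$beta0,
         coefficients = as.list(beta_nz),
         convergence = report$model$convergence,
         seed = report$config$seed),
    pth("model.json"), auto_unbox = TRUE, digits = NA)
  write_tsv(report$predictions, pth("predictions.tsv"))
  write_tsv(report$selected_features, pth("selected_features.tsv"))
  if (!is.null(report$heatmap)) {
    hm <- data.frame(feature_id = rownames(report$heatmap),
                     report$heatmap, check.names = FALSE)
    write_tsv(hm, pth("heatmap.tsv"))
  }
  if (!is.null(report$pca)) {
    sc <- data.frame(sample_id = rownames(report$pca$scores),
                     pc1 = report$pca$scores[, 1],
                     pc2 = report$pca$scores[, 2])
    write_tsv(sc, pth("pca_scores.tsv"))
  }
  if (!is.null(report$truth)) write_tsv(report$truth, pth("truth.tsv"))
  invisible(dir)
}
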