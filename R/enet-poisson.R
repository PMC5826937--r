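#' Soft-thresholding operator
#'
#' `S(z, gamma) = sign(z) * max(|z| - gamma, 0)`, the elementary update of
#' coordinate descent under an l1 penalty.
#'
#' @param z Numeric vector.
#' @param gamma Threshold, `gamma >= 0`.
#' @return Thresholded values, same shape as `z`.
#' @export
soft_threshold <- function(z, gamma) {
  if (any(gamma < 0)) stop("gamma must be >= 0")
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Poisson deviance
#'
#' `D = 2 sum_i [ y_i log(y_i / mu_i) - (y_i - mu_i) ]`, with the log term
#' read as 0 when `y_i = 0`. Non-negative, and zero exactly when
#' `y = mu`. Used as the cross-validation loss.
#'
#' @param y Non-negative observed counts.
#' @param mu Positive predicted means.
#' @return The total deviance (scalar).
#' @export
poisson_deviance <- function(y, mu) {
  if (length(y) != length(mu)) stop("y and mu must have equal length")
  if (any(mu <= 0)) stop("mu must be strictly positive")
  if (any(y < 0)) stop("y must be non-negative")
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

eta_cap_default <- 30

capped_eta <- function(X, beta0, beta, cap = eta_cap_default) {
  eta <- drop(beta0 + X %*% beta)
  pmin(pmax(eta, -cap), cap)
}

#' Penalised Poisson objective
#'
#' The quantity the solver minimises:
#' \deqn{-\frac{1}{N} \sum_i \big( y_i \eta_i - e^{\eta_i} \big)
#'   + \lambda\Big((1-\alpha)\sum_j \beta_j^2/2 +
#'   \alpha\sum_j |\beta_j|\Big),}
#' with \eqn{\eta_i = \beta_0 + x_i'\beta}. The intercept is
#' unpenalised. The linear predictor is capped at +/-30 before
#' exponentiation to guard against overflow.
#'
#' @param X Centred samples x features design matrix.
#' @param y Non-negative integer outcome (storage days).
#' @param beta0 Intercept.
#' @param beta Coefficient vector (length `ncol(X)`).
#' @param alpha Elastic-net mixing parameter in \[0, 1\].
#' @param lambda Penalty strength, `lambda >= 0`.
#' @return Objective value (scalar).
#' @export
penalized_objective <- function(X, y, beta0, beta, alpha, lambda) {
  stopifnot(length(beta) == ncol(X), length(y) == nrow(X),
            alpha >= 0, alpha <= 1, lambda >= 0)
  eta <- capped_eta(X, beta0, beta)
  ll <- sum(y * eta - exp(eta))
  penalty <- (1 - alpha) * sum(beta^2) / 2 + alpha * sum(abs(beta))
  -ll / nrow(X) + lambda * penalty
}

check_design <- function(X, y) {
  if (!is.matrix(X)) stop("X must be a matrix")
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("y must be non-negative integers (storage days)")
  cm <- max(abs(colMeans(X)))
  if (cm > 1e-8)
    stop("X columns must be centred (max |column mean| = ",
         format(cm), "); autoscale the matrix first")
  invisible(TRUE)
}

#' Descending lambda grid for the penalised Poisson problem
#'
#' The largest grid value is the smallest penalty at which the null
#' model (all coefficients zero, intercept at `log(mean(y))`) satisfies
#' the optimality conditions:
#' `lambda_max = max_j |<x_j, y - mean(y)>| / (N * alpha)`. For
#' `alpha < 0.001` the `alpha = 0.001` surrogate is used (ridge has no
#' finite lambda_max). The grid is log-spaced down to
#' `lambda_max * lambda_min_ratio`.
#'
#' @inheritParams penalized_objective
#' @param n_lambda Number of grid points.
#' @param lambda_min_ratio Ratio of smallest to largest lambda; defaults
#'   to 0.01 when `nrow(X) < ncol(X)`, else 1e-4.
#' @return Strictly decreasing numeric vector of length `n_lambda`.
#' @export
compute_lambda_grid <- function(X, y, alpha, n_lambda = 100,
                                lambda_min_ratio = NULL) {
  check_design(X, y)
  if (stats::var(y) == 0)
    stop("constant outcome: no lambda path to construct")
  if (is.null(lambda_min_ratio))
    lambda_min_ratio <- if (nrow(X) < ncol(X)) 0.01 else 1e-4
  alpha_eff <- max(alpha, 0.001)
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / (nrow(X) * alpha_eff)
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = n_lambda))
}

new_enet_model <- function(alpha, lambda, beta0, beta, feature_names,
                           sweeps, max_delta, converged) {
  names(beta) <- feature_names
  structure(list(alpha = alpha, lambda = lambda, beta0 = beta0,
                 beta = beta,
                 nonzero = feature_names[beta != 0],
                 convergence = list(sweeps = sweeps, max_delta = max_delta,
                                    converged = converged)),
            class = "enet_model")
}

#' @export
print.enet_model <- function(x, ...) {
  cat(sprintf(
    "enet_model: alpha = %g, lambda = %g, intercept = %.4f, %d/%d nonzero\n",
    x$alpha, x$lambda, x$beta0, length(x$nonzero), length(x$beta)))
  invisible(x)
}

# Fit the full lambda path with warm starts; workhorse behind the
# exported single-lambda fit and the cross-validation loop.
fit_path <- function(X, y, alpha, lambda_seq, tol = 1e-7,
                     max_sweeps = 1e5, warm_start = NULL) {
  check_design(X, y)
  stopifnot(alpha >= 0, alpha <= 1, all(lambda_seq >= 0))
  beta0_init <- if (is.null(warm_start)) log(mean(y)) else warm_start$beta0
  beta_init <- if (is.null(warm_start)) numeric(ncol(X)) else
    unname(warm_start$beta)
  .cd_poisson_path(X, as.numeric(y), alpha, as.numeric(lambda_seq),
                   tol, as.integer(max_sweeps), beta0_init, beta_init,
                   eta_cap_default)
}

#' Fit the elastic-net-penalised Poisson regression at one penalty
#'
#' Minimises the [penalized_objective()] by outer iteratively reweighted
#' least squares (weights `w = mu`, working response
#' `z = eta + (y - mu)/mu`) and inner cyclic coordinate descent with
#' soft-thresholding, declared converged when no coefficient moves by
#' more than `tol`. The design matrix must already be column-centred
#' (autoscaled upstream); no internal standardisation is performed.
#'
#' @inheritParams penalized_objective
#' @param warm_start Optional `enet_model` used as the starting point.
#' @param tol Convergence tolerance on the largest coefficient change.
#' @param max_sweeps Cap on coordinate sweeps before giving up.
#' @return An `enet_model`: `alpha`, `lambda`, `beta0`, named coefficient
#'   vector `beta`, the nonzero set and convergence diagnostics.
#' @export
fit_elastic_net_poisson <- function(X, y, alpha, lambda, warm_start = NULL,
                                    tol = 1e-7, max_sweeps = 1e5) {
  fit <- fit_path(X, y, alpha, lambda, tol = tol, max_sweeps = max_sweeps,
                  warm_start = warm_start)
  if (!fit$converged[1])
    stop("coordinate descent did not converge (", fit$sweeps[1],
         " sweeps, last max coefficient change ",
         format(fit$max_delta[1]), ")")
  new_enet_model(alpha, lambda, fit$beta0[1], fit$beta[, 1],
                 colnames(X), fit$sweeps[1], fit$max_delta[1],
                 fit$converged[1])
}

#' Karush-Kuhn-Tucker residual of a fitted model
#'
#' First-order certificate of optimality for the non-smooth objective:
#' with `g_j` the gradient of the smooth part (negative mean
#' log-likelihood plus ridge term), an optimal solution has
#' `|g_j| <= lambda * alpha` wherever `beta_j = 0` and
#' `g_j + lambda * alpha * sign(beta_j) = 0` elsewhere; the intercept
#' gradient must vanish. Returns the largest violation.
#'
#' @inheritParams penalized_objective
#' @param model An `enet_model`.
#' @return Maximum KKT violation (scalar; ~0 at an optimum).
#' @export
kkt_residual <- function(X, y, model) {
  mu <- exp(capped_eta(X, model$beta0, model$beta))
  g <- drop(crossprod(X, mu - y)) / nrow(X) +
    model$lambda * (1 - model$alpha) * model$beta
  la <- model$lambda * model$alpha
  zero <- model$beta == 0
  res_zero <- if (any(zero)) max(pmax(abs(g[zero]) - la, 0)) else 0
  res_nz <- if (any(!zero))
    max(abs(g[!zero] + la * sign(model$beta[!zero]))) else 0
  res_int <- abs(mean(mu - y))
  max(res_zero, res_nz, res_int)
}

#' Cross-validate the penalty strength
#'
#' Builds the lambda grid on the full data (so fold assignment never
#' changes the grid), fits the path on each training portion with warm
#' starts, and records the held-out Poisson deviance per observation.
#' `lambda_min` minimises the mean curve; `lambda_1se` is the largest
#' lambda whose mean is within one standard error of that minimum (the
#' conventional parsimony rule).
#'
#' @inheritParams compute_lambda_grid
#' @param folds `"loo"` for leave-one-out (the default) or an integer
#'   number of folds.
#' @param seed Seed for k-fold assignment (ignored for LOO).
#' @param lambda Optional explicit grid; overrides `n_lambda`.
#' @param tol,max_sweeps Passed to the solver.
#' @return List of class `cv_result`: `lambda` (descending), `cvm` (mean
#'   held-out deviance per observation), `cvse`, `lambda_min`,
#'   `lambda_1se`, `fold_id`, `alpha`, `seed`.
#' @export
cross_validate_lambda <- function(X, y, alpha, folds = "loo", seed = 1,
                                  n_lambda = 100, lambda_min_ratio = NULL,
                                  lambda = NULL, tol = 1e-7,
                                  max_sweeps = 1e5) {
  check_design(X, y)
  N <- nrow(X)
  if (N < 3) stop("need at least 3 samples to cross-validate")
  if (is.null(lambda))
    lambda <- compute_lambda_grid(X, y, alpha, n_lambda, lambda_min_ratio)
  if (identical(folds, "loo")) {
    fold_id <- seq_len(N)
  } else {
    k <- as.integer(folds)
    if (is.na(k) || k < 2 || k > N) stop("folds must be 'loo' or 2..N")
    fold_id <- with_local_seed(seed,
                               sample(rep_len(seq_len(k), N)))
  }
  nfold <- length(unique(fold_id))
  fold_dev <- matrix(NA_real_, nrow = nfold, ncol = length(lambda))
  for (f in seq_len(nfold)) {
    test <- fold_id == f
    ytr <- y[!test]
    if (stats::var(ytr) == 0) {
      warning("fold ", f, " skipped: constant training outcome")
      next
    }
    Xtr <- X[!test, , drop = FALSE]
    # re-centre the training block so the solver contract holds exactly
    ctr <- colMeans(Xtr)
    Xtr <- sweep(Xtr, 2, ctr)
    Xte <- sweep(X[test, , drop = FALSE], 2, ctr)
    fit <- fit_path(Xtr, ytr, alpha, lambda, tol = tol,
                    max_sweeps = max_sweeps)
    if (!all(fit$converged))
      stop("solver failed to converge in fold ", f)
    for (l in seq_along(lambda)) {
      eta <- drop(fit$beta0[l] + Xte %*% fit$beta[, l])
      mu <- exp(pmin(pmax(eta, -eta_cap_default), eta_cap_default))
      fold_dev[f, l] <- poisson_deviance(y[test], mu) / sum(test)
    }
  }
  used <- stats::complete.cases(fold_dev)
  if (!any(used)) stop("no usable folds")
  cvm <- colMeans(fold_dev[used, , drop = FALSE])
  cvse <- apply(fold_dev[used, , drop = FALSE], 2, stats::sd) /
    sqrt(sum(used))
  i_min <- which.min(cvm)
  lambda_min <- lambda[i_min]
  ok_1se <- which(cvm <= cvm[i_min] + cvse[i_min])
  lambda_1se <- lambda[min(ok_1se)]   # grid descending: first = largest
  structure(list(lambda = lambda, cvm = cvm, cvse = cvse,
                 lambda_min = lambda_min, lambda_1se = lambda_1se,
                 fold_id = fold_id, alpha = alpha, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cv_result: alpha = %g, %d lambdas, %d folds\n  lambda_min = %.5g (cvm %.4f), lambda_1se = %.5g\n",
    x$alpha, length(x$lambda), length(unique(x$fold_id)),
    x$lambda_min, min(x$cvm), x$lambda_1se))
  invisible(x)
}

#' Screen the elastic-net mixing parameter
#'
#' Cross-validates each alpha on the same folds and picks the one whose
#' minimum mean cross-validated deviance is lowest. Exact ties break
#' towards 0.5 (equal weight to the ridge and lasso penalties).
#'
#' @inheritParams cross_validate_lambda
#' @param alpha_grid Candidate mixing parameters.
#' @return List with `best_alpha` and `cv_results` (named per-alpha
#'   [cross_validate_lambda()] results).
#' @export
select_alpha <- function(X, y, alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                         folds = "loo", seed = 1, ...) {
  if (any(alpha_grid < 0 | alpha_grid > 1))
    stop("alpha values must lie in [0, 1]")
  cvs <- lapply(alpha_grid, function(a)
    cross_validate_lambda(X, y, a, folds = folds, seed = seed, ...))
  names(cvs) <- as.character(alpha_grid)
  best_cvm <- vapply(cvs, function(cv) min(cv$cvm), numeric(1))
  cand <- which(best_cvm <= min(best_cvm) + 1e-12)
  pick <- cand[order(abs(alpha_grid[cand] - 0.5), alpha_grid[cand])][1]
  list(best_alpha = alpha_grid[pick], cv_results = cvs)
}

#' Stratified train/test split of the study samples
#'
#' Splits the study samples by storage day so every day is represented
#' in the training set: each day contributes `ceiling(fraction * n_day)`
#' samples to training and the rest to test. A day with a single sample
#' goes to training with a warning.
#'
#' @param table A [feature_table()] (its study samples are split), or a
#'   data frame with columns `sample_id` and `storage_day`.
#' @param fraction Training fraction (default 0.75).
#' @param seed Seed for the random assignment.
#' @return List with `train` and `test` sample-id vectors.
#' @export
split_train_test <- function(table, fraction = 0.75, seed = 1) {
  if (inherits(table, "feature_table")) {
    s <- table$samples[table$samples$role == "study", ]
    ids <- s$sample_id; day <- s$storage_day
  } else {
    ids <- table$sample_id; day <- table$storage_day
  }
  stopifnot(fraction > 0, fraction < 1)
  with_local_seed(seed, {
    train <- character(0)
    for (d in sort(unique(day))) {
      pool <- ids[day == d]
      if (length(pool) == 1) {
        warning("day ", d, " has a single sample; assigned to training")
        train <- c(train, pool)
        next
      }
      n_train <- ceiling(fraction * length(pool))
      train <- c(train, sample(pool, n_train))
    }
    list(train = sort(train), test = sort(setdiff(ids, train)))
  })
}

#' Predict storage days from a fitted model
#'
#' `yhat_i = exp(beta0 + x_i' beta)`: the model's continuous estimate of
#' how many days the sample spent in storage.
#'
#' @param model An `enet_model`.
#' @param X Matrix whose columns align with the model's features.
#' @return Numeric vector of predicted days (non-negative).
#' @export
predict_storage_days <- function(model, X) {
  if (!identical(colnames(X), names(model$beta)))
    stop("X columns do not match the model's features")
  exp(capped_eta(X, model$beta0, model$beta))
}

#' Accuracy of predicted storage days
#'
#' Root mean squared error plus the squared Pearson correlation between
#' actual and predicted days, with the usual t-transform p-value for the
#' correlation (n - 2 df).
#'
#' @param actual Observed storage days.
#' @param predicted Model predictions.
#' @return List: `rmse`, `r2`, `p_value`, `n`. `r2`/`p_value` are `NA`
#'   when either vector has zero variance.
#' @export
evaluate_predictions <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 3)
    stop("actual and predicted must have equal length >= 3")
  rmse <- sqrt(mean((actual - predicted)^2))
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0)
    return(list(rmse = rmse, r2 = NA_real_, p_value = NA_real_,
                n = length(actual)))
  r <- stats::cor(actual, predicted)
  n <- length(actual)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(rmse = rmse, r2 = r^2, p_value = p, n = n)
}

#' Rank the features selected by the model
#'
#' Features with nonzero coefficients, ordered by absolute coefficient
#' descending (larger magnitude = larger contribution to the storage-time
#' prediction); ties break by feature id.
#'
#' @param model An `enet_model`.
#' @return Data frame `feature_id`, `coefficient`, `rank` (possibly
#'   zero rows).
#' @export
rank_selected_features <- function(model) {
  nz <- model$beta[model$beta != 0]
  if (!length(nz))
    return(data.frame(feature_id = character(0), coefficient = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  ord <- order(-abs(nz), names(nz))
  data.frame(feature_id = names(nz)[ord], coefficient = unname(nz[ord]),
             rank = seq_along(nz), stringsAsFactors = FALSE)
}
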