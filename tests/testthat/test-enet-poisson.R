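test_that("soft threshold matches its closed form", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_equal(soft_threshold(c(-2, 0, 2), 0.5), c(-1.5, 0, 1.5))
  expect_error(soft_threshold(1, -0.1), ">= 0")
})

test_that("Poisson deviance has its closed-form values and sign", {
  expect_equal(poisson_deviance(c(1, 4, 2), c(1, 4, 2)), 0)
  expect_equal(poisson_deviance(0, 3), 6)
  expect_equal(poisson_deviance(2, 1), 2 * (2 * log(2) - 1))
  expect_error(poisson_deviance(1, 0), "positive")
  set.seed(2)
  y <- rpois(20, 4)
  mu <- runif(20, 0.5, 8)
  expect_gte(poisson_deviance(y, mu), 0)
})

test_that("penalised objective evaluates the stated form", {
  inst <- random_poisson_instance(1)
  p <- ncol(inst$X)
  # null parameters at lambda 0: -(1/N) sum (0 - 1) = 1
  expect_equal(penalized_objective(inst$X, inst$y, 0, numeric(p), 0.5, 0), 1)
  set.seed(3)
  beta <- rnorm(p, 0, 0.2)
  pen <- 0.5 * sum(beta^2) / 2 + 0.5 * sum(abs(beta))
  o1 <- penalized_objective(inst$X, inst$y, 0.1, beta, 0.5, 0.2)
  o2 <- penalized_objective(inst$X, inst$y, 0.1, beta, 0.5, 0.4)
  expect_equal(o2 - o1, 0.2 * pen)    # linear in lambda
  o_ridge <- penalized_objective(inst$X, inst$y, 0.1, beta, 0, 0.3)
  o_lasso <- penalized_objective(inst$X, inst$y, 0.1, beta, 1, 0.3)
  expect_equal(o_lasso - o_ridge,
               0.3 * (sum(abs(beta)) - sum(beta^2) / 2))
})

test_that("the lambda grid starts exactly at the null-model boundary", {
  inst <- random_poisson_instance(4, N = 30, p = 6)
  grid <- compute_lambda_grid(inst$X, inst$y, alpha = 0.5, n_lambda = 10)
  expect_true(all(diff(grid) < 0))
  m <- fit_elastic_net_poisson(inst$X, inst$y, 0.5, grid[1])
  expect_true(all(m$beta == 0))
  # null intercept at machine precision (exp/log round trip costs 1 ulp)
  expect_lte(abs(m$beta0 - log(mean(inst$y))), 4 * .Machine$double.eps)
  m_above <- fit_elastic_net_poisson(inst$X, inst$y, 0.5, 1.01 * grid[1])
  expect_true(all(m_above$beta == 0))
  # lambda_max is inversely proportional to alpha
  g_half <- compute_lambda_grid(inst$X, inst$y, alpha = 0.25, n_lambda = 10)
  expect_equal(g_half[1], 2 * grid[1], tolerance = 1e-12)
  expect_error(compute_lambda_grid(inst$X, rep(3, 30), 0.5), "constant")
})

test_that("solutions beat an independent numerical minimiser", {
  for (seed in 1:5) {
    inst <- random_poisson_instance(seed)
    grid <- compute_lambda_grid(inst$X, inst$y, 0.5, n_lambda = 5,
                                lambda_min_ratio = 0.05)
    m <- fit_elastic_net_poisson(inst$X, inst$y, 0.5, grid[3])
    obj <- penalized_objective(inst$X, inst$y, m$beta0, m$beta, 0.5, grid[3])
    ref <- oracle_objective_min(inst$X, inst$y, 0.5, grid[3], m$beta0,
                                m$beta, seed = seed)
    expect_lte(obj, ref + 1e-6)
  }
})

test_that("ridge at vanishing penalty matches the unpenalised Poisson GLM", {
  inst <- random_poisson_instance(6, N = 40, p = 5)
  m <- fit_elastic_net_poisson(inst$X, inst$y, alpha = 0, lambda = 1e-8)
  g <- stats::glm(inst$y ~ inst$X, family = stats::poisson())
  expect_equal(unname(c(m$beta0, m$beta)), unname(coef(g)),
               tolerance = 1e-4)
})

test_that("fitted models carry a valid KKT certificate", {
  for (seed in 1:10) {
    inst <- random_poisson_instance(seed, N = sample(10:30, 1),
                                    p = sample(3:10, 1))
    alpha <- sample(c(0, 0.5, 1), 1)
    grid <- compute_lambda_grid(inst$X, inst$y, alpha, n_lambda = 4,
                                lambda_min_ratio = 0.05)
    for (lam in grid) {
      m <- fit_elastic_net_poisson(inst$X, inst$y, alpha, lam)
      expect_lte(kkt_residual(inst$X, inst$y, m), 1e-5)
    }
  }
})

test_that("glmnet agrees with the coordinate-descent solver", {
  skip_if_not_installed("glmnet")
  inst <- random_poisson_instance(8, N = 50, p = 8)
  grid <- compute_lambda_grid(inst$X, inst$y, 0.5, n_lambda = 20,
                              lambda_min_ratio = 0.05)
  ours <- sapply(grid, function(l)
    fit_elastic_net_poisson(inst$X, inst$y, 0.5, l)$beta)
  ref <- glmnet::glmnet(inst$X, inst$y, family = "poisson", alpha = 0.5,
                        lambda = grid, standardize = FALSE,
                        thresh = 1e-12)
  expect_equal(unname(ours), unname(as.matrix(ref$beta)), tolerance = 1e-4)
})

test_that("training deviance is monotone along the path and lasso is bounded", {
  inst <- random_poisson_instance(9, N = 15, p = 30)
  grid <- compute_lambda_grid(inst$X, inst$y, 1, n_lambda = 25,
                              lambda_min_ratio = 0.01)
  dev <- numeric(length(grid))
  card <- integer(length(grid))
  m <- NULL
  for (i in seq_along(grid)) {
    m <- fit_elastic_net_poisson(inst$X, inst$y, 1, grid[i], warm_start = m)
    mu <- predict_storage_days(m, inst$X)
    dev[i] <- poisson_deviance(inst$y, mu)
    card[i] <- length(m$nonzero)
  }
  expect_true(all(diff(dev) <= 1e-8))
  expect_true(all(card <= nrow(inst$X)))
})

test_that("LOO cross-validation has N folds and a null-model plateau", {
  inst <- random_poisson_instance(10, N = 16, p = 5)
  # a grid strictly above every per-fold lambda_max: scale the full-data
  # lambda_max up by a wide margin
  lam_hi <- 50 * compute_lambda_grid(inst$X, inst$y, 0.5, n_lambda = 2,
                                     lambda_min_ratio = 0.9)
  cv <- cross_validate_lambda(inst$X, inst$y, 0.5, folds = "loo",
                              lambda = lam_hi)
  expect_equal(length(unique(cv$fold_id)), 16)
  # direct held-out null deviance per fold
  ref <- mean(vapply(seq_len(16), function(i)
    poisson_deviance(inst$y[i], mean(inst$y[-i])), numeric(1)))
  expect_equal(cv$cvm[1], ref, tolerance = 1e-8)
  expect_equal(cv$cvm[2], ref, tolerance = 1e-8)
})

test_that("lambda_1se never falls below lambda_min and CV is reproducible", {
  inst <- random_poisson_instance(11, N = 30, p = 8)
  cv1 <- cross_validate_lambda(inst$X, inst$y, 0.5, folds = 5, seed = 7,
                               n_lambda = 30)
  cv2 <- cross_validate_lambda(inst$X, inst$y, 0.5, folds = 5, seed = 7,
                               n_lambda = 30)
  expect_identical(cv1, cv2)
  expect_gte(cv1$lambda_1se, cv1$lambda_min)
  cv3 <- cross_validate_lambda(inst$X, inst$y, 0.5, folds = 5, seed = 8,
                               n_lambda = 30)
  expect_identical(cv3$lambda, cv1$lambda)      # grid independent of seed
  expect_false(identical(cv3$fold_id, cv1$fold_id))
})

test_that("alpha screening honours the tie-break towards 0.5", {
  inst <- random_poisson_instance(12, N = 24, p = 6)
  sel <- select_alpha(inst$X, inst$y, alpha_grid = 0.5, folds = 4,
                      seed = 1, n_lambda = 15)
  expect_equal(sel$best_alpha, 0.5)
  # degenerate tie: feed identical cvm curves through exact ties
  # (constant design columns never enter the model, all alphas coincide)
  set.seed(5)
  Xc <- matrix(rnorm(20 * 3), 20, 3)
  Xc <- sweep(Xc, 2, colMeans(Xc))
  colnames(Xc) <- paste0("f", 1:3)
  y <- rpois(20, 5)
  if (var(y) == 0) y[1] <- y[1] + 1
  lam_hi <- 100 * max(abs(crossprod(Xc, y - mean(y)))) / 20
  sel2 <- select_alpha(Xc, y, alpha_grid = c(0.25, 0.5, 0.75), folds = 4,
                       seed = 2, lambda = c(2 * lam_hi, lam_hi))
  expect_equal(sel2$best_alpha, 0.5)
})

test_that("the stratified split follows the per-day ceiling arithmetic", {
  sim <- generate_experiment(small_synthetic_config(20, seed = 13))
  sp <- split_train_test(sim$table, fraction = 0.75, seed = 4)
  expect_length(sp$train, 88)                    # ceil(0.75*10)=8 per day
  expect_length(sp$test, 22)
  expect_length(intersect(sp$train, sp$test), 0)
  study_ids <- sim$table$samples$sample_id[sim$table$samples$role == "study"]
  expect_setequal(c(sp$train, sp$test), study_ids)
  expect_identical(split_train_test(sim$table, seed = 4), sp)
  sp2 <- split_train_test(sim$table, seed = 5)
  expect_false(identical(sp2$train, sp$train))
  # single-sample day goes to training with a warning
  df <- data.frame(sample_id = c("a", "b", "c"), storage_day = c(0, 0, 3))
  expect_warning(sp3 <- split_train_test(df, fraction = 0.75, seed = 1),
                 "single sample")
  expect_true("c" %in% sp3$train)
})

test_that("predictions are the exponentiated linear predictor", {
  X <- matrix(0, 4, 2, dimnames = list(NULL, c("f1", "f2")))
  m <- structure(list(alpha = 0.5, lambda = 0.1, beta0 = log(15),
                      beta = c(f1 = 0.1, f2 = 0), nonzero = "f1",
                      convergence = list()), class = "enet_model")
  expect_equal(predict_storage_days(m, X), rep(15, 4))
  Xg <- cbind(f1 = seq(-2, 2, length.out = 9), f2 = 0)
  expect_true(all(diff(predict_storage_days(m, Xg)) > 0))
  colnames(Xg) <- c("f1", "other")
  expect_error(predict_storage_days(m, Xg), "match")
})

test_that("prediction evaluation reports RMSE, R2 and the null behaviour", {
  y <- c(0, 3, 6)
  ev <- evaluate_predictions(y, y)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$r2, 1)
  ev2 <- evaluate_predictions(y, y + 1)
  expect_equal(ev2$rmse, 1)
  expect_equal(ev2$r2, 1)
  set.seed(14)
  r2s <- vapply(1:200, function(i) {
    yy <- rep(seq(0, 30, 3), each = 2)
    evaluate_predictions(yy, sample(yy))$r2
  }, numeric(1))
  expect_lt(median(r2s), 0.05)
  ev3 <- evaluate_predictions(y, rep(2, 3))
  expect_true(is.na(ev3$r2))
})

test_that("feature ranking orders by absolute coefficient", {
  m <- structure(list(beta = c(f1 = 0.5, f2 = -0.8, f3 = 0)),
                 class = "enet_model")
  r <- rank_selected_features(m)
  expect_equal(r$feature_id, c("f2", "f1"))
  expect_equal(r$coefficient, c(-0.8, 0.5))
  m$beta <- -m$beta
  expect_equal(rank_selected_features(m)$feature_id, c("f2", "f1"))
  m$beta <- c(f1 = 0, f2 = 0)
  expect_equal(nrow(rank_selected_features(m)), 0)
})

test_that("uncentred designs are rejected by the solver contract", {
  inst <- random_poisson_instance(15)
  Xoff <- inst$X + 1
  expect_error(fit_elastic_net_poisson(Xoff, inst$y, 0.5, 0.1), "centred")
})
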