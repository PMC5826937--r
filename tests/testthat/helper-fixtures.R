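# Small in-code fixtures shared across test files.

# A tiny hand-built feature table: 2 study days x 3 replicates, 3 QC
# injections, a 4-point dilution series, 4 features with distinct QC
# behaviour.
tiny_table <- function(intensities = NULL) {
  samples <- data.frame(
    sample_id = c(sprintf("S_d%02d_r%02d", rep(c(0, 3), each = 3), 1:3),
                  sprintf("QC_%02d", 1:3),
                  sprintf("QCD_%02d", 1:4)),
    role = c(rep("study", 6), rep("qc", 3), rep("qc_dilution", 4)),
    storage_day = c(rep(c(0, 3), each = 3), rep(NA, 7)),
    replicate = c(rep(1:3, 2), rep(NA, 7)),
    dilution_factor = c(rep(NA, 9), 1, 0.2, 0.1, 0.02),
    mode = "pos", stringsAsFactors = FALSE)
  features <- data.frame(feature_id = paste0("f", 1:4),
                         rt_min = 1:4, mz = 100 * (1:4), mode = "pos",
                         stringsAsFactors = FALSE)
  if (is.null(intensities)) {
    set.seed(99)
    intensities <- matrix(stats::runif(13 * 4, 50, 150), nrow = 13,
                          dimnames = list(samples$sample_id,
                                          features$feature_id))
    # make every feature respond to dilution so default fixtures survive
    intensities[10:13, ] <- outer(c(1, 0.2, 0.1, 0.02), rep(100, 4))
  }
  feature_table(intensities, samples, features)
}

# Balanced long-format design helpers for the statistical stages.
balanced_design <- function(n_rep, days) {
  grid <- expand.grid(replicate = seq_len(n_rep), day = days)
  grid[order(grid$day, grid$replicate), ]
}

# Random centred design matrix + Poisson outcome for solver tests.
random_poisson_instance <- function(seed, N = 20, p = 5, signal = 0.4) {
  set.seed(seed)
  X <- matrix(rnorm(N * p), N, p)
  X <- sweep(X, 2, colMeans(X))
  colnames(X) <- paste0("f", seq_len(p))
  beta_true <- c(signal, -signal, numeric(p - 2))
  y <- rpois(N, exp(0.3 + drop(X %*% beta_true)))
  if (var(y) == 0) y[1] <- y[1] + 1L
  list(X = X, y = y)
}

# Independent numerical minimiser of the penalised objective, used as
# the oracle for the coordinate-descent solver: Nelder-Mead restarts
# from the candidate solution plus random perturbations.
oracle_objective_min <- function(X, y, alpha, lambda, start_beta0,
                                 start_beta, n_restarts = 4, seed = 1) {
  obj <- function(par) penalized_objective(X, y, par[1], par[-1],
                                           alpha, lambda)
  set.seed(seed)
  best <- obj(c(start_beta0, start_beta))
  for (r in seq_len(n_restarts)) {
    pert <- if (r == 1) 0 else rnorm(length(start_beta) + 1, 0, 0.05)
    fit <- stats::optim(c(start_beta0, start_beta) + pert, obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 20000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Classical (nu = 0) one-sample Hotelling T2 on an arbitrary flatness
# contrast, written independently of the package implementation.
classical_hotelling_contrast <- function(Y, C) {
  Xc <- Y %*% t(C)
  n <- nrow(Xc)
  xbar <- colMeans(Xc)
  S <- stats::cov(Xc)
  drop(n * t(xbar) %*% solve(S) %*% xbar)
}

# synthetic_config with class counts scaled down for small feature counts
small_synthetic_config <- function(n_features, ...) {
  n <- max(1L, round(0.05 * n_features))
  synthetic_config(n_features = n_features, n_increasing = n,
                   n_decreasing = n, n_erratic = n, ...)
}
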