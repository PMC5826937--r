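#' Successive-difference flatness contrast matrix
#'
#' Rows are `e_{t+1} - e_t`; applying it to a temporal profile yields the
#' k-1 successive changes, which are all zero exactly when the profile is
#' flat. Any full-rank flatness contrast gives the same classical
#' Hotelling statistic.
#'
#' @param k Number of time points.
#' @return A (k-1) x k contrast matrix.
#' @export
successive_diff_contrasts <- function(k) {
  stopifnot(k >= 2)
  C <- matrix(0, k - 1, k)
  C[cbind(seq_len(k - 1), seq_len(k - 1))] <- -1
  C[cbind(seq_len(k - 1), seq_len(k - 1) + 1)] <- 1
  C
}

#' Moderated one-sample Hotelling T-squared for a temporal profile
#'
#' Tests whether a feature's temporal profile is flat. Replicate profiles
#' are mapped through the flatness contrasts `C` (successive
#' differences); with contrast mean `xbar_C` and contrast covariance
#' `S_C`, the covariance is shrunk towards a diagonal prior:
#' \deqn{\tilde S = \frac{\nu \Lambda_C + (n-1) S_C}{\nu + n - 1},
#'   \qquad T^2 = n\, \bar x_C' \tilde S^{-1} \bar x_C,}
#' where `Lambda_C = C diag(prior) C'` is the prior mapped through the
#' contrasts. With `nu = 0` this is the classical one-sample Hotelling
#' statistic on contrasts; a positive `nu` keeps the statistic finite
#' when replicates are scarcer than time points (n - 1 < k - 1), the
#' usual situation in time-course metabolomics.
#'
#' @param feature_data Replicates x timepoints numeric matrix.
#' @param prior_cov Length-k positive vector: the diagonal of the prior
#'   covariance on the time-point scale.
#' @param nu Prior degrees of freedom, `nu >= 0`.
#' @return The T-squared value (non-negative scalar).
#' @export
moderated_hotelling_t2 <- function(feature_data, prior_cov, nu) {
  feature_data <- as.matrix(feature_data)
  n <- nrow(feature_data); k <- ncol(feature_data)
  if (n < 2 || k < 2) stop("need >= 2 replicates and >= 2 timepoints")
  if (nu < 0) stop("nu must be >= 0")
  if (length(prior_cov) != k || any(prior_cov <= 0))
    stop("prior_cov must be a length-k positive vector")
  if (nu == 0 && n - 1 < k - 1)
    stop("classical statistic singular with n - 1 < k - 1 contrasts; ",
         "use a positive prior df nu")
  C <- successive_diff_contrasts(k)
  Xc <- feature_data %*% t(C)
  xbar <- colMeans(Xc)
  S <- stats::cov(Xc)
  Lc <- C %*% (prior_cov * t(C))
  S_mod <- (nu * Lc + (n - 1) * S) / (nu + n - 1)
  sol <- tryCatch(solve(S_mod, xbar), error = function(e)
    stop("moderated covariance numerically singular; ",
         "increase the prior df nu", call. = FALSE))
  drop(n * crossprod(xbar, sol))
}

#' Rank features by moderated Hotelling T-squared
#'
#' Estimates a shared diagonal prior as the across-feature mean of the
#' per-timepoint replicate variances, computes the moderated T-squared
#' per feature, and ranks descending (rank 1 = largest temporal change).
#' Ties break by feature id, lexicographically.
#'
#' @inheritParams rm_anova
#' @param nu Prior degrees of freedom; defaults to `k - 1`, enough to
#'   regularise designs where replicates do not outnumber time points.
#' @return Data frame of class `meba_result`, ordered by rank:
#'   `feature_id`, `t2`, `rank`, with attributes `nu`, `prior_cov` and
#'   `contrast_dim`.
#' @export
rank_features_t2 <- function(matrix, day, replicate, nu = NULL) {
  if (inherits(matrix, "preprocessed_matrix")) matrix <- matrix$values
  check_balanced_design(day, replicate)
  days <- sort(unique(day))
  k <- length(days)
  if (is.null(nu)) nu <- k - 1

  # replicates x timepoints x features cube, rows ordered by replicate
  reps <- sort(unique(replicate))
  n <- length(reps)
  p <- ncol(matrix)
  idx <- order(match(day, days), match(replicate, reps))
  cube <- array(matrix[idx, , drop = FALSE], dim = c(n, k, p))

  # prior: per-timepoint variance across replicates, averaged over features
  tp_var <- apply(cube, c(2, 3), stats::var)    # k x p
  prior <- rowMeans(tp_var)
  prior[prior <= 0] <- max(mean(prior), .Machine$double.eps)

  t2 <- vapply(seq_len(p), function(j)
    moderated_hotelling_t2(cube[, , j], prior, nu), numeric(1))
  ids <- feature_ids(matrix)
  ord <- order(-t2, ids)
  out <- data.frame(feature_id = ids[ord], t2 = t2[ord],
                    rank = seq_len(p), stringsAsFactors = FALSE)
  attr(out, "nu") <- nu
  attr(out, "prior_cov") <- prior
  attr(out, "contrast_dim") <- k - 1
  class(out) <- c("meba_result", "data.frame")
  out
}
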