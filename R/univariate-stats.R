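#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up procedure: sort the m p-values ascending, set
#' `adj_i = min_{j >= i} (m * p_j / j)` capped at 1, and return the
#' adjusted values in the original order. Delegates to
#' [stats::p.adjust()] (method `"BH"`), which implements exactly this,
#' after validating the input.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

feature_ids <- function(matrix) {
  if (is.null(colnames(matrix))) paste0("V", seq_len(ncol(matrix)))
  else colnames(matrix)
}

check_balanced_design <- function(day, replicate) {
  tab <- table(day, replicate)
  if (any(tab != 1))
    stop("unbalanced design: every (day, replicate) pair must occur ",
         "exactly once")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need >= 2 days and >= 2 replicates")
  invisible(tab)
}

#' One-way repeated-measures ANOVA across the time series
#'
#' Screens every feature for change across storage days, treating the
#' replicate aliquot as the repeatedly measured subject. The
#' within-subject decomposition is
#' `SS_total = SS_subject + SS_time + SS_error`, and
#' `F = MS_time / MS_error` with `(k-1, (k-1)(n-1))` degrees of freedom
#' for `k` days and `n` replicates. Features with no variation beyond the
#' subject effect report `F = 0`, `p = 1` so downstream ranking never
#' sees missing statistics.
#'
#' @param matrix Samples x features numeric matrix (typically the
#'   `values` of a [preprocess_matrix()] result) or a
#'   `preprocessed_matrix`.
#' @param day Storage day of each sample row.
#' @param replicate Replicate (subject) id of each sample row.
#' @return Data frame of class `anova_result`: `feature_id`, `F`, `df1`,
#'   `df2`, `p`, `p_adj` (BH across features).
#' @export
rm_anova <- function(matrix, day, replicate) {
  if (inherits(matrix, "preprocessed_matrix")) matrix <- matrix$values
  check_balanced_design(day, replicate)
  day <- factor(day)
  replicate <- factor(replicate)
  k <- nlevels(day)
  n <- nlevels(replicate)

  gm <- colMeans(matrix)
  centered <- sweep(matrix, 2, gm)
  ss_total <- colSums(centered^2)
  day_means <- rowsum(centered, day) / n      # k x p deviations of day means
  ss_time <- n * colSums(day_means^2)
  rep_means <- rowsum(centered, replicate) / k
  ss_subject <- k * colSums(rep_means^2)
  ss_error <- pmax(ss_total - ss_time - ss_subject, 0)

  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  eps <- 1e-12 * pmax(ss_total, 1)
  f <- ifelse(ss_error <= eps,
              ifelse(ss_time <= eps, 0, Inf),
              (ss_time / df1) / (ss_error / df2))
  p <- ifelse(is.infinite(f), 0,
              ifelse(f == 0 & ss_time <= eps, 1,
                     stats::pf(f, df1, df2, lower.tail = FALSE)))
  out <- data.frame(feature_id = feature_ids(matrix), F = f,
                    df1 = df1, df2 = df2, p = p,
                    p_adj = bh_adjust(p), stringsAsFactors = FALSE)
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Paired t-tests of every later day against day 0
#'
#' For each storage day `d > 0` and feature, the per-replicate
#' differences against day 0 feed a two-sided paired t-test; BH
#' adjustment is applied per day across features, and the number of
#' features significant at adjusted p < 0.05 is reported per day.
#' Zero-variance differences give `t = 0, p = 1` when the mean
#' difference is also zero and `t = +/-Inf, p = 0` otherwise.
#'
#' @inheritParams rm_anova
#' @param alpha Significance level for the per-day counts.
#' @return List of class `pairwise_result`: `tests` (day, feature_id, t,
#'   p, p_adj) and `counts` (day, n_significant).
#' @export
paired_t_vs_day0 <- function(matrix, day, replicate, alpha = 0.05) {
  if (inherits(matrix, "preprocessed_matrix")) matrix <- matrix$values
  check_balanced_design(day, replicate)
  days <- sort(unique(day))
  if (days[1] != 0) stop("design must contain day 0 as the reference")
  base_ord <- order(replicate[day == days[1]])
  base <- matrix[day == days[1], , drop = FALSE][base_ord, , drop = FALSE]
  n <- nrow(base)

  tests <- vector("list", length(days) - 1)
  counts <- data.frame(day = days[-1], n_significant = NA_integer_)
  for (i in seq_along(days[-1])) {
    d <- days[-1][i]
    cur_ord <- order(replicate[day == d])
    cur <- matrix[day == d, , drop = FALSE][cur_ord, , drop = FALSE]
    diffs <- cur - base
    md <- colMeans(diffs)
    sdd <- apply(diffs, 2, stats::sd)
    tt <- ifelse(sdd == 0, ifelse(md == 0, 0, sign(md) * Inf),
                 md / (sdd / sqrt(n)))
    p <- ifelse(is.infinite(tt), 0,
                2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE))
    p_adj <- bh_adjust(p)
    tests[[i]] <- data.frame(day = d, feature_id = feature_ids(matrix),
                             t = tt, p = p, p_adj = p_adj,
                             stringsAsFactors = FALSE)
    counts$n_significant[i] <- sum(p_adj < alpha)
  }
  structure(list(tests = do.call(rbind, c(tests, make.row.names = FALSE)),
                 counts = counts),
            class = "pairwise_result")
}
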