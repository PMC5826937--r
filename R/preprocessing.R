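#' K-nearest-neighbour imputation of missing intensities
#'
#' Each missing cell is replaced by the inverse-distance-weighted mean
#' of the feature's values in the `k` nearest samples (the classical
#' KNN-imputation scheme), with distance the Euclidean distance over
#' co-observed features normalised by the number of co-observed features
#' (so samples with different missingness patterns are comparable). A
#' neighbour at distance zero — a duplicate sample — therefore donates
#' its value outright at any `k`. Observed cells are never touched.
#'
#' @param matrix Numeric samples x features matrix with `NA` for missing.
#' @param k Number of neighbours (default 10).
#' @return The completed matrix.
#' @export
impute_knn <- function(matrix, k = 10) {
  stopifnot(k >= 1)
  if (!anyNA(matrix)) return(matrix)
  if (any(colSums(!is.na(matrix)) == 0))
    stop("feature(s) missing in all samples; filter them before imputing")
  if (any(rowSums(!is.na(matrix)) == 0))
    stop("sample(s) with no observed values")
  n <- nrow(matrix)
  obs <- !is.na(matrix)
  # normalised squared distances: mean over co-observed features
  x0 <- matrix; x0[!obs] <- 0
  co <- obs %*% t(obs)                       # co-observed feature counts
  sq <- x0^2
  cross <- x0 %*% t(x0)
  ssq <- sq %*% t(obs)                       # sum of x_i^2 over j-observed
  d2 <- (ssq + t(ssq) - 2 * cross) / pmax(co, 1)
  d2[co == 0] <- Inf
  diag(d2) <- Inf

  out <- matrix
  need <- which(!obs, arr.ind = TRUE)
  for (r in seq_len(nrow(need))) {
    i <- need[r, 1]; j <- need[r, 2]
    donors <- which(obs[, j])
    dd <- d2[i, donors]
    usable <- donors[is.finite(dd)]
    if (!length(usable))
      stop("no usable neighbour for sample ", rownames(matrix)[i],
           ", feature ", colnames(matrix)[j])
    ord <- usable[order(d2[i, usable], usable)]
    nn <- ord[seq_len(min(k, length(ord)))]
    dd <- sqrt(d2[i, nn])
    out[i, j] <- if (any(dd == 0)) mean(matrix[nn[dd == 0], j]) else
      sum(matrix[nn, j] / dd) / sum(1 / dd)
  }
  out
}

#' Normalise each sample to constant sum
#'
#' Divides every sample row by its total intensity so rows sum to one,
#' removing between-sample differences in total signal (injection volume,
#' overall concentration).
#'
#' @param matrix Complete numeric samples x features matrix.
#' @return Row-normalised matrix.
#' @export
normalize_constant_sum <- function(matrix) {
  rs <- rowSums(matrix)
  if (any(!is.finite(rs) | rs <= 0)) {
    bad <- rownames(matrix)[which(!is.finite(rs) | rs <= 0)]
    if (is.null(bad)) bad <- which(!is.finite(rs) | rs <= 0)
    stop("non-positive total intensity for sample(s): ",
         paste(bad, collapse = ", "))
  }
  matrix / rs
}

#' Generalised log transformation
#'
#' Applies the variance-stabilising transform
#' \deqn{g(x) = \log_2\big((x + \sqrt{x^2 + a^2})/2\big),}
#' which behaves like `log2(x)` for large `x` but remains finite at zero.
#'
#' @param matrix Numeric matrix (non-negative intensities).
#' @param a Transform parameter, `a > 0`; controls where the transform
#'   flattens out at low intensity.
#' @return Transformed matrix.
#' @export
glog_transform <- function(matrix, a = 1) {
  if (!is.numeric(a) || length(a) != 1 || a <= 0)
    stop("glog parameter 'a' must be a single positive number")
  log2((matrix + sqrt(matrix^2 + a^2)) / 2)
}

#' Autoscale (unit-variance scale) each feature
#'
#' Centres every feature column to mean zero and divides by its sample
#' standard deviation (n-1 convention), putting all features on the same
#' footing regardless of absolute abundance. Constant columns are
#' centred and left at zero with a warning.
#'
#' @param matrix Complete numeric samples x features matrix.
#' @return The scaled matrix with attributes `center` and `scale`
#'   (per-feature means and SDs) for inverse mapping.
#' @export
autoscale <- function(matrix) {
  ctr <- colMeans(matrix)
  sds <- apply(matrix, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning(sum(const), " constant feature column(s) left at zero ",
            "after centering")
    sds[const] <- 1
  }
  out <- sweep(sweep(matrix, 2, ctr), 2, sds, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sds
  out
}

#' Full preprocessing chain for the study-sample matrix
#'
#' Runs, in order: KNN imputation, constant-sum normalisation,
#' generalised log transform, autoscaling. The output matrix is complete
#' with every feature column at mean 0 / SD 1, which is the contract the
#' penalised regression solver relies on (it performs no internal
#' standardisation).
#'
#' @param matrix Samples x features matrix with `NA` for missing.
#' @param k Neighbours for [impute_knn()].
#' @param glog_a Parameter of [glog_transform()], applied on the
#'   constant-sum-normalised scale.
#' @param impute_first If `FALSE`, normalisation runs before imputation
#'   (sensitivity-analysis variant; the default order imputes first).
#' @return List of class `preprocessed_matrix` with `values` (the scaled
#'   matrix) and `provenance` (k, glog a, per-feature centers/scales).
#' @export
preprocess_matrix <- function(matrix, k = 10, glog_a = 1,
                              impute_first = TRUE) {
  if (impute_first) {
    m <- impute_knn(matrix, k = k)
    m <- normalize_constant_sum(m)
  } else {
    rs <- rowSums(matrix, na.rm = TRUE)
    if (any(rs <= 0)) stop("non-positive total intensity in a sample")
    m <- impute_knn(matrix / rs, k = k)
  }
  m <- glog_transform(m, a = glog_a)
  m <- autoscale(m)
  structure(list(values = m,
                 provenance = list(knn_k = k, glog_a = glog_a,
                                   normalization = "constant_sum",
                                   impute_first = impute_first,
                                   center = attr(m, "center"),
                                   scale = attr(m, "scale"))),
            class = "preprocessed_matrix")
}

#' @export
print.preprocessed_matrix <- function(x, ...) {
  cat("preprocessed_matrix:", nrow(x$values), "samples x",
      ncol(x$values), "features (imputed, constant-sum, glog a =",
      x$provenance$glog_a, ", autoscaled)\n")
  invisible(x)
}
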