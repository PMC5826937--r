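#' Convert exact zeros to missing values
#'
#' Deconvolution software reports unintegrated peaks as zero intensity;
#' these are absences, not measurements, and are recoded as missing
#' before any statistic is computed.
#'
#' @param table A [feature_table()].
#' @return The table with every exact-zero intensity replaced by `NA`;
#'   all other cells unchanged.
#' @export
zeros_to_missing <- function(table) {
  ints <- table$intensities
  ints[!is.na(ints) & ints == 0] <- NA_real_
  table$intensities <- ints
  table
}

new_filter_report <- function(stage, feature_id, statistic, decision,
                              reason = NA_character_) {
  stopifnot(decision %in% c("retained", "removed"))
  data.frame(feature_id = feature_id, stage = stage,
             statistic = statistic, decision = decision,
             reason = reason, stringsAsFactors = FALSE)
}

#' Filter features by QC dilution-series response
#'
#' Genuine analytes scale with the concentration of the diluted QC
#' sample; background noise does not. Per feature, the squared Pearson
#' correlation between raw intensity and relative concentration is
#' computed over the QC-dilution samples (missing values dropped
#' pairwise). A feature is retained when r-squared exceeds the threshold
#' *and* the correlation is positive (intensity increasing with
#' concentration); anything else is background.
#'
#' @param table A [feature_table()] containing at least 3 `qc_dilution`
#'   samples with distinct dilution factors.
#' @param r2_threshold Retention threshold on r-squared (strict `>`).
#' @return A filter report data frame (feature_id, stage, statistic,
#'   decision, reason). Features with fewer than 3 usable dilution points
#'   are removed with reason `"insufficient_dilution_data"`.
#' @export
filter_dilution_response <- function(table, r2_threshold = 0.5) {
  idx <- table$samples$role == "qc_dilution"
  conc <- table$samples$dilution_factor[idx]
  if (length(unique(conc)) < 3)
    stop("need >= 3 qc_dilution samples with distinct dilution factors")
  mat <- table$intensities[idx, , drop = FALSE]
  p <- ncol(mat)
  r2 <- numeric(p); keep <- logical(p); reason <- rep(NA_character_, p)
  for (j in seq_len(p)) {
    ok <- !is.na(mat[, j])
    if (sum(ok) < 3 || length(unique(conc[ok])) < 3) {
      r2[j] <- NA_real_; keep[j] <- FALSE
      reason[j] <- "insufficient_dilution_data"
      next
    }
    sdx <- stats::sd(mat[ok, j])
    if (sdx == 0) { r2[j] <- 0; keep[j] <- FALSE; next }
    r <- stats::cor(mat[ok, j], conc[ok])
    r2[j] <- r^2
    keep[j] <- (r > 0) && (r^2 > r2_threshold)
  }
  new_filter_report("dilution", table$features$feature_id, r2,
                    ifelse(keep, "retained", "removed"), reason)
}

#' Filter features by QC replicate coefficient of variation
#'
#' Repeated injections of the same pooled QC sample measure pure
#' technical variability; a feature whose %CV over the QC replicates
#' exceeds the threshold is not measured reproducibly enough to analyse.
#' %CV = 100 * sample SD / mean (n-1 convention), missing values dropped.
#' The inequality is strict: %CV exactly at the threshold is retained.
#'
#' @param table A [feature_table()] with at least 2 undiluted `qc`
#'   samples.
#' @param cv_threshold Removal threshold in percent (strict `>`).
#' @return A filter report data frame for stage `"qc_cv"`. Features with
#'   fewer than 2 non-missing QC values or non-positive QC mean are
#'   removed with an explanatory reason.
#' @export
filter_qc_cv <- function(table, cv_threshold = 30) {
  idx <- table$samples$role == "qc"
  if (sum(idx) < 2) stop("need >= 2 qc replicate samples")
  mat <- table$intensities[idx, , drop = FALSE]
  p <- ncol(mat)
  cv <- rep(NA_real_, p); keep <- logical(p); reason <- rep(NA_character_, p)
  for (j in seq_len(p)) {
    x <- mat[!is.na(mat[, j]), j]
    if (length(x) < 2) { reason[j] <- "insufficient_qc_data"; next }
    m <- mean(x)
    if (m <= 0) { reason[j] <- "nonpositive_qc_mean"; next }
    cv[j] <- 100 * stats::sd(x) / m
    keep[j] <- cv[j] <= cv_threshold
  }
  new_filter_report("qc_cv", table$features$feature_id, cv,
                    ifelse(keep, "retained", "removed"), reason)
}

#' Filter features by missing-value fraction
#'
#' The missing fraction is computed over the quantified samples (study
#' and undiluted QC; blanks and the dilution series are excluded).
#' Strictly more than `max_missing` missing removes the feature; exactly
#' at the threshold is retained.
#'
#' @param table A [feature_table()].
#' @param max_missing Maximum tolerated missing fraction (strict `>`).
#' @return A filter report data frame for stage `"missingness"`.
#' @export
filter_missingness <- function(table, max_missing = 0.20) {
  idx <- table$samples$role %in% c("study", "qc")
  mat <- table$intensities[idx, , drop = FALSE]
  frac <- colMeans(is.na(mat))
  new_filter_report("missingness", table$features$feature_id, frac,
                    ifelse(frac <= max_missing, "retained", "removed"))
}

#' Run the full QC filter chain
#'
#' Applies, in order: zero-to-missing conversion, the dilution-response
#' filter, the QC %CV filter, and the missingness filter. Each stage sees
#' only the features retained by the previous stage.
#'
#' @param table A [feature_table()].
#' @param r2_threshold,cv_threshold,max_missing Stage thresholds; see the
#'   individual filters.
#' @return List of class `qc_filter_result` with `table` (filtered),
#'   `report` (row-bound per-stage reports), and `counts` (per-stage
#'   entered/retained/removed bookkeeping).
#' @export
apply_qc_filters <- function(table, r2_threshold = 0.5, cv_threshold = 30,
                             max_missing = 0.20) {
  table <- zeros_to_missing(table)
  reports <- list()
  counts <- list()
  stages <- list(
    dilution = function(t) filter_dilution_response(t, r2_threshold),
    qc_cv = function(t) filter_qc_cv(t, cv_threshold),
    missingness = function(t) filter_missingness(t, max_missing))
  for (stage in names(stages)) {
    rep_j <- stages[[stage]](table)
    reports[[stage]] <- rep_j
    kept <- rep_j$feature_id[rep_j$decision == "retained"]
    counts[[stage]] <- data.frame(stage = stage,
                                  entered = nrow(rep_j),
                                  retained = length(kept),
                                  removed = nrow(rep_j) - length(kept))
    table <- ft_keep_features(table, kept)
  }
  structure(list(table = table,
                 report = do.call(rbind, c(reports, make.row.names = FALSE)),
                 counts = do.call(rbind, c(counts, make.row.names = FALSE))),
            class = "qc_filter_result")
}

#' @export
print.qc_filter_result <- function(x, ...) {
  cat("QC filter chain:\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Write a filter report to TSV
#'
#' @param result A `qc_filter_result` from [apply_qc_filters()].
#' @param path Output file (`filter_report.tsv` convention).
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(result, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(result$counts)))
    writeLines(sprintf("# %s: entered=%d retained=%d removed=%d",
                       result$counts$stage[i], result$counts$entered[i],
                       result$counts$retained[i], result$counts$removed[i]),
               con)
  utils::write.table(result$report, con, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
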