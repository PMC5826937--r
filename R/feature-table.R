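#' Assemble a feature table
#'
#' The central container of the package: a samples x features intensity
#' matrix together with sample metadata and feature metadata. Missing
#' intensities are `NA`. Features are named by the conventional
#' `rt_mz` convention (retention time, underscore, mass-to-charge).
#'
#' @param intensities Numeric matrix, rows = samples, columns = features.
#'   Row names must match `samples$sample_id`, column names
#'   `features$feature_id`. Values are non-negative or `NA`.
#' @param samples Data frame with columns `sample_id`, `role` (one of
#'   `"study"`, `"qc"`, `"qc_dilution"`, `"blank"`), `storage_day`
#'   (integer days, `NA` unless role is `"study"`), `replicate`,
#'   `dilution_factor` (relative concentration in (0, 1], `NA` unless role
#'   is `"qc_dilution"`) and `mode` (`"pos"` or `"neg"`).
#' @param features Data frame with columns `feature_id`, `rt_min`, `mz`,
#'   `mode`.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `intensities`, `samples`, `features`.
#' @export
feature_table <- function(intensities, samples, features) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)

  if (anyDuplicated(features$feature_id))
    stop("feature ids must be unique")
  if (anyDuplicated(samples$sample_id))
    stop("sample ids must be unique")
  if (nrow(intensities) != nrow(samples))
    stop("intensity rows (", nrow(intensities), ") != samples (",
         nrow(samples), ")")
  if (ncol(intensities) != nrow(features))
    stop("intensity columns (", ncol(intensities), ") != features (",
         nrow(features), ")")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- samples$sample_id
  if (is.null(colnames(intensities)))
    colnames(intensities) <- features$feature_id
  if (!identical(rownames(intensities), as.character(samples$sample_id)))
    stop("intensity row names do not match sample ids")
  if (!identical(colnames(intensities), as.character(features$feature_id)))
    stop("intensity column names do not match feature ids")
  if (any(intensities < 0, na.rm = TRUE))
    stop("negative intensities are not allowed")

  bad_role <- setdiff(unique(samples$role),
                      c("study", "qc", "qc_dilution", "blank"))
  if (length(bad_role))
    stop("unknown sample role(s): ", paste(bad_role, collapse = ", "))

  is_study <- samples$role == "study"
  if (any(is_study & is.na(samples$storage_day)))
    stop("study samples must carry a storage_day")
  if (any(!is_study & !is.na(samples$storage_day)))
    stop("storage_day must be NA for non-study samples")
  is_dil <- samples$role == "qc_dilution"
  if (any(is_dil & is.na(samples$dilution_factor)))
    stop("qc_dilution samples must carry a dilution_factor")
  if (any(!is_dil & !is.na(samples$dilution_factor)))
    stop("dilution_factor must be NA for non qc_dilution samples")
  df <- samples$dilution_factor[is_dil]
  if (any(df <= 0 | df > 1))
    stop("dilution factors must lie in (0, 1]")

  structure(list(intensities = intensities,
                 samples = samples,
                 features = features),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$intensities), "samples x",
      ncol(x$intensities), "features\n")
  tab <- table(x$samples$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  nmiss <- sum(is.na(x$intensities))
  cat("  missing cells:", nmiss,
      sprintf("(%.1f%%)\n", 100 * nmiss / length(x$intensities)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Restrict a feature table to a subset of features
#'
#' @param table A `feature_table`.
#' @param feature_ids Character vector of feature ids to keep (order kept
#'   as in the table).
#' @return A `feature_table` with only the requested features.
#' @export
ft_keep_features <- function(table, feature_ids) {
  keep <- table$features$feature_id %in% feature_ids
  feature_table(table$intensities[, keep, drop = FALSE],
                table$samples,
                table$features[keep, , drop = FALSE])
}

#' Extract the study-sample intensity matrix and its time design
#'
#' Returns the intensities of the study samples ordered by storage day
#' then replicate, together with the day and replicate labels used by the
#' statistical stages.
#'
#' @param table A `feature_table`.
#' @return List with `values` (samples x features matrix), `day` (integer
#'   vector) and `replicate` (vector of replicate ids).
#' @export
ft_study_matrix <- function(table) {
  idx <- which(table$samples$role == "study")
  ord <- idx[order(table$samples$storage_day[idx],
                   table$samples$replicate[idx])]
  list(values = table$intensities[ord, , drop = FALSE],
       day = table$samples$storage_day[ord],
       replicate = table$samples$replicate[ord])
}

#' Write a feature table to a directory
#'
#' Writes the on-disk trio `intensities.csv` (rows = sample_id, columns =
#' feature_id, empty cell = missing), `samples.csv` and `features.csv`.
#'
#' @param table A `feature_table`.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_feature_table <- function(table, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ints <- data.frame(sample_id = rownames(table$intensities),
                     table$intensities, check.names = FALSE)
  utils::write.csv(ints, file.path(dir, "intensities.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(table$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(table$features, file.path(dir, "features.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param dir Directory containing `intensities.csv`, `samples.csv`,
#'   `features.csv`.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(dir) {
  ints <- utils::read.csv(file.path(dir, "intensities.csv"),
                          check.names = FALSE,
                          colClasses = c(sample_id = "character"))
  samples <- utils::read.csv(file.path(dir, "samples.csv"),
                             colClasses = c(sample_id = "character"),
                             stringsAsFactors = FALSE)
  features <- utils::read.csv(file.path(dir, "features.csv"),
                              colClasses = c(feature_id = "character"),
                              stringsAsFactors = FALSE)
  m <- as.matrix(ints[, -1, drop = FALSE])
  rownames(m) <- ints$sample_id
  feature_table(m, samples, features)
}
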