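test_that("zeros_to_missing converts exactly the zero cells", {
  tab <- tiny_table()
  expect_identical(zeros_to_missing(tab), tab)   # no zeros: identity

  ints <- tab$intensities
  ints["S_d00_r01", "f2"] <- 0
  tab0 <- tiny_table(ints)
  out <- zeros_to_missing(tab0)
  expect_true(is.na(out$intensities["S_d00_r01", "f2"]))
  out$intensities["S_d00_r01", "f2"] <- ints["S_d00_r01", "f2"] <- 99
  expect_identical(out$intensities, ints)        # all other cells bitwise

  ints <- tab$intensities
  ints[1:4, "f3"] <- 0                            # 4 zeros among study rows
  conv <- zeros_to_missing(tiny_table(ints))
  study <- conv$intensities[conv$samples$role == "study", "f3"]
  expect_equal(mean(is.na(study)), 4 / 6)
})

test_that("dilution filter keeps linear responders and drops flat features", {
  tab <- tiny_table()
  ints <- tab$intensities
  conc <- c(1, 0.2, 0.1, 0.02)
  ints[10:13, "f1"] <- 500 * conc           # exactly proportional
  ints[10:13, "f2"] <- 80                   # constant across dilutions
  ints[10:13, "f3"] <- c(100, 30, 12, 4)    # decided by the r2 value
  ints[10:13, "f4"] <- rev(200 * conc)      # anti-correlated
  rep <- filter_dilution_response(tiny_table(ints), r2_threshold = 0.5)

  expect_equal(rep$decision[rep$feature_id == "f1"], "retained")
  expect_equal(rep$statistic[rep$feature_id == "f1"], 1)
  expect_equal(rep$decision[rep$feature_id == "f2"], "removed")
  expect_equal(rep$statistic[rep$feature_id == "f2"], 0)
  # oracle: plain Pearson correlation on the four points
  r_ref <- cor(c(100, 30, 12, 4), conc)
  expect_equal(rep$statistic[rep$feature_id == "f3"], r_ref^2)
  expect_equal(rep$decision[rep$feature_id == "f3"],
               if (r_ref > 0 && r_ref^2 > 0.5) "retained" else "removed")
  # responds to dilution but in the wrong direction: background
  expect_equal(rep$decision[rep$feature_id == "f4"], "removed")
})

test_that("dilution filter flags features without enough usable points", {
  tab <- tiny_table()
  ints <- tab$intensities
  ints[10:12, "f1"] <- NA
  rep <- filter_dilution_response(tiny_table(ints))
  expect_equal(rep$decision[rep$feature_id == "f1"], "removed")
  expect_equal(rep$reason[rep$feature_id == "f1"],
               "insufficient_dilution_data")
})

test_that("QC %CV filter uses the n-1 SD and a strict threshold", {
  tab <- tiny_table()
  ints <- tab$intensities
  ints[7:9, "f1"] <- c(100, 100, 100)   # %CV 0
  ints[7:9, "f2"] <- c(40, 100, 160)    # mean 100, sd 60, %CV 60
  # %CV exactly 30: sd/mean = 0.3; sd({a-d,a,a+d}) = d
  ints[7:9, "f3"] <- c(100 - 30, 100, 100 + 30)
  rep <- filter_qc_cv(tiny_table(ints), cv_threshold = 30)
  expect_equal(rep$decision[rep$feature_id == "f1"], "retained")
  expect_equal(rep$statistic[rep$feature_id == "f2"], 60)
  expect_equal(rep$decision[rep$feature_id == "f2"], "removed")
  expect_equal(rep$statistic[rep$feature_id == "f3"], 30)
  expect_equal(rep$decision[rep$feature_id == "f3"], "retained")
})

test_that("missingness filter is strict at the threshold", {
  tab <- tiny_table()
  ints <- tab$intensities
  # 9 quantified samples (6 study + 3 qc) in the tiny table: use a bigger
  # synthetic table for clean tenths
  sim <- generate_experiment(synthetic_config(n_features = 30,
                                              qc_n_injections = 10,
                                              n_replicates = 5,
                                              n_timepoints = 2,
                                              n_increasing = 2,
                                              n_decreasing = 2,
                                              n_erratic = 2,
                                              missing_rate = 0, seed = 8))
  ints <- sim$table$intensities
  quant <- sim$table$samples$role %in% c("study", "qc")
  f <- colnames(ints)[1:3]
  ints[which(quant)[1:6], f[1]] <- NA    # 6/20 = 30% missing
  ints[which(quant)[1:4], f[2]] <- NA    # 4/20 = 20% missing
  tab <- feature_table(ints, sim$table$samples, sim$table$features)
  rep <- filter_missingness(tab, max_missing = 0.20)
  expect_equal(rep$decision[rep$feature_id == f[1]], "removed")
  expect_equal(rep$decision[rep$feature_id == f[2]], "retained")
  expect_equal(rep$decision[rep$feature_id == f[3]], "retained")
})

test_that("filter chain is ordered and its bookkeeping is exact", {
  sim <- generate_experiment(synthetic_config(n_features = 400, seed = 17))
  res <- apply_qc_filters(sim$table)
  expect_equal(res$counts$stage, c("dilution", "qc_cv", "missingness"))
  expect_equal(res$counts$entered[1], 400)
  expect_equal(res$counts$entered[-1], head(res$counts$retained, -1))
  expect_equal(ncol(res$table$intensities), tail(res$counts$retained, 1))
  expect_equal(res$counts$entered, res$counts$retained + res$counts$removed)
  # each stage's report covers exactly the features that reached it
  for (i in seq_len(nrow(res$counts)))
    expect_equal(sum(res$report$stage == res$counts$stage[i]),
                 res$counts$entered[i])
  # background features should fall at the dilution stage
  dil <- res$report[res$report$stage == "dilution", ]
  bg <- sim$truth$feature_id[sim$truth$class == "background"]
  expect_gt(mean(dil$decision[dil$feature_id %in% bg] == "removed"), 0.9)
  noisy <- sim$truth$feature_id[sim$truth$class == "noisy_qc"]
  cvs <- res$report[res$report$stage == "qc_cv", ]
  expect_gt(mean(cvs$decision[cvs$feature_id %in% noisy] == "removed"), 0.9)
})

test_that("decisions are invariant to sample order and feature scaling", {
  sim <- generate_experiment(small_synthetic_config(60, seed = 23))
  res <- apply_qc_filters(sim$table)

  perm <- sample(nrow(sim$table$intensities))
  tab_perm <- feature_table(sim$table$intensities[perm, , drop = FALSE],
                            sim$table$samples[perm, , drop = FALSE],
                            sim$table$features)
  res_perm <- apply_qc_filters(tab_perm)
  expect_equal(res_perm$report$decision, res$report$decision)

  ints <- sim$table$intensities
  ints[, 1] <- ints[, 1] * 7.3
  res_scaled <- apply_qc_filters(feature_table(ints, sim$table$samples,
                                               sim$table$features))
  expect_equal(res_scaled$report$decision, res$report$decision)
  expect_equal(res_scaled$report$statistic, res$report$statistic,
               tolerance = 1e-12)
})
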