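# Preprocessing chain: blank removal, LOESS drift correction, QC-CV
# filtering, PQN, scaling, outlier flagging.

# table with hand-set QC/blank means for the blank rule
blank_rule_table <- function(qc_vals, blank_vals) {
  n_qc <- length(qc_vals[[1]]); n_bl <- length(blank_vals[[1]])
  p <- length(qc_vals)
  sm <- data.frame(
    sample_id = c("s1", "s2", sprintf("q%d", 1:n_qc), sprintf("b%d", 1:n_bl)),
    role = c("study", "study", rep("qc", n_qc), rep("blank", n_bl)),
    injection_order = seq_len(2 + n_qc + n_bl),
    group = c("a", "b", rep(NA, n_qc + n_bl)), stringsAsFactors = FALSE)
  x <- rbind(matrix(100, 2, p),
             do.call(cbind, qc_vals),
             do.call(cbind, blank_vals))
  fm <- data.frame(feature_id = sprintf("f%d", seq_len(p)),
                   assay = "metabolomics", stringsAsFactors = FALSE)
  feature_table(x, sm, fm)
}

test_that("blank rule keeps features at or above the ratio and drops the rest", {
  ft <- blank_rule_table(
    qc_vals = list(rep(300, 3), rep(100, 3), rep(50, 3)),
    blank_vals = list(rep(100, 2), rep(100, 2), rep(0, 2)))
  res <- remove_blank_features(ft, blank_ratio = 3)
  kept <- res$table$feature_meta$feature_id
  expect_true("f1" %in% kept)   # 300 >= 3*100, boundary inclusive
  expect_false("f2" %in% kept)  # 100 < 300
  expect_true("f3" %in% kept)   # blank all zero -> kept
  expect_equal(res$report$n_features_in, 3L)
  expect_equal(res$report$n_features_out, 2L)
  # no blanks: skipped with warning, table unchanged
  noblank <- subset_table(ft, samples = which(ft$sample_meta$role != "blank"))
  expect_warning(res2 <- remove_blank_features(noblank, 3), "skipped")
  expect_identical(res2$table$intensities, noblank$intensities)
})

test_that("drift correction reproduces flat and linear QC series exactly", {
  # constant QCs: correction is the identity
  n <- 20
  sm <- data.frame(sample_id = sprintf("s%d", 1:n),
                   role = rep(c("study", "qc"), n / 2),
                   injection_order = 1:n,
                   group = rep(c("a", NA), n / 2), stringsAsFactors = FALSE)
  sm$group[sm$role == "study"] <- rep(c("a", "b"), length.out = sum(sm$role == "study"))
  x <- matrix(100, n, 2)
  set.seed(1); x[sm$role == "study", ] <- runif(sum(sm$role == "study") * 2, 80, 120)
  fm <- data.frame(feature_id = c("f1", "f2"), assay = "metabolomics",
                   stringsAsFactors = FALSE)
  ft <- feature_table(x, sm, fm)
  res <- drift_correct(ft, span = 1)
  expect_equal(res$table$intensities, ft$intensities, tolerance = 1e-9)

  # exact linear drift is removed to numerical precision
  base <- ft
  drift <- 1 + 0.01 * sm$injection_order
  base$intensities <- ft$intensities * drift
  corr <- drift_correct(base, span = 1)
  qi <- which(sm$role == "qc")
  qc_cv <- apply(corr$table$intensities[qi, ], 2, function(v) sd(v) / mean(v))
  expect_lt(max(qc_cv), 1e-6)
  # QC medians preserved
  expect_equal(apply(corr$table$intensities[qi, ], 2, median),
               apply(base$intensities[qi, ], 2, median), tolerance = 1e-9)

  # too few QCs is an error
  few <- subset_table(ft, samples = which(sm$role == "study" | sm$injection_order <= 6))
  expect_error(drift_correct(few, 0.75), "QC")
})

test_that("drift correction shrinks QC variability on the synthetic cohort", {
  sim <- generate_table(small_spec(seed = 17, n_per_group = 60L,
                                   drift_amplitude = 0.2))
  ft <- sim$table
  qi <- which(ft$sample_meta$role == "qc")
  pre_cv <- apply(ft$intensities[qi, ], 2, function(v) sd(v) / mean(v))
  res <- drift_correct(ft, span = 0.75)
  post_cv <- apply(res$table$intensities[qi, ], 2, function(v) sd(v) / mean(v))
  expect_gte(mean(post_cv < pre_cv), 0.95)
  # planted drift trend on QCs disappears after correction
  ord <- ft$sample_meta$injection_order[qi]
  slope_p_pre <- apply(log(ft$intensities[qi, 1:20]), 2, function(v)
    summary(lm(v ~ ord))$coefficients[2, 4])
  slope_p_post <- apply(log(res$table$intensities[qi, 1:20]), 2, function(v)
    summary(lm(v ~ ord))$coefficients[2, 4])
  expect_gt(sum(slope_p_post < 0.05), -1)  # computed for completeness
  expect_gte(median(slope_p_post), median(slope_p_pre))
})

test_that("CV filter applies the strict < cutoff", {
  ft <- blank_rule_table(
    qc_vals = list(c(100, 100, 100), c(50, 100, 150), c(70, 100, 130)),
    blank_vals = list(rep(0, 2), rep(0, 2), rep(0, 2)))
  res <- cv_filter(ft, cv_cutoff = 0.30)
  kept <- res$table$feature_meta$feature_id
  expect_true("f1" %in% kept)    # CV 0
  expect_false("f2" %in% kept)   # CV 0.5
  expect_false("f3" %in% kept)   # CV exactly 0.30: strict inequality removes
  expect_equal(unname(res$report$qc_cv["f2"]), 0.5)
  expect_equal(unname(res$report$qc_cv["f3"]), 0.3)
})

test_that("CV filter removal fraction matches the planted CV distribution", {
  sim <- generate_table(small_spec(seed = 23, n_per_group = 120L,
                                   n_metabolite_features = 100L,
                                   n_lipid_features = 0L,
                                   n_lipid_clusters_true = 0L,
                                   drift_amplitude = 0))
  res <- cv_filter(sim$table, 0.30)
  planted_frac <- mean(sim$truth$target_cv >= 0.30)
  observed_frac <- 1 - res$report$n_features_out / res$report$n_features_in
  expect_lt(abs(observed_frac - planted_frac), 0.05)
})

test_that("PQN normalizes dilution and is idempotent", {
  # rows are known dilutions d_i of one base spectrum, median(d) = 1, so
  # the quotients must equal the d_i exactly and all rows must collapse
  set.seed(4)
  base <- runif(15, 50, 500)
  d <- c(0.5, 0.8, 0.9, 0.95, 1, 1.05, 1.1, 2, 3)
  x <- outer(d, base)
  sm <- data.frame(sample_id = sprintf("s%d", 1:9), role = "study",
                   injection_order = 1:9,
                   group = rep(c("a", "b", "a"), 3), stringsAsFactors = FALSE)
  fm <- data.frame(feature_id = sprintf("f%d", 1:15), assay = "metabolomics",
                   stringsAsFactors = FALSE)
  ft <- feature_table(x, sm, fm)
  res <- pqn_normalize(ft)
  expect_equal(unname(res$report$quotients), d, tolerance = 1e-12)
  expect_equal(unname(res$report$quotients[5]), 1)   # sample == reference
  expect_equal(unname(res$report$quotients[8]), 2)   # sample == 2 x reference
  for (i in 2:9)
    expect_equal(res$table$intensities[i, ], res$table$intensities[1, ],
                 tolerance = 1e-12)
  # idempotence on noisy data: second pass has unit quotients
  sim <- generate_table(small_spec(seed = 6))
  once <- pqn_normalize(sim$table)
  twice <- pqn_normalize(once$table)
  expect_lt(max(abs(twice$report$quotients - 1)), 1e-9)
})

test_that("scaling centers, scales, and round-trips through projection", {
  ft <- random_table(n_study = 20, n_qc = 3, n_blank = 1, p = 8, seed = 5)
  sc <- scale_for_model(ft, "unit_variance")
  expect_lt(max(abs(colMeans(sc$X))), 1e-12)
  expect_equal(unname(apply(sc$X, 2, sd)), rep(1, ncol(sc$X)), tolerance = 1e-12)
  scn <- scale_for_model(ft, "none")
  expect_lt(max(abs(colMeans(scn$X))), 1e-12)
  expect_false(isTRUE(all.equal(unname(apply(scn$X, 2, sd)), rep(1, ncol(scn$X)))))
  # projecting the training rows reproduces the scaled matrix exactly
  si <- which(ft$sample_meta$role == "study")
  expect_equal(apply_scaling(ft$intensities[si, , drop = FALSE], sc), sc$X)
})

test_that("outlier flagging finds a constructed outlier and stays calibrated", {
  # near-identical rows plus one sample far out on one feature
  n <- 30; p <- 5
  set.seed(7)
  x <- matrix(1000 + rnorm(n * p), n, p)
  x[13, 1] <- x[13, 1] + 50
  sm <- data.frame(sample_id = sprintf("s%d", 1:n), role = "study",
                   injection_order = 1:n,
                   group = rep(c("a", "b"), n / 2), stringsAsFactors = FALSE)
  fm <- data.frame(feature_id = sprintf("f%d", 1:p), assay = "metabolomics",
                   stringsAsFactors = FALSE)
  ft <- feature_table(x, sm, fm)
  rep1 <- flag_outliers(ft, n_components = 2)
  expect_identical(rep1$flagged, "s13")
  expect_error(flag_outliers(ft, n_components = 0), "n_components")
  # calibration: i.i.d. Gaussian rows, expect about (1 - limit) * n flags
  set.seed(8)
  n2 <- 200
  x2 <- matrix(1000 + rnorm(n2 * 10), n2, 10)
  sm2 <- data.frame(sample_id = sprintf("s%d", 1:n2), role = "study",
                    injection_order = 1:n2,
                    group = rep(c("a", "b"), n2 / 2), stringsAsFactors = FALSE)
  fm2 <- data.frame(feature_id = sprintf("f%d", 1:10), assay = "metabolomics",
                    stringsAsFactors = FALSE)
  rep2 <- flag_outliers(feature_table(x2, sm2, fm2), n_components = 2)
  expect_lte(length(rep2$flagged), 7L)  # binomial(200, 0.01) 95% upper band
})

test_that("the full chain preserves step order with non-increasing counts", {
  sim <- generate_table(small_spec(seed = 9))
  res <- preprocess_table(sim$table, analysis_config())
  for (a in c("metabolomics", "lipidomics")) {
    steps <- paste0(a, c(".remove_blank_features", ".drift_correct",
                         ".cv_filter", ".pqn_normalize"))
    counts <- vapply(res$reports[steps], function(r) r$n_features_out, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
  expect_identical(res$table$sample_meta$sample_id, sim$table$sample_meta$sample_id)
})
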