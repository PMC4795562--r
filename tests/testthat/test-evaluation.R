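test_that("stratified folds balance classes and are deterministic", {
  ids <- sprintf("u%03d", 1:100)
  strata <- rep(c("pos", "neg"), each = 50)
  folds <- stratified_kfold(ids, strata, k = 10, seed = 3)
  for (f in folds) {
    expect_length(f$test, 10L)
    expect_equal(sum(strata[match(f$test, ids)] == "pos"), 5L)
  }
  # test sets partition the units
  expect_setequal(unlist(lapply(folds, `[[`, "test")), ids)
  expect_equal(sum(lengths(lapply(folds, `[[`, "test"))), 100L)

  # 37/63 split: per-fold class counts within one of the exact share
  strata2 <- rep(c("pos", "neg"), c(37, 63))
  folds2 <- stratified_kfold(ids, strata2, k = 10, seed = 5)
  for (f in folds2) {
    np <- sum(strata2[match(f$test, ids)] == "pos")
    expect_true(abs(np - 3.7) < 1)
    expect_true(abs(length(f$test) - np - 6.3) < 1)
  }

  expect_identical(stratified_kfold(ids, strata, k = 10, seed = 3), folds)
  expect_error(stratified_kfold(ids[1:5], strata[1:5], k = 10),
               "k exceeds|at least k")
})

test_that("AUC matches hand examples and the Mann-Whitney tie rule", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  # 4 pos/neg pairs: 3 wins, 1 loss
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("rank AUC equals exhaustive pair counting on random instances", {
  withr::with_seed(17, {
    for (i in 1:50) {
      n <- sample(5:60, 1)
      scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      expect_equal(auc(scores, labels), brute_force_auc(scores, labels))
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(19, {
    for (i in 1:5) {
      s <- runif(50); y <- rbinom(50, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(auc(s, y), ref, tolerance = 1e-12)
    }
  })
})

test_that("ROC curves have the standard endpoints, monotonicity and area", {
  r <- roc_curve(c(0.9, 0.1), c(1, 0))
  expect_equal(r$fpr, c(0, 0, 1))
  expect_equal(r$tpr, c(0, 1, 1))

  withr::with_seed(23, {
    scores <- runif(80)             # tie-free almost surely
    labels <- rbinom(80, 1, 0.4)
    r2 <- roc_curve(scores, labels)
    expect_equal(r2$fpr[1], 0); expect_equal(r2$tpr[1], 0)
    expect_equal(r2$fpr[nrow(r2)], 1); expect_equal(r2$tpr[nrow(r2)], 1)
    expect_true(all(diff(r2$fpr) >= 0))
    expect_true(all(diff(r2$tpr) >= 0))
    expect_equal(roc_area(r2), auc(scores, labels), tolerance = 1e-12)

    # inverting labels reflects the curve through the diagonal
    r3 <- roc_curve(scores, 1 - labels)
    expect_equal(roc_area(r3), 1 - roc_area(r2), tolerance = 1e-12)
  })
})

test_that("rate-averaged ROC reduces to the single curve for identical folds", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  labels <- c(1, 1, 0, 1, 0, 0)
  folds <- rep(list(list(scores = scores, labels = labels)), 4)
  avg <- average_roc(folds, grid_size = 13)
  # zero-width bounds everywhere: every fold contributes the same curve
  expect_equal(avg$tpr_lo, avg$mean_tpr, tolerance = 1e-12)
  expect_equal(avg$tpr_hi, avg$mean_tpr, tolerance = 1e-12)
  # rate 0.5 -> 3 of 6 predicted positive: 2 TP of 3, 1 FP of 3
  at_half <- avg[abs(avg$rate - 0.5) < 1e-9, ]
  expect_equal(at_half$mean_tpr, 2 / 3)
  expect_equal(at_half$mean_fpr, 1 / 3)
  # endpoints
  expect_equal(avg$mean_tpr[1], 0); expect_equal(avg$mean_fpr[1], 0)
  expect_equal(avg$mean_tpr[nrow(avg)], 1)
  expect_equal(avg$mean_fpr[nrow(avg)], 1)
})

test_that("two hand-computable folds average to the interpolated means", {
  f1 <- list(scores = c(0.9, 0.6, 0.4, 0.1), labels = c(1, 1, 0, 0))
  f2 <- list(scores = c(0.8, 0.7, 0.3, 0.2), labels = c(1, 0, 1, 0))
  avg <- average_roc(list(f1, f2), grid_size = 5)
  # at rate 0.5 (two predicted positive): f1 TPR=1, FPR=0; f2 TPR=.5, FPR=.5
  at_half <- avg[abs(avg$rate - 0.5) < 1e-9, ]
  expect_equal(at_half$mean_tpr, (1 + 0.5) / 2)
  expect_equal(at_half$mean_fpr, (0 + 0.5) / 2)
  # bounds bracket the mean
  expect_true(all(avg$tpr_lo <= avg$mean_tpr + 1e-12))
  expect_true(all(avg$tpr_hi >= avg$mean_tpr - 1e-12))
})

test_that("count equalization is deterministic given the seed", {
  withr::with_seed(31, {
    folds <- lapply(1:3, function(i) {
      n <- c(8, 10, 12)[i]
      list(scores = runif(n), labels = rbinom(n, 1, 0.5))
    })
    for (f in seq_along(folds))
      if (length(unique(folds[[f]]$labels)) < 2)
        folds[[f]]$labels[1:2] <- c(0, 1)
  })
  a1 <- average_roc(folds, grid_size = 21, equalize_counts = TRUE, seed = 7)
  a2 <- average_roc(folds, grid_size = 21, equalize_counts = TRUE, seed = 7)
  expect_identical(a1, a2)
})

test_that("fold t-tests match the textbook formulas and flag degeneracy", {
  withr::with_seed(41, {
    a <- 0.9 + rnorm(10, 0, 0.01)
    b <- 0.8 + rnorm(10, 0, 0.01)
  })
  paired <- compare_auc(a, b, paired = TRUE)
  expect_false(paired$degenerate)
  expect_equal(paired$p_value, paired_t_oracle(a, b), tolerance = 1e-10)
  expect_lt(paired$p_value, 0.001)

  unpaired <- compare_auc(a, b, paired = FALSE)
  expect_equal(unpaired$p_value, welch_t_oracle(a, b), tolerance = 1e-10)

  same <- compare_auc(rep(0.9, 10), rep(0.9, 10), paired = TRUE)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
})

test_that("permutation p-values behave at the extremes and under the null", {
  scores <- c(rep(0.9, 5), rep(0.1, 5))
  labels <- c(rep(1, 5), rep(0, 5))
  p <- permutation_pvalue(scores, labels, B = 99, seed = 1)
  expect_equal(p$observed, 1.0)
  expect_equal(p$p_value, 1 / 100)

  withr::with_seed(51, {
    s <- runif(60); y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  })
  pn <- permutation_pvalue(s, y, B = 999, seed = 2)
  expect_gt(pn$p_value, 0.05)  # null data should not look significant

  expect_identical(permutation_pvalue(s, y, B = 199, seed = 9)$p_value,
                   permutation_pvalue(s, y, B = 199, seed = 9)$p_value)
})

test_that("calibration tables bin correctly and flag empty bins", {
  ct <- calibration_table(rep(0.8, 100), rep(c(1, 0), c(80, 20)))
  occ <- ct[ct$count > 0, ]
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$observed, 0.8)
  expect_equal(occ$mean_score, 0.8)

  ct0 <- calibration_table(c(0.1, 0.5, 0.9), c(0, 0, 0))
  expect_true(all(ct0$observed[ct0$count > 0] == 0))
  expect_true(all(is.na(ct0$observed[ct0$count == 0])))

  withr::with_seed(61, {
    s <- runif(10000)
    y <- rbinom(10000, 1, s)
  })
  ct2 <- calibration_table(s, y)
  occ2 <- ct2[ct2$count > 0, ]
  expect_lt(max(abs(occ2$observed - occ2$mean_score)), 0.05)
})
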