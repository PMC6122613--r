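test_that("CV engine records the configured evaluation structure", {
  f <- one_signal_features(seed = 2)
  cfg <- cv_config(n_repeats = 6, n_folds = 4, K = 5, seed = 10)
  cv <- balanced_repeated_cv(f$x, f$y, "cancer", cfg)
  expect_equal(nrow(cv$per_eval), 24L)
  # every balanced set holds the minority size per class
  expect_true(all(cv$class_counts == 24L))
  expect_true(all(cv$per_eval$mce >= 0 & cv$per_eval$mce <= 1))
  expect_true(all(cv$selection_frequency >= 0 &
                    cv$selection_frequency <= 1))
})

test_that("same master seed reproduces the full CV result", {
  f <- one_signal_features(seed = 5)
  cfg <- cv_config(n_repeats = 4, K = 5, ncomp = 2, seed = 77)
  a <- balanced_repeated_cv(f$x, f$y, "cancer", cfg)
  b <- balanced_repeated_cv(f$x, f$y, "cancer", cfg)
  expect_identical(a$per_eval, b$per_eval)
  expect_identical(a$selection_frequency, b$selection_frequency)
})

test_that("balanced folds satisfy the MCE/sensitivity/specificity identity", {
  f <- one_signal_features(seed = 3)
  cv <- balanced_repeated_cv(f$x, f$y, "cancer",
                             cv_config(n_repeats = 5, K = 5, ncomp = 2,
                                       seed = 4))
  # MCE = 1 - (sens + spec)/2 up to integer fold-size rounding
  resid <- with(cv$per_eval, mce - (1 - (sens + spec) / 2))
  expect_lt(max(abs(resid)), 0.05)
})

test_that("the designed signal region is selected in every evaluation", {
  f <- one_signal_features(seed = 6)
  cv <- balanced_repeated_cv(f$x, f$y, "cancer",
                             cv_config(n_repeats = 10, K = 5, ncomp = 2,
                                       seed = 8))
  expect_equal(unname(cv$selection_frequency["IR20"]), 1.0)
  # and classification succeeds well above chance
  expect_lt(cv$mce_mean, 0.3)
})

test_that("no leakage: test rows cannot influence their own model", {
  # poison one subject's feature values after training folds are fixed:
  # a model fitted without subject i must give the same prediction for the
  # original x_i whether or not x_i was perturbed in the stored table.
  f <- one_signal_features(seed = 9)
  x <- f$x
  fit_wo <- plslda(x[-1, , drop = FALSE], f$y[-1], K = 5, ncomp = 2)
  x_poison <- x
  x_poison[1, ] <- x_poison[1, ] * 100
  fit_wo2 <- plslda(x_poison[-1, , drop = FALSE], f$y[-1], K = 5, ncomp = 2)
  expect_identical(predict(fit_wo, x[1, , drop = FALSE]),
                   predict(fit_wo2, x[1, , drop = FALSE]))
})

test_that("label permutation drives mean CV error to chance", {
  f <- one_signal_features(seed = 12)
  set.seed(99)
  y_perm <- sample(f$y)
  cv <- balanced_repeated_cv(f$x, y_perm, "cancer",
                             cv_config(n_repeats = 20, K = 5, ncomp = 2,
                                       seed = 13))
  se <- sd(cv$per_eval$mce) / sqrt(nrow(cv$per_eval))
  expect_lt(abs(cv$mce_mean - 0.5), 3 * se + 0.02)
})

test_that("ablating the signal region strictly increases paired mean MCE", {
  f <- one_signal_features(seed = 14)
  cfg <- cv_config(n_repeats = 20, K = 5, ncomp = 2, seed = 15)
  full <- balanced_repeated_cv(f$x, f$y, "cancer", cfg)
  ablated <- ablation_cv(f$x, f$y, "IR20", "cancer", cfg)
  expect_gt(ablated$mce_mean, full$mce_mean)
  # signal gone: error approaches chance
  expect_gt(ablated$mce_mean, 0.35)

  # removing a background region leaves MCE unchanged within noise
  bg <- ablation_cv(f$x, f$y, "IR3", "cancer", cfg)
  expect_lt(abs(bg$mce_mean - full$mce_mean), 0.05)

  # empty removal set is the identity
  none <- ablation_cv(f$x, f$y, integer(0), "cancer", cfg)
  expect_identical(none$per_eval, full$per_eval)

  expect_error(ablation_cv(f$x, f$y, seq_len(ncol(f$x)), "cancer", cfg),
               "every feature")
  expect_error(ablation_cv(f$x, f$y, "IR999", "cancer", cfg), "unknown")
})

test_that("LOOCV attributes errors to stages and is exhaustive", {
  cfg <- one_signal_config(seed = 16, n_cancer = 24L, n_inflam = 16L,
                           n_ir = 12L)
  cfg$groups[[1]]$stage_distribution <- c(I = 8L, II = 8L, III = 8L)
  co <- normalize_total_area(generate_cohort(cfg, glutamate_ir = 5L))
  f <- cohort_features(co)
  res <- loocv_per_stage(f$x, f$y, f$stage, "cancer", K = 4, ncomp = 2,
                         seed = 21)
  expect_equal(res$n_eval, 32L)  # balanced 16 + 16
  expect_equal(sort(res$per_stage$stage), c("I", "II", "III"))
  expect_true(all(res$per_stage$mce >= 0 & res$per_stage$mce <= 1,
                  na.rm = TRUE))
  # separable toy data: zero error overall and per stage
  d <- toy_clouds(n = 12, shift = 6)
  st <- ifelse(d$y == "case", rep(c("I", "II"), 12), NA)
  r0 <- loocv_per_stage(d$x, d$y, st, "case", K = 2, ncomp = 1, seed = 1)
  expect_equal(unname(r0$overall["mce"]), 0)
  expect_true(all(r0$per_stage$mce == 0))
})

test_that("stage shuffling equalizes per-stage LOOCV error", {
  cfg <- one_signal_config(seed = 18, n_cancer = 24L, n_inflam = 16L,
                           n_ir = 12L)
  cfg$groups[[1]]$stage_distribution <- c(I = 12L, II = 12L)
  co <- normalize_total_area(generate_cohort(cfg, glutamate_ir = 5L))
  f <- cohort_features(co)
  set.seed(20)
  stage_shuffled <- f$stage
  idx <- which(!is.na(stage_shuffled))
  stage_shuffled[idx] <- sample(stage_shuffled[idx])
  res <- loocv_per_stage(f$x, f$y, stage_shuffled, "cancer", K = 4,
                         ncomp = 2, seed = 22)
  # under exchangeability the two stage MCEs differ by at most binomial noise
  p <- res$per_stage$mce
  n <- res$per_stage$n
  pooled <- sum(res$per_stage$errors) / sum(n)
  se <- sqrt(pooled * (1 - pooled) * sum(1 / n))
  expect_lt(abs(p[1] - p[2]), 3 * se + 1e-9)
})
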