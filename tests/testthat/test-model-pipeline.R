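# Pipeline unit tests run on deliberately small cohorts (scaled-down specs)
# so each block stays in the seconds range; the full reference conditions
# are exercised in the acceptance suite.

test_that("stratified folds preserve class proportions within one organism", {
  set.seed(71)
  for (i in 1:20) {
    n_pos <- sample(5:40, 1); n_neg <- sample(5:40, 1); k <- sample(2:10, 1)
    y <- factor(c(rep("probiotic", n_pos), rep("non-probiotic", n_neg)))
    fold <- probioscreen:::stratified_folds(y, k)
    for (f in seq_len(k)) {
      for (cl in levels(y)) {
        got <- sum(y[fold == f] == cl)
        expect_lte(abs(got - sum(y == cl) / k), 1)
      }
      expect_equal(length(unique(y[fold != f])), 2L)
    }
  }
})

test_that("preprocessing parameters come from the training part only", {
  x_tr <- data.frame(a = c(1, 2, 3, NA), b = c(10, 20, 30, 40))
  x_te <- data.frame(a = c(100, NA), b = c(0, 1000))
  pp <- probioscreen:::fit_preprocessor(x_tr)
  expect_equal(pp$median[["a"]], 2)        # training median, NA excluded
  z_te <- probioscreen:::apply_preprocessor(pp, x_te)
  # the test-set NA is filled with the TRAINING median then standardized
  expect_equal(z_te$a[2], (2 - pp$mean[["a"]]) / pp$sd[["a"]])
  # test-set values are scaled by training parameters, not refitted
  expect_equal(z_te$b, (x_te$b - pp$mean[["b"]]) / pp$sd[["b"]])
})

test_that("RFE recovers planted informative features and honours a trivial grid", {
  tab <- small_feature_table(seed = 72, n_pos = 12, n_neg = 10,
                             n_test_pos = 0, n_test_neg = 0)
  cfg <- pipeline_config(rfe_folds = 5, rfe_repeats = 2,
                         rfe_sizes = c(2, 4, 8, 16, 61),
                         rf_ntree = 200, seed = 1)
  rfe <- recursive_feature_selection(tab, cfg)
  expect_equal(rfe$profile$size, c(2, 4, 8, 16, 61))
  expect_true(all(rfe$profile$accuracy >= 0 & rfe$profile$accuracy <= 1))
  expect_gte(sum(trio_features %in% rfe$ranking[1:8]), 2)

  cfg_all <- pipeline_config(rfe_folds = 5, rfe_repeats = 1,
                             rfe_sizes = 61, rf_ntree = 100, seed = 1)
  rfe_all <- recursive_feature_selection(tab, cfg_all)
  expect_equal(nrow(rfe_all$profile), 1L)
  expect_setequal(rfe_all$subset, feature_catalog()$name)

  single <- tab[tab$outcome == "probiotic", ]
  expect_error(recursive_feature_selection(single, cfg), "single class")
})

test_that("repeated CV is reproducible and separates a planted-effect cohort", {
  tab <- small_feature_table(seed = 73, n_pos = 12, n_neg = 10,
                             n_test_pos = 0, n_test_neg = 0)
  cfg <- pipeline_config(cv_folds = 5, cv_repeats = 3, rf_ntree = 200,
                         algorithms = c("glm", "rf", "svm", "nn"),
                         nn_size = 3L, nn_decay = 0.1, svm_cost = 1,
                         seed = 2)
  cv1 <- train_models(tab, trio_features, cfg)
  cv2 <- train_models(tab, trio_features, cfg)
  for (alg in cfg$algorithms) {
    expect_identical(cv1$results[[alg]]$resamples, cv2$results[[alg]]$resamples)
    expect_gte(cv1$results[[alg]]$mean_accuracy, 0.85)
  }
  expect_s3_class(cv1, "cv_result")
  expect_true(all(cv1$summary$kappa >= -1 & cv1$summary$kappa <= 1))
})

test_that("label permutation drives Kappa to its null", {
  tab <- small_feature_table(seed = 74, n_pos = 12, n_neg = 12,
                             n_test_pos = 0, n_test_neg = 0)
  # resamples within one permutation share that permutation's spurious
  # signal, so the replication unit is the permutation
  set.seed(74)
  perm_means <- vapply(1:8, function(i) {
    tab$outcome <- sample(tab$outcome)
    cfg <- pipeline_config(cv_folds = 4, cv_repeats = 2,
                           algorithms = "glm", seed = i)
    cv <- train_models(tab, trio_features, cfg)
    mean(cv$results$glm$resamples$kappa, na.rm = TRUE)
  }, numeric(1))
  se <- stats::sd(perm_means) / sqrt(length(perm_means))
  expect_lte(abs(mean(perm_means)), 3 * se)
})

test_that("importance puts all mass on a single-feature model", {
  tab <- small_feature_table(seed = 75, n_pos = 10, n_neg = 10,
                             n_test_pos = 0, n_test_neg = 0)
  cfg <- pipeline_config(cv_folds = 4, cv_repeats = 2, algorithms = "glm",
                         seed = 4)
  cv <- train_models(tab, "tRNA_chargaff_score_ct", cfg)
  imp <- feature_importance(cv, folds = 4, repeats = 2)
  expect_equal(imp$feature, "tRNA_chargaff_score_ct")
  expect_equal(imp$importance, 100)
})

test_that("prediction returns one row per organism and algorithm with probabilities", {
  tab <- small_feature_table(seed = 76, n_pos = 12, n_neg = 10,
                             n_test_pos = 8, n_test_neg = 4)
  roles <- attr(tab, "roles")
  train <- tab[roles == "train", ]
  test <- tab[roles == "test", ]
  cfg <- pipeline_config(cv_folds = 5, cv_repeats = 2,
                         algorithms = c("glm", "rf", "svm", "nn"),
                         nn_size = 3L, nn_decay = 0.1, svm_cost = 1, seed = 5)
  cv <- train_models(train, trio_features, cfg)
  pred <- predict_cohort(cv, test)
  expect_equal(nrow(pred), nrow(test) * 4L)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_true(all(pred$classification %in% c("probiotic", "non-probiotic")))
  expect_identical(pred$classification,
                   ifelse(pred$probability >= 0.5, "probiotic", "non-probiotic"))

  # feeding the training data back cannot be worse than resampled accuracy
  back <- predict_cohort(cv, train)
  for (alg in c("glm", "rf")) {
    sub <- back[back$algorithm == alg, ]
    train_acc <- mean(sub$classification == train$outcome)
    expect_gte(train_acc, cv$results[[alg]]$mean_accuracy - 0.05)
  }

  expect_error(predict_cohort(cv, test[, 1:3]), "lacks feature column")
  broken <- test
  broken[, trio_features] <- NA_real_
  expect_warning(pred_na <- predict_cohort(cv, broken), "imputed")
  expect_equal(nrow(pred_na), nrow(test) * 4L)
})
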