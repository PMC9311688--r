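test_that("confusion counts tally the held-out calls correctly", {
  truth <- c(rep("probiotic", 9), rep("non-probiotic", 3))
  pred <- c(rep("probiotic", 7), rep("non-probiotic", 2),
            rep("non-probiotic", 3))
  cc <- confusion_counts(pred, truth)
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 7L, tn = 3L, fp = 0L, fn = 2L))
  same <- confusion_counts(truth, truth)
  expect_equal(same$fp + same$fn, 0L)
  flipped <- confusion_counts(rev(truth), truth)
  expect_equal(flipped$tp, 6L)   # 9 and 3 overlap on 6 positives
  expect_error(confusion_counts(pred[-1], truth), "length")
})

test_that("the algebraic 2x2 Kappa equals standard Cohen's kappa", {
  set.seed(81)
  for (i in 1:200) {
    cells <- sample(0:30, 4, replace = TRUE)
    if (sum(cells) == 0) cells[1] <- 1
    m <- classification_metrics(do.call(new_confusion_counts, as.list(cells)))
    expected <- kappa_oracle(cells[1], cells[2], cells[3], cells[4])
    if (is.finite(expected)) expect_equal(m$kappa, expected)
  }
})

test_that("metric identities hold: F1 harmonic mean, MCC class-swap symmetry", {
  set.seed(82)
  for (i in 1:100) {
    cells <- as.list(sample(0:25, 4, replace = TRUE))
    if (Reduce(`+`, cells) == 0) cells[[1]] <- 1
    names(cells) <- c("tp", "tn", "fp", "fn")
    m <- classification_metrics(do.call(new_confusion_counts, cells))
    if (m$precision + m$sensitivity > 0 &&
        !"precision" %in% m$degenerate && !"sensitivity" %in% m$degenerate) {
      expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                           (m$precision + m$sensitivity))
    }
    swapped <- classification_metrics(new_confusion_counts(
      tp = cells$tn, tn = cells$tp, fp = cells$fn, fn = cells$fp))
    expect_equal(m$mcc, swapped$mcc)
    expect_equal(m$tot_err, 1 - m$accuracy)
    expect_true(m$ci_low <= m$accuracy && m$accuracy <= m$ci_high)
  }
})

test_that("perfect and degenerate confusion tables are handled", {
  perfect <- classification_metrics(new_confusion_counts(5, 5, 0, 0))
  for (f in c("accuracy", "sensitivity", "specificity", "precision",
              "kappa", "f1", "mcc")) {
    expect_equal(perfect[[f]], 1, info = f)
  }
  no_pos_calls <- classification_metrics(new_confusion_counts(0, 5, 0, 5))
  expect_equal(no_pos_calls$precision, 0)
  expect_true("precision" %in% no_pos_calls$degenerate)
  expect_equal(no_pos_calls$mcc, 0)
})

test_that("rank AUC equals brute-force pair enumeration", {
  expect_equal(auc_rank(c(.9, .8, .2, .1),
                        c("probiotic", "probiotic",
                          "non-probiotic", "non-probiotic")), 1)
  expect_equal(auc_rank(rep(0.5, 6),
                        rep(c("probiotic", "non-probiotic"), 3)), 0.5)
  # 9 positives vs 3 negatives with one misordered pair and one tie
  scores <- c(rep(.9, 7), .5, .4, .3, .35, .5)
  truth <- c(rep("probiotic", 9), rep("non-probiotic", 3))
  expect_equal(auc_rank(scores, truth), 25.5 / 27)
  expect_equal(auc_rank(scores, truth), auc_oracle(scores, truth))
  set.seed(83)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    truth <- sample(c("probiotic", "non-probiotic"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("probiotic", "non-probiotic")
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # force ties
    expect_equal(auc_rank(scores, truth), auc_oracle(scores, truth))
  }
  expect_error(auc_rank(1:3, rep("probiotic", 3)), "at least one")
})

test_that("rank AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(84)
  for (i in 1:20) {
    truth <- sample(c("probiotic", "non-probiotic"), 30, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("probiotic", "non-probiotic")
    scores <- round(runif(30), 2)
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(truth, scores, levels = c("non-probiotic", "probiotic"),
                direction = "<"))))
    expect_equal(auc_rank(scores, truth), ref)
  }
})

test_that("exact binomial intervals are conservative at nominal level", {
  set.seed(85)
  draws <- stats::rbinom(2000, 12, 0.8)
  covered <- vapply(draws, function(x) {
    ci <- binomial_ci(x, 12)
    ci[1] <= 0.8 && 0.8 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_equal(binomial_ci(12, 12)[2], 1)
  expect_error(binomial_ci(13, 12))
})

test_that("comparison report has the published table shape", {
  preds <- do.call(rbind, lapply(c("glm", "rf", "svm", "nn"), function(alg) {
    data.frame(organism_id = sprintf("org%02d", 1:12), algorithm = alg,
               probability = c(rep(.9, 7), .3, .2, .1, .2, .3),
               classification = c(rep("probiotic", 7),
                                  rep("non-probiotic", 5)),
               stringsAsFactors = FALSE)
  }))
  truth <- stats::setNames(c(rep("probiotic", 9), rep("non-probiotic", 3)),
                           sprintf("org%02d", 1:12))
  rep_out <- comparison_report(preds, truth)
  expect_equal(nrow(rep_out$metrics), 4L)
  expect_identical(names(rep_out$metrics),
                   c("Method", "Accuracy", "CI", "Se", "Sp", "Precision",
                     "Kappa", "F1", "MCC", "AUC"))
  expect_identical(names(rep_out$errors),
                   c("Method", "FN.ERR", "FP.ERR", "TOT.ERR"))
  expect_equal(rep_out$errors$TOT.ERR, rep(2 / 12, 4))
  expect_equal(rep_out$errors$FP.ERR, rep(0, 4))

  # an algorithm without probabilities keeps its row, with AUC empty
  preds$probability[preds$algorithm == "nn"] <- NA_real_
  expect_message(rep2 <- comparison_report(preds, truth), "AUC left empty")
  expect_true(is.na(rep2$metrics$AUC[rep2$metrics$Method == "nn"]))

  path <- withr::local_tempfile(fileext = ".csv")
  write_comparison_csv(rep_out, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.csv$", "_errors.csv", path)))
})
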