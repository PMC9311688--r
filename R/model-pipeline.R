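# Recursive feature elimination and repeated stratified cross-validation
# over four classifier families (logistic GLM, random forest, RBF-SVM,
# single-hidden-layer neural network), with within-fold median imputation
# and standardization, caret-style tuning by resamples, permutation feature
# importance, and held-out prediction.
#
# Leakage discipline: every preprocessing parameter (imputation medians,
# centering means, scaling SDs) is estimated on the training part of a
# resample and applied unchanged to its validation part.

ALGORITHMS <- c("glm", "rf", "svm", "nn")
POSITIVE_CLASS <- "probiotic"
NEGATIVE_CLASS <- "non-probiotic"

#' Pipeline configuration
#'
#' Defaults follow the study protocol: feature selection under 10-fold CV
#' repeated 100 times, model training/validation under stratified 10-fold
#' CV repeated 1000 times. `preset = "ci"` scales the repeats down
#' (10 and 50) for desk-scale runs; all estimates are unchanged in
#' expectation, only noisier.
#'
#' @param rfe_folds,rfe_repeats Folds/repeats for recursive feature
#'   elimination.
#' @param rfe_sizes Candidate subset sizes; `NULL` for an automatic grid.
#' @param cv_folds,cv_repeats Folds/repeats for model training CV.
#' @param algorithms Subset of `c("glm", "rf", "svm", "nn")`.
#' @param rf_ntree Trees per random forest.
#' @param rf_mtry `mtry` grid; `NULL` for `{floor(sqrt(p)), floor(p/3)}`.
#' @param svm_cost RBF-SVM cost grid.
#' @param nn_size,nn_decay Hidden-layer size and weight-decay grids.
#' @param parsimony_se Parsimony tolerance: the chosen subset is the
#'   smallest whose profile accuracy is within this many standard errors of
#'   the maximum (the one-standard-error rule by default).
#' @param seed Master seed; fixes folds, tuning and fits bit-exactly.
#' @param preset `"full"` (protocol-scale repeats) or `"ci"` (desk scale).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(rfe_folds = 10L, rfe_repeats = 100L,
                            rfe_sizes = NULL,
                            cv_folds = 10L, cv_repeats = 1000L,
                            algorithms = ALGORITHMS,
                            rf_ntree = 500L, rf_mtry = NULL,
                            svm_cost = c(0.25, 0.5, 1, 2, 4),
                            nn_size = c(1L, 3L, 5L),
                            nn_decay = c(0, 1e-4, 0.1),
                            parsimony_se = 1,
                            seed = 1L,
                            preset = c("full", "ci")) {
  preset <- match.arg(preset)
  if (preset == "ci") {
    if (missing(rfe_repeats)) rfe_repeats <- 10L
    if (missing(cv_repeats)) cv_repeats <- 50L
  }
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  stopifnot(rfe_folds >= 2L, cv_folds >= 2L, rfe_repeats >= 1L,
            cv_repeats >= 1L, parsimony_se >= 0)
  structure(list(rfe_folds = as.integer(rfe_folds),
                 rfe_repeats = as.integer(rfe_repeats),
                 rfe_sizes = rfe_sizes,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 algorithms = algorithms,
                 rf_ntree = as.integer(rf_ntree), rf_mtry = rf_mtry,
                 svm_cost = svm_cost, nn_size = as.integer(nn_size),
                 nn_decay = nn_decay, parsimony_se = parsimony_se,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# ---- resampling helpers ----------------------------------------------------

# Stratified k-fold assignment: class proportions per fold within one
# organism of the global ratio. Redraws (with a warning) in the rare case a
# fold ends up single-class.
stratified_folds <- function(y, k, max_tries = 20L) {
  for (try in seq_len(max_tries)) {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y[fold != f])) == 2L
    }, logical(1)))
    if (ok) return(fold)
    warning("single-class training fold drawn; redrawing")
  }
  stop("could not draw stratified folds with two classes per training fold")
}

# Preprocessing fitted on training rows only: median imputation then
# center/scale. Constant columns get sd 1 so they pass through as zeros.
fit_preprocessor <- function(x) {
  med <- vapply(x, function(col) stats::median(col, na.rm = TRUE), numeric(1))
  med[is.na(med)] <- 0
  ximp <- as.data.frame(Map(function(col, m) ifelse(is.na(col), m, col), x, med))
  mu <- vapply(ximp, mean, numeric(1))
  sd <- vapply(ximp, stats::sd, numeric(1))
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(median = med, mean = mu, sd = sd)
}

apply_preprocessor <- function(pp, x) {
  out <- Map(function(col, m, mu, s) {
    col[is.na(col)] <- m
    (col - mu) / s
  }, x, pp$median[names(x)], pp$mean[names(x)], pp$sd[names(x)])
  as.data.frame(out, check.names = FALSE)
}

as_outcome_factor <- function(y) {
  factor(y, levels = c(NEGATIVE_CLASS, POSITIVE_CLASS))
}

check_training_table <- function(table) {
  y <- table$outcome
  if (!all(y %in% c(POSITIVE_CLASS, NEGATIVE_CLASS))) {
    stop("training table contains unlabeled rows; partition the dataset first")
  }
  if (length(unique(y)) < 2L) stop("training table has a single class")
  tab <- table(y)
  if (any(tab < 2L)) stop("need at least 2 organisms per class")
  as_outcome_factor(y)
}

# ---- learners --------------------------------------------------------------
# Each fits on a preprocessed data.frame x and factor y
# (levels: non-probiotic, probiotic) and predicts P(probiotic).

fit_learner <- function(algorithm, x, y, tune, probability = FALSE) {
  switch(algorithm,
    glm = {
      df <- x
      df$.y <- as.integer(y == POSITIVE_CLASS)
      suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(), data = df))
    },
    rf = randomForest::randomForest(
      x = x, y = y, ntree = tune$ntree, mtry = tune$mtry),
    svm = e1071::svm(x = as.matrix(x), y = y, kernel = "radial",
                     cost = tune$cost, probability = probability),
    nn = suppressWarnings(nnet::nnet(
      x = as.matrix(x), y = as.integer(y == POSITIVE_CLASS),
      size = tune$size, decay = tune$decay, entropy = TRUE,
      maxit = 200, trace = FALSE, MaxNWts = 5000))
  )
}

predict_prob <- function(algorithm, fit, x) {
  switch(algorithm,
    glm = unname(suppressWarnings(
      stats::predict(fit, newdata = x, type = "response"))),
    rf = unname(stats::predict(fit, newdata = x, type = "prob")[, POSITIVE_CLASS]),
    svm = {
      if (isTRUE(fit$compprob)) {
        pr <- stats::predict(fit, newdata = as.matrix(x), probability = TRUE)
        unname(attr(pr, "probabilities")[, POSITIVE_CLASS])
      } else {
        # no Platt model fitted (CV resamples): hard labels as 0/1
        as.numeric(stats::predict(fit, newdata = as.matrix(x)) == POSITIVE_CLASS)
      }
    },
    nn = as.numeric(stats::predict(fit, newdata = as.matrix(x)))
  )
}

tune_grid <- function(algorithm, config, p) {
  switch(algorithm,
    glm = list(list()),
    rf = {
      mtry <- config$rf_mtry
      if (is.null(mtry)) mtry <- unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3))))
      lapply(mtry, function(m) list(ntree = config$rf_ntree, mtry = m))
    },
    svm = lapply(config$svm_cost, function(cst) list(cost = cst)),
    nn = {
      grid <- expand.grid(size = config$nn_size, decay = config$nn_decay)
      lapply(seq_len(nrow(grid)), function(i)
        list(size = grid$size[i], decay = grid$decay[i]))
    })
}

accuracy_kappa <- function(pred, truth) {
  tp <- sum(pred == POSITIVE_CLASS & truth == POSITIVE_CLASS)
  tn <- sum(pred == NEGATIVE_CLASS & truth == NEGATIVE_CLASS)
  fp <- sum(pred == POSITIVE_CLASS & truth == NEGATIVE_CLASS)
  fn <- sum(pred == NEGATIVE_CLASS & truth == POSITIVE_CLASS)
  n <- tp + tn + fp + fn
  den <- (tp + fp) * (fp + tn) + (tp + fn) * (fn + tn)
  list(accuracy = (tp + tn) / n,
       kappa = if (den > 0) 2 * (tp * tn - fn * fp) / den else NA_real_)
}

# ---- recursive feature elimination ----------------------------------------

default_rfe_sizes <- function(p) {
  sizes <- unique(c(1:10, 12L, 16L, 20L, 25L, 30L, 40L, 50L, p))
  sort(sizes[sizes <= p])
}

#' Recursive feature elimination under repeated cross-validation
#'
#' For every resample (fold x repeat), a random forest is fitted on the
#' training part with all features and its impurity importance ranks the
#' features; for each candidate subset size the top-ranked features are
#' refitted and scored on the validation part. The selection profile is the
#' mean validation accuracy per subset size; the chosen subset is the
#' smallest size whose accuracy is within `parsimony_se` standard errors of
#' the profile maximum, populated by the features with the best mean rank
#' across resamples.
#'
#' @param table A labeled feature table (rows with known outcome only).
#' @param config A [pipeline_config()].
#' @return An object of class `rfe_result`: list with `profile`
#'   (`data.frame` size/accuracy/sd/se), `ranking` (features by mean rank),
#'   `subset` (chosen feature names) and `size`.
#' @export
recursive_feature_selection <- function(table, config = pipeline_config()) {
  y <- check_training_table(table)
  features <- feature_catalog()$name
  x <- table[, features, drop = FALSE]
  p <- length(features)
  sizes <- config$rfe_sizes
  if (is.null(sizes)) sizes <- default_rfe_sizes(p)
  sizes <- sort(unique(pmin(sizes, p)))

  set.seed(config$seed)
  acc <- matrix(NA_real_, nrow = config$rfe_folds * config$rfe_repeats,
                ncol = length(sizes))
  rank_sum <- stats::setNames(numeric(p), features)
  r <- 0L
  for (rep_i in seq_len(config$rfe_repeats)) {
    fold <- stratified_folds(y, config$rfe_folds)
    for (f in seq_len(config$rfe_folds)) {
      r <- r + 1L
      tr <- fold != f
      pp <- fit_preprocessor(x[tr, , drop = FALSE])
      xtr <- apply_preprocessor(pp, x[tr, , drop = FALSE])
      xte <- apply_preprocessor(pp, x[!tr, , drop = FALSE])
      rf_full <- randomForest::randomForest(x = xtr, y = y[tr],
                                            ntree = config$rf_ntree)
      imp <- randomForest::importance(rf_full)[, 1L]
      ord <- names(sort(imp, decreasing = TRUE))
      rank_sum[ord] <- rank_sum[ord] + seq_along(ord)
      for (si in seq_along(sizes)) {
        keep <- ord[seq_len(sizes[si])]
        fit <- randomForest::randomForest(x = xtr[, keep, drop = FALSE],
                                          y = y[tr], ntree = config$rf_ntree)
        pred <- stats::predict(fit, xte[, keep, drop = FALSE])
        acc[r, si] <- mean(pred == y[!tr])
      }
    }
  }
  profile <- data.frame(
    size = sizes,
    accuracy = colMeans(acc),
    sd = apply(acc, 2L, stats::sd))
  profile$se <- profile$sd / sqrt(nrow(acc))
  best_i <- which.max(profile$accuracy)
  threshold <- profile$accuracy[best_i] -
    config$parsimony_se * profile$se[best_i]
  chosen_size <- min(profile$size[profile$accuracy >= threshold])
  ranking <- names(sort(rank_sum))
  structure(list(profile = profile, ranking = ranking,
                 subset = ranking[seq_len(chosen_size)], size = chosen_size),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  best <- x$profile[which.max(x$profile$accuracy), ]
  cat(sprintf(
    "recursive feature elimination: %d sizes tested, peak accuracy %.3f at %d features\n",
    nrow(x$profile), best$accuracy, best$size))
  cat(sprintf("chosen subset (%d features): %s\n", x$size,
              paste(x$subset, collapse = ", ")))
  invisible(x)
}

# ---- model training --------------------------------------------------------

#' Train the classifier families under repeated stratified cross-validation
#'
#' For each algorithm, every hyperparameter candidate is evaluated on the
#' same stratified fold x repeat resamples (training part: impute,
#' standardize, fit; validation part: transform with training-part
#' parameters, predict) and the candidate with the best mean validation
#' accuracy is retained, together with its per-resample accuracy and Kappa
#' distributions. A final model per algorithm is then fitted on the full
#' training set (SVM with a probability model) for later prediction.
#'
#' @param table A labeled feature table.
#' @param subset Feature names to model on (e.g. `rfe$subset`); `NULL` for
#'   all catalog features.
#' @param config A [pipeline_config()].
#' @return An object of class `cv_result`: per-algorithm `resamples`
#'   (accuracy/kappa per resample), `summary` (mean accuracy and Kappa),
#'   `best_tune`, fitted `final_models` (with their preprocessor), the
#'   `subset`, the `best_algorithm` (highest mean accuracy, ties by Kappa
#'   then by the fixed order glm, rf, svm, nn) and the training data.
#' @export
train_models <- function(table, subset = NULL, config = pipeline_config()) {
  y <- check_training_table(table)
  if (is.null(subset)) subset <- feature_catalog()$name
  missing <- setdiff(subset, names(table))
  if (length(missing)) stop("feature table lacks column(s): ",
                            paste(missing, collapse = ", "))
  x <- table[, subset, drop = FALSE]
  p <- length(subset)

  set.seed(config$seed)
  n_res <- config$cv_folds * config$cv_repeats
  folds <- matrix(0L, nrow = nrow(table), ncol = config$cv_repeats)
  for (rep_i in seq_len(config$cv_repeats)) {
    folds[, rep_i] <- stratified_folds(y, config$cv_folds)
  }

  results <- list()
  for (alg in config$algorithms) {
    grid <- tune_grid(alg, config, p)
    acc <- matrix(NA_real_, n_res, length(grid))
    kap <- matrix(NA_real_, n_res, length(grid))
    set.seed(config$seed + match(alg, ALGORITHMS))
    r <- 0L
    for (rep_i in seq_len(config$cv_repeats)) {
      for (f in seq_len(config$cv_folds)) {
        r <- r + 1L
        tr <- folds[, rep_i] != f
        if (all(tr) || !any(tr)) next
        pp <- fit_preprocessor(x[tr, , drop = FALSE])
        xtr <- apply_preprocessor(pp, x[tr, , drop = FALSE])
        xte <- apply_preprocessor(pp, x[!tr, , drop = FALSE])
        for (gi in seq_along(grid)) {
          fit <- fit_learner(alg, xtr, y[tr], grid[[gi]])
          prob <- predict_prob(alg, fit, xte)
          pred <- ifelse(prob >= 0.5, POSITIVE_CLASS, NEGATIVE_CLASS)
          m <- accuracy_kappa(pred, as.character(y[!tr]))
          acc[r, gi] <- m$accuracy
          kap[r, gi] <- m$kappa
        }
      }
    }
    best_gi <- which.max(colMeans(acc, na.rm = TRUE))
    results[[alg]] <- list(
      resamples = data.frame(accuracy = acc[, best_gi], kappa = kap[, best_gi]),
      best_tune = grid[[best_gi]],
      mean_accuracy = mean(acc[, best_gi], na.rm = TRUE),
      mean_kappa = mean(kap[, best_gi], na.rm = TRUE))
  }

  # final fits on the full training set
  pp_full <- fit_preprocessor(x)
  x_full <- apply_preprocessor(pp_full, x)
  final_models <- list()
  for (alg in config$algorithms) {
    set.seed(config$seed + 100L + match(alg, ALGORITHMS))
    final_models[[alg]] <- fit_learner(alg, x_full, y, results[[alg]]$best_tune,
                                       probability = TRUE)
  }

  summary_df <- data.frame(
    algorithm = config$algorithms,
    accuracy = vapply(results, `[[`, numeric(1), "mean_accuracy"),
    kappa = vapply(results, `[[`, numeric(1), "mean_kappa"),
    row.names = NULL)
  ord <- order(-summary_df$accuracy, -summary_df$kappa,
               match(summary_df$algorithm, ALGORITHMS))
  best_algorithm <- summary_df$algorithm[ord[1L]]

  structure(list(results = results, summary = summary_df,
                 best_algorithm = best_algorithm,
                 final_models = final_models, preprocessor = pp_full,
                 subset = subset, config = config,
                 train_x = x, train_y = y),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("repeated stratified %d-fold CV x %d repeats on %d features\n",
              x$config$cv_folds, x$config$cv_repeats, length(x$subset)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s accuracy %.3f  kappa %.3f%s\n", s$algorithm[i],
                s$accuracy[i], s$kappa[i],
                if (s$algorithm[i] == x$best_algorithm) "  <- best" else ""))
  }
  invisible(x)
}

# ---- permutation importance ------------------------------------------------

#' Permutation feature importance of the best model
#'
#' Model-agnostic importance on held-out data: across fresh stratified
#' resamples, the best algorithm (per [train_models()] ranking) is refitted
#' on the training part and each feature column of the validation part is
#' permuted in turn; the importance of a feature is the mean held-out
#' accuracy drop it causes, clipped at zero and scaled so the top feature
#' is 100.
#'
#' @param result A `cv_result`.
#' @param folds,repeats Resampling plan for the importance estimate.
#' @param n_perm Permutations per feature per resample.
#' @return A `data.frame` (`feature`, `importance`) sorted descending.
#' @export
feature_importance <- function(result, folds = 5L, repeats = 4L, n_perm = 3L) {
  stopifnot(inherits(result, "cv_result"))
  alg <- result$best_algorithm
  tune <- result$results[[alg]]$best_tune
  x <- result$train_x
  y <- result$train_y
  set.seed(result$config$seed + 1000L)
  drops <- matrix(0, nrow = length(result$subset), ncol = folds * repeats,
                  dimnames = list(result$subset, NULL))
  r <- 0L
  for (rep_i in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      r <- r + 1L
      tr <- fold != f
      pp <- fit_preprocessor(x[tr, , drop = FALSE])
      xtr <- apply_preprocessor(pp, x[tr, , drop = FALSE])
      xte <- apply_preprocessor(pp, x[!tr, , drop = FALSE])
      fit <- fit_learner(alg, xtr, y[tr], tune)
      base_prob <- predict_prob(alg, fit, xte)
      base_acc <- mean(ifelse(base_prob >= 0.5, POSITIVE_CLASS,
                              NEGATIVE_CLASS) == y[!tr])
      for (feat in result$subset) {
        perm_acc <- numeric(n_perm)
        for (k in seq_len(n_perm)) {
          xperm <- xte
          xperm[[feat]] <- sample(xperm[[feat]])
          prob <- predict_prob(alg, fit, xperm)
          perm_acc[k] <- mean(ifelse(prob >= 0.5, POSITIVE_CLASS,
                                     NEGATIVE_CLASS) == y[!tr])
        }
        drops[feat, r] <- base_acc - mean(perm_acc)
      }
    }
  }
  imp <- pmax(rowMeans(drops), 0)
  top <- max(imp)
  if (top > 0) imp <- imp / top * 100
  out <- data.frame(feature = names(imp), importance = unname(imp))
  out[order(-out$importance, out$feature), , drop = FALSE]
}

# ---- prediction ------------------------------------------------------------

#' Predict the probiotic status of new organisms
#'
#' Applies every fitted final model to a feature table. Missing values in
#' the selected features are imputed with the training medians (with a
#' warning). Hard calls threshold the probiotic probability at 0.5.
#'
#' @param result A `cv_result`.
#' @param table A feature table covering the selected features.
#' @return A `data.frame` with one row per organism x algorithm:
#'   `organism_id`, `algorithm`, `probability` (of probiotic),
#'   `classification`.
#' @export
predict_cohort <- function(result, table) {
  stopifnot(inherits(result, "cv_result"))
  missing <- setdiff(result$subset, names(table))
  if (length(missing)) stop("prediction table lacks feature column(s): ",
                            paste(missing, collapse = ", "))
  x <- table[, result$subset, drop = FALSE]
  if (anyNA(x)) warning("missing feature values imputed with training medians")
  xs <- apply_preprocessor(result$preprocessor, x)
  ids <- if ("organism_id" %in% names(table)) table$organism_id
         else sprintf("organism%03d", seq_len(nrow(table)))
  out <- list()
  for (alg in names(result$final_models)) {
    prob <- predict_prob(alg, result$final_models[[alg]], xs)
    out[[alg]] <- data.frame(
      organism_id = ids, algorithm = alg, probability = prob,
      classification = ifelse(prob >= 0.5, POSITIVE_CLASS, NEGATIVE_CLASS),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
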