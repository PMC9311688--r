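# Binary-classification evaluation: confusion counts, the printed metric
# formulas (accuracy, Cohen's Kappa in its algebraic 2x2 form, sensitivity,
# specificity, precision, F1, MCC), error decomposition, exact binomial
# confidence intervals, rank-based AUC, and the per-algorithm comparison
# report. The probiotic label is the positive class throughout.

#' Confusion counts for a prediction set
#'
#' @param predicted,truth Equal-length character vectors over
#'   `"probiotic"` / `"non-probiotic"`.
#' @param positive The positive-class label (default `"probiotic"`).
#' @return A `confusion_counts` object: list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, truth, positive = POSITIVE_CLASS) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth differ in length (", length(predicted),
         " vs ", length(truth), ")")
  }
  new_confusion_counts(
    tp = sum(predicted == positive & truth == positive),
    tn = sum(predicted != positive & truth != positive),
    fp = sum(predicted == positive & truth != positive),
    fn = sum(predicted != positive & truth == positive))
}

#' @rdname confusion_counts
#' @param tp,tn,fp,fn Non-negative integer cell counts.
#' @export
new_confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn >= 1)
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den > 0) num / den else 0

#' Classification metrics from a 2x2 confusion table
#'
#' Computes the standard metric suite in its algebraic 2x2 forms:
#' accuracy, Cohen's Kappa as
#' \eqn{2(TP \cdot TN - FN \cdot FP) / ((TP+FP)(FP+TN) + (TP+FN)(FN+TN))}
#' (equivalent to the usual \eqn{(p_o - p_e)/(1 - p_e)}), sensitivity,
#' specificity, precision, \eqn{F1 = 2TP/(2TP+FP+FN)}, MCC with the
#' four-factor root denominator, the error decomposition (false-positive
#' rate on negatives, false-negative rate on positives, total error), and
#' an exact binomial confidence interval on accuracy.
#'
#' Degenerate denominators return 0 (and are flagged in the `degenerate`
#' field) so report generation is total; the MCC convention sets the score
#' to 0 when any marginal is empty.
#'
#' @param counts A `confusion_counts` object.
#' @param level Confidence level for the accuracy interval (default 0.95).
#' @param auc Optional AUC to carry along (computed separately from
#'   probabilities via [auc_rank()]).
#' @return A `confusion_metrics` object: list with `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `kappa`, `f1`, `mcc`,
#'   `fp_err`, `fn_err`, `tot_err`, `ci_low`, `ci_high`, `auc`,
#'   `degenerate`.
#' @export
classification_metrics <- function(counts, level = 0.95, auc = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  degenerate <- character(0)
  flag <- function(metric, num, den) {
    if (den <= 0) degenerate <<- c(degenerate, metric)
    safe_ratio(num, den)
  }
  accuracy <- (tp + tn) / n
  sensitivity <- flag("sensitivity", tp, tp + fn)
  specificity <- flag("specificity", tn, tn + fp)
  precision <- flag("precision", tp, tp + fp)
  kappa_den <- (tp + fp) * (fp + tn) + (tp + fn) * (fn + tn)
  kappa <- flag("kappa", 2 * (tp * tn - fn * fp), kappa_den)
  f1 <- flag("f1", 2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- flag("mcc", tp * tn - fp * fn, mcc_den)
  ci <- binomial_ci(tp + tn, n, level)
  structure(list(
    accuracy = accuracy, sensitivity = sensitivity,
    specificity = specificity, precision = precision, kappa = kappa,
    f1 = f1, mcc = mcc,
    fp_err = flag("fp_err", fp, tn + fp),
    fn_err = flag("fn_err", fn, tp + fn),
    tot_err = (fp + fn) / n,
    ci_low = ci[1L], ci_high = ci[2L], auc = auc,
    degenerate = degenerate), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f (95%% CI %.3f-%.3f)  Se %.3f  Sp %.3f  precision %.3f\n",
    x$accuracy, x$ci_low, x$ci_high, x$sensitivity, x$specificity,
    x$precision))
  cat(sprintf("kappa %.3f  F1 %.3f  MCC %.3f  errors FP %.3f FN %.3f total %.3f\n",
              x$kappa, x$f1, x$mcc, x$fp_err, x$fn_err, x$tot_err))
  if (length(x$degenerate)) {
    cat("degenerate denominators (returned 0):",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exact binomial confidence interval
#'
#' Two-sided Clopper-Pearson interval for a binomial proportion (the exact
#' interval used for the accuracy column of the comparison report).
#'
#' @param successes,n Success count and trial count, `0 <= successes <= n`,
#'   `n >= 1`.
#' @param level Confidence level in (0, 1).
#' @return A numeric vector `c(low, high)`.
#' @export
binomial_ci <- function(successes, n, level = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n, level > 0, level < 1)
  as.numeric(stats::binom.test(successes, n,
                               conf.level = level)$conf.int)
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' The area under the ROC curve computed as the fraction of
#' positive-negative pairs in which the positive organism receives the
#' higher positive-class probability, ties counted one half.
#'
#' @param scores Numeric positive-class probabilities (or any monotone
#'   scores).
#' @param truth Class labels, same length as `scores`.
#' @param positive The positive-class label.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, truth, positive = POSITIVE_CLASS) {
  stopifnot(length(scores) == length(truth))
  pos <- truth == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC requires at least one positive and one negative")
  }
  r <- rank(scores)                     # average ranks handle ties as 1/2
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-algorithm comparison report on a labeled prediction set
#'
#' Builds the metrics table (one row per algorithm: accuracy with its exact
#' 95% CI, sensitivity, specificity, precision, Kappa, F1, MCC, AUC) and
#' the error decomposition (FN.ERR, FP.ERR, TOT.ERR per algorithm).
#'
#' @param predictions A `data.frame` as returned by [predict_cohort()]
#'   (`organism_id`, `algorithm`, `probability`, `classification`).
#' @param truth Named character vector or `data.frame`
#'   (`organism_id`, `outcome`) with the true labels.
#' @return A `comparison_report` object: list with `metrics`
#'   (columns `Method`, `Accuracy`, `CI`, `Se`, `Sp`, `Precision`, `Kappa`,
#'   `F1`, `MCC`, `AUC`), `errors` (`Method`, `FN.ERR`, `FP.ERR`,
#'   `TOT.ERR`) and the per-algorithm `confusion_metrics`.
#' @export
comparison_report <- function(predictions, truth) {
  if (is.data.frame(truth)) truth <- stats::setNames(truth$outcome,
                                                     truth$organism_id)
  algs <- unique(predictions$algorithm)
  metrics <- list()
  rows <- list(); erows <- list()
  for (alg in algs) {
    sub <- predictions[predictions$algorithm == alg, , drop = FALSE]
    tv <- unname(truth[sub$organism_id])
    if (anyNA(tv)) stop("truth labels missing for: ",
                        paste(sub$organism_id[is.na(tv)], collapse = ", "))
    cc <- confusion_counts(sub$classification, tv)
    auc <- if (all(is.na(sub$probability)) ||
               length(unique(tv)) < 2L) NA_real_
           else auc_rank(sub$probability, tv)
    if (is.na(auc)) message("no probabilities for ", alg,
                            "; AUC left empty")
    m <- classification_metrics(cc, auc = auc)
    metrics[[alg]] <- m
    rows[[alg]] <- data.frame(
      Method = alg, Accuracy = m$accuracy,
      CI = sprintf("%.3f-%.3f", m$ci_low, m$ci_high),
      Se = m$sensitivity, Sp = m$specificity, Precision = m$precision,
      Kappa = m$kappa, F1 = m$f1, MCC = m$mcc, AUC = m$auc,
      stringsAsFactors = FALSE)
    erows[[alg]] <- data.frame(Method = alg, FN.ERR = m$fn_err,
                               FP.ERR = m$fp_err, TOT.ERR = m$tot_err,
                               check.names = FALSE, stringsAsFactors = FALSE)
  }
  out <- list(metrics = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              errors = do.call(rbind, c(erows, list(make.row.names = FALSE))),
              details = metrics)
  class(out) <- "comparison_report"
  out
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  tab <- x$metrics
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  cat("\nerror decomposition:\n")
  err <- x$errors
  err[-1L] <- lapply(err[-1L], round, digits = digits)
  print(err, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report as CSV
#'
#' @param report A `comparison_report`.
#' @param path Output CSV path (metrics table; the error decomposition goes
#'   to `<path base>_errors.csv`).
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(report, path) {
  utils::write.csv(report$metrics, path, row.names = FALSE)
  err_path <- sub("(\\.[A-Za-z]+)?$", "_errors.csv",
                  sub("\\.csv$", "", path))
  utils::write.csv(report$errors, err_path, row.names = FALSE)
  invisible(path)
}
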