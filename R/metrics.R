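#' Coefficient of determination (pooled over traces and time points)
#'
#' `R2 = 1 - SS_res/SS_tot` with the residual and total sums of squares
#' pooled over all samples and time points.
#'
#' @param y_true,y_pred matrices (samples x time) or vectors of equal
#'   shape.
#' @return Scalar R2 (1 for perfect prediction, 0 for predicting the
#'   global mean).
#' @export
r2_score <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("shape mismatch between truth and prediction")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("R2 undefined: zero variance in the true values")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Threshold classification metrics
#'
#' Confusion counts at a probability threshold, plus accuracy (in percent,
#' `100 * (TP + TN) / n`), recall `TP/(TP+FN)`, precision `TP/(TP+FP)` and
#' false-positive rate `FP/(FP+TN)`.  Precision is reported as `NA` (not
#' 0) when nothing is predicted positive.
#'
#' @param labels 0/1 vector.
#' @param probabilities predicted probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return Named list with `accuracy_percent`, `recall`, `precision`,
#'   `fpr`, and counts `tp`, `tn`, `fp`, `fn`.
#' @export
classification_metrics <- function(labels, probabilities, threshold = 0.5) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (length(labels) != length(probabilities)) stop("length mismatch")
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  list(accuracy_percent = 100 * (tp + tn) / length(labels),
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Area under the ROC curve
#'
#' Computed by the rank (pair) formulation, equivalent to
#' `P(score_pos > score_neg) + 0.5 * P(tie)` and to trapezoidal
#' integration of the ROC curve over all thresholds.
#'
#' @param labels 0/1 vector (both classes must be present).
#' @param scores classifier scores or probabilities.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUROC requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean APD90 prediction error
#'
#' Mean over samples of `100 * |APD90(pred) - APD90(true)| / APD90(true)`,
#' computed on denormalized (mV) traces.  Traces whose APD90 cannot be
#' computed are excluded with a warning and counted.
#'
#' @param true_mv,pred_mv matrices (samples x time) of traces in mV.
#' @param dt sampling step, ms.
#' @return Scalar percentage error with attributes `n_used`, `n_failed`.
#' @export
apd90_error <- function(true_mv, pred_mv, dt = 1) {
  if (!identical(dim(true_mv), dim(pred_mv))) stop("shape mismatch")
  per <- vapply(seq_len(nrow(true_mv)), function(i) {
    tryCatch({
      a_t <- apd90(true_mv[i, ], dt)
      a_p <- apd90(pred_mv[i, ], dt)
      100 * abs(a_p - a_t) / a_t
    }, error = function(e) NA_real_)
  }, numeric(1))
  failed <- sum(is.na(per))
  if (failed)
    warning(failed, " trace(s) excluded from the APD90 error (no measurable APD90)")
  structure(mean(per, na.rm = TRUE), n_used = sum(!is.na(per)),
            n_failed = failed)
}

#' Evaluate a trained network on a dataset
#'
#' Runs the forward pass with dropout off on every sample, denormalizes
#' the translated traces with the training-set statistics and assembles
#' the full evaluation report: translation MSE (normalized scale), pooled
#' R2 and mean APD90 error, plus AUROC, accuracy, recall, precision and
#' confusion counts for the classification head (when present).
#'
#' @param net a `net_params` or `trained_net`.
#' @param data a [prepare_dataset()] result.
#' @param indices sample indices to evaluate (default: the test split).
#' @param threshold classification threshold.
#' @return An object of class `eval_report`.
#' @export
evaluate_network <- function(net, data, indices = NULL, threshold = 0.5) {
  if (inherits(net, "trained_net")) net <- net$net
  stopifnot(inherits(net, "net_params"))
  if (is.null(indices)) indices <- data$split$test
  if (!length(indices)) stop("empty evaluation set")
  x <- data$input[indices, , drop = FALSE]
  y <- data$target[indices, , drop = FALSE]
  lab <- data$label[indices]
  fw <- net_forward(net, x, training = FALSE)
  mse <- mse_loss(y, fw$translated)
  r2 <- r2_score(y, fw$translated)
  true_mv <- denormalize_traces(y, data$stats_target)
  pred_mv <- denormalize_traces(fw$translated, data$stats_target)
  apd_err <- apd90_error(true_mv, pred_mv)
  rep <- list(n = length(indices), mse = mse, r2 = r2,
              apd90_error_percent = as.numeric(apd_err),
              apd90_n_failed = attr(apd_err, "n_failed"))
  if (!is.null(fw$prob)) {
    cm <- classification_metrics(lab, fw$prob, threshold)
    rep$auroc <- if (length(unique(lab)) == 2) auroc(lab, fw$prob) else NA_real_
    rep <- c(rep, cm)
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n, "\n")
  cat(sprintf("  Translation:     MSE %.4f | R2 %.3f | APD90 error %.2f%%\n",
              x$mse, x$r2, x$apd90_error_percent))
  if (!is.null(x$auroc))
    cat(sprintf("  Classification:  AUROC %.3f | accuracy %.1f%% | recall %.3f | precision %.3f\n",
                x$auroc, x$accuracy_percent, x$recall, x$precision))
  invisible(x)
}

#' @export
format.eval_report <- function(x, ...) {
  utils::capture.output(print(x))
}
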