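#' Regression metrics for joint-angle estimation
#'
#' Pearson correlation coefficient (PCC), coefficient of determination
#' (R-squared), root-mean-square error (RMSE, in degrees) and RMSE
#' normalized by the range of the true signal (NRMSE, dimensionless).
#'
#' `r_squared` uses the standard residual-sum form
#' `1 - SS_res / SS_tot`; `variant = "variance_ratio"` gives the
#' variance-comparison form `1 - SS_est / SS_tot` (sum of squared deviations
#' of the estimates about their own mean over that of the truth), provided
#' for comparison only.
#'
#' @param est,real numeric vectors of equal length (estimated and true joint
#'   angle, degrees).
#' @return a single numeric value.
#' @name metrics
NULL

#' @rdname metrics
#' @export
pcc <- function(est, real) {
  check_metric_args(est, real)
  de <- est - mean(est)
  dr <- real - mean(real)
  se <- sum(de^2)
  sr <- sum(dr^2)
  if (se == 0 || sr == 0)
    stopf("undefined correlation: zero variance in %s",
          if (se == 0) "est" else "real")
  sum(de * dr) / sqrt(se * sr)
}

#' @rdname metrics
#' @param variant `"standard"` or `"variance_ratio"` (see Details).
#' @export
r_squared <- function(est, real, variant = c("standard", "variance_ratio")) {
  variant <- match.arg(variant)
  check_metric_args(est, real)
  sr <- sum((real - mean(real))^2)
  if (sr == 0) stopf("undefined R-squared: constant true signal")
  num <- if (variant == "standard") sum((est - real)^2)
         else sum((est - mean(est))^2)
  1 - num / sr
}

#' @rdname metrics
#' @export
rmse <- function(est, real) {
  check_metric_args(est, real, min_n = 1L)
  sqrt(mean((est - real)^2))
}

#' @rdname metrics
#' @export
nrmse <- function(est, real) {
  check_metric_args(est, real, min_n = 1L)
  rng <- max(real) - min(real)
  if (rng <= 0) stopf("undefined NRMSE: flat true signal")
  rmse(est, real) / rng
}

check_metric_args <- function(est, real, min_n = 2L) {
  if (length(est) != length(real))
    stopf("est and real must have equal length")
  if (length(est) < min_n)
    stopf("need at least %d observations", min_n)
  if (!all(is.finite(est)) || !all(is.finite(real)))
    stopf("non-finite values in input")
  invisible(TRUE)
}

metric_row <- function(fun, est, real) {
  tryCatch(fun(est, real), error = function(e) {
    warnf("metric undefined, reported as NA: %s", conditionMessage(e))
    NA_real_
  })
}

#' Evaluate predictions joint by joint
#'
#' Computes PCC, R-squared, RMSE and NRMSE per joint over the concatenated
#' window predictions of one evaluation stream and returns them as a tidy
#' evaluation report. Undefined cells (e.g. a flat true signal) are reported
#' as `NA` with a warning and excluded from aggregates.
#'
#' @param pred,truth `n x J` matrices of predicted and true angles, degrees.
#' @param subject,model,fold provenance labels attached to every row.
#' @return a data frame of class `eval_report` with columns
#'   `subject, model, joint, metric, value, fold`.
#' @export
evaluate <- function(pred, truth, subject = 1L, model = "model",
                     fold = "7:3") {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth)))
    stopf("pred and truth must have identical shape")
  J <- ncol(truth)
  rows <- lapply(seq_len(J), function(j) {
    data.frame(subject = subject, model = model, joint = j,
               metric = c("pcc", "r2", "rmse", "nrmse"),
               value = c(metric_row(pcc, pred[, j], truth[, j]),
                         metric_row(r_squared, pred[, j], truth[, j]),
                         metric_row(rmse, pred[, j], truth[, j]),
                         metric_row(nrmse, pred[, j], truth[, j])),
               fold = fold)
  })
  structure(do.call(rbind, rows), class = c("eval_report", "data.frame"))
}

#' Aggregate an evaluation report
#'
#' `report_subject_means()` averages over joints within each
#' (subject, model, fold, metric) cell; `report_joint_means()` averages over
#' subjects within each (joint, model, fold, metric) cell;
#' `report_grand()` gives the mean and standard deviation of the per-subject
#' means for each (model, fold, metric).
#'
#' @param report an `eval_report` data frame (rows from [evaluate()] may be
#'   concatenated with `rbind`).
#' @return a data frame of aggregate rows.
#' @export
report_subject_means <- function(report) {
  stats::aggregate(value ~ subject + model + fold + metric, report, mean,
                   na.rm = TRUE, na.action = stats::na.pass)
}

#' @rdname report_subject_means
#' @export
report_joint_means <- function(report) {
  stats::aggregate(value ~ joint + model + fold + metric, report, mean,
                   na.rm = TRUE, na.action = stats::na.pass)
}

#' @rdname report_subject_means
#' @export
report_grand <- function(report) {
  sm <- report_subject_means(report)
  mean_df <- stats::aggregate(value ~ model + fold + metric, sm, mean,
                              na.rm = TRUE, na.action = stats::na.pass)
  sd_df <- stats::aggregate(value ~ model + fold + metric, sm, stats::sd,
                            na.rm = TRUE, na.action = stats::na.pass)
  names(mean_df)[names(mean_df) == "value"] <- "mean"
  mean_df$sd <- sd_df$value
  mean_df
}
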