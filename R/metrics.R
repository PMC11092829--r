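#' Classification metrics report
#'
#' Accuracy, macro- and support-weighted F1, and macro one-vs-rest AUC for a
#' matrix of predicted class probabilities. Predicted classes are the
#' row-wise argmax (ties broken toward the lowest class index, for
#' determinism). Macro averages weight every class equally; weighted averages
#' weight by class support. If some declared class is absent from `labels`,
#' its one-vs-rest AUC is undefined and the macro AUC is reported as `NA`
#' rather than 0.
#'
#' @param probs `N x K` matrix of class probabilities with class names as
#'   column names.
#' @param labels True classes (factor or character), drawn from
#'   `colnames(probs)`.
#' @return A list of class `metrics_report` with elements `accuracy`,
#'   `f1_macro`, `f1_weighted`, `auc_macro` and the per-class F1 table.
#' @export
classification_metrics <- function(probs, labels) {
  probs <- as.matrix(probs)
  classes <- colnames(probs)
  if (is.null(classes)) stop("'probs' needs class column names", call. = FALSE)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(probs), nrow(probs) >= 1)
  pred <- classes[max.col(probs, ties.method = "first")]
  acc <- mean(pred == labels)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  support <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  auc <- if (all(support > 0) && length(classes) >= 2) {
    mean(vapply(classes, function(cl) {
      resp <- factor(labels == cl, levels = c(FALSE, TRUE))
      as.numeric(pROC::auc(pROC::roc(resp, probs[, cl], quiet = TRUE,
                                     direction = "<", levels = c(FALSE, TRUE))))
    }, numeric(1)))
  } else NA_real_
  structure(list(accuracy = acc,
                 f1_macro = mean(f1),
                 f1_weighted = sum(f1 * support) / sum(support),
                 auc_macro = auc,
                 f1_per_class = f1,
                 support = support),
            class = "metrics_report")
}

#' Regression metrics report
#'
#' MAE, MSE, RMSE, sMAPE and \eqn{R^2} for real-valued predictions. sMAPE is
#' the symmetric mean absolute percentage error
#' \deqn{\frac{100}{n}\sum_i \frac{2\,\lvert \hat y_i - y_i\rvert}
#'   {\lvert y_i\rvert + \lvert \hat y_i\rvert},}
#' bounded in `[0, 200]`, with a `0/0` point defined as 0.
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}; it is `NA` when the targets are
#' constant (the mean model has zero residual variance).
#'
#' @param predictions,targets Numeric vectors of equal length.
#' @return A list of class `metrics_report` with elements `mae`, `mse`,
#'   `rmse`, `smape`, `r2`.
#' @export
regression_metrics <- function(predictions, targets) {
  predictions <- as.numeric(predictions)
  targets <- as.numeric(targets)
  stopifnot(length(predictions) == length(targets), length(targets) >= 1)
  err <- predictions - targets
  denom <- abs(targets) + abs(predictions)
  sm <- ifelse(denom == 0, 0, 2 * abs(err) / denom)
  ss_tot <- sum((targets - mean(targets))^2)
  structure(list(mae = mean(abs(err)),
                 mse = mean(err^2),
                 rmse = sqrt(mean(err^2)),
                 smape = 100 * mean(sm),
                 r2 = if (ss_tot == 0) NA_real_ else 1 - sum(err^2) / ss_tot),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  keep <- intersect(c("accuracy", "f1_macro", "f1_weighted", "auc_macro",
                      "mae", "mse", "rmse", "smape", "r2"), names(x))
  vals <- unlist(x[keep])
  cat("<metrics_report>\n")
  for (nm in names(vals)) {
    cat(sprintf("  %-12s %s\n", nm,
                formatC(vals[[nm]], digits = digits, format = "fg")))
  }
  invisible(x)
}
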