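#' Classification metrics for activity-cliff prediction
#'
#' Recall on the cliff class, the area under the ROC curve computed from
#' raw decision values, and the Matthews correlation coefficient. MCC is 0
#' by convention when any factor of its denominator vanishes; AUC is `NA`
#' when only one class is present.
#'
#' @param y_true,y_pred character vectors of `"AC"` / `"NON_AC"`.
#' @param decision numeric decision values (higher favours `"AC"`);
#'   optional, needed only for AUC.
#' @return named list with `recall`, `auc_roc`, `mcc` and the confusion
#'   counts `tp`, `fn`, `fp`, `tn`.
#' @examples
#' classification_metrics(c("AC", "AC", "NON_AC"), c("AC", "NON_AC", "NON_AC"),
#'                        c(1.2, -0.1, -2))
#' @export
classification_metrics <- function(y_true, y_pred, decision = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == "AC" & y_pred == "AC")
  fn <- sum(y_true == "AC" & y_pred == "NON_AC")
  fp <- sum(y_true == "NON_AC" & y_pred == "AC")
  tn <- sum(y_true == "NON_AC" & y_pred == "NON_AC")
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  auc <- NA_real_
  if (!is.null(decision) && length(unique(y_true)) == 2L) {
    r <- pROC::roc(response = y_true, predictor = as.numeric(decision),
                   levels = c("NON_AC", "AC"), direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(r))
  }
  list(recall = recall, auc_roc = auc, mcc = mcc(y_true, y_pred),
       tp = tp, fn = fn, fp = fp, tn = tn)
}

mcc <- function(y_true, y_pred) {
  tp <- sum(y_true == "AC" & y_pred == "AC")
  fn <- sum(y_true == "AC" & y_pred == "NON_AC")
  fp <- sum(y_true == "NON_AC" & y_pred == "AC")
  tn <- sum(y_true == "NON_AC" & y_pred == "NON_AC")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Series-wise leave-one-out evaluation
#'
#' Holds out one matched molecular series (all MMPs sharing a core) per
#' fold and trains on the remaining series, so no core ever crosses the
#' train/test boundary. Test MMPs containing a compound that also occurs in
#' any training MMP are eliminated from the fold, making every fold a
#' genuine extrapolation. The model (including its feature universe) is
#' rebuilt per fold from training data only; predictions are pooled over
#' folds before computing metrics.
#'
#' @param mms named list of `mmp_table` series from [group_into_mms()].
#' @param C,cv_folds,seed passed to [ac_svm()] per fold.
#' @param kernel kernel passed to [ac_svm()].
#' @return object of class `ac_eval`: `predictions` (data frame with fold,
#'   pair ids, decision value, predicted and true class), `metrics` (pooled
#'   [classification_metrics()]), `skipped` (folds with no evaluable test
#'   MMP).
#' @export
mms_loo_evaluate <- function(mms, C = c(0.01, 0.1, 1, 10, 100, 1000),
                             cv_folds = 5L, seed = 1L, kernel = "mmp") {
  if (length(mms) < 2L) stop("need at least 2 matched molecular series")
  preds <- list(); skipped <- character(0)
  for (f in seq_along(mms)) {
    test <- mms[[f]]
    train <- do.call(rbind, mms[-f])
    train_cpds <- unique(c(train$cid_low, train$cid_high))
    keep <- !(test$cid_low %in% train_cpds | test$cid_high %in% train_cpds)
    test <- test[keep, , drop = FALSE]
    if (nrow(test) == 0L) {
      skipped <- c(skipped, names(mms)[f]); next
    }
    if (length(unique(train$label)) < 2L) {
      skipped <- c(skipped, names(mms)[f]); next
    }
    fit <- ac_svm(train, C = C, cv_folds = cv_folds, seed = seed,
                  kernel = kernel)
    d <- predict(fit, test, type = "decision")
    preds[[length(preds) + 1L]] <- data.frame(
      fold = f, core = test$core, cid_low = test$cid_low,
      cid_high = test$cid_high, decision = d,
      pred = ifelse(d > 0, "AC", "NON_AC"), truth = test$label,
      stringsAsFactors = FALSE)
  }
  if (length(preds) == 0L) stop("no evaluable test MMPs in any fold")
  preds <- do.call(rbind, preds)
  met <- classification_metrics(preds$truth, preds$pred, preds$decision)
  structure(list(predictions = preds, metrics = met, skipped = skipped),
            class = "ac_eval")
}

#' @export
print.ac_eval <- function(x, ...) {
  m <- x$metrics
  cat("Series-wise leave-one-out evaluation\n")
  cat("  evaluated MMPs:", nrow(x$predictions),
      " folds:", length(unique(x$predictions$fold)),
      if (length(x$skipped)) paste0(" (skipped: ",
                                    length(x$skipped), ")") else "", "\n")
  cat(sprintf("  recall %.3f  AUC ROC %.3f  MCC %.3f\n",
              m$recall, m$auc_roc, m$mcc))
  cat(sprintf("  confusion: TP %d  FN %d  FP %d  TN %d\n",
              m$tp, m$fn, m$fp, m$tn))
  invisible(x)
}
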