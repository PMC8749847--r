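# Evaluation metrics: confusion counts, per-class average precision
# (ranked) and per-class precision (confusion-based), micro-mAP
# (pooled TP / (TP + FP), which equals overall accuracy for single-label
# prediction) and macro-mAP (unweighted mean of class APs).

#' Confusion matrix
#'
#' @param predictions,truths Equal-length label vectors.
#' @param class_names Ordered class labels; unknown labels are an error.
#' @return `K x K` integer matrix; entry `(i, j)` counts samples of true
#'   class `i` predicted as class `j`.
#' @export
confusion_matrix <- function(predictions, truths,
                             class_names = emotion_classes()) {
  if (length(predictions) != length(truths))
    gm_stop("'predictions' and 'truths' must have equal length", "contract")
  bad <- setdiff(unique(c(predictions, truths)), class_names)
  if (length(bad))
    gm_stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
            "contract")
  K <- length(class_names)
  cm <- matrix(0L, K, K, dimnames = list(true = class_names,
                                         predicted = class_names))
  if (length(truths)) {
    tab <- table(factor(truths, levels = class_names),
                 factor(predictions, levels = class_names))
    cm[] <- as.integer(tab)
  }
  cm
}

#' Micro mean average precision
#'
#' Pooled over classes: `sum(TP_i) / (sum(TP_i) + sum(FP_i))` with `TP_i`
#' the diagonal entry and `FP_i` the off-diagonal column sum. For
#' single-label multiclass prediction this is exactly
#' `trace(confusion) / n_samples`, i.e. overall accuracy.
#'
#' @param confusion Matrix from [confusion_matrix()].
#' @return Value in `[0, 1]`.
#' @export
micro_map <- function(confusion) {
  n <- sum(confusion)
  if (n == 0) gm_stop("micro-mAP undefined for zero samples", "metric")
  tp <- sum(diag(confusion))
  fp <- sum(colSums(confusion) - diag(confusion))
  tp / (tp + fp)
}

#' Macro mean average precision
#'
#' Unweighted arithmetic mean of the per-class average precision values.
#'
#' @param class_ap Numeric vector of per-class AP values (`NA` entries --
#'   classes with no positives -- are dropped with a warning).
#' @return Value in `[0, 1]`.
#' @export
macro_map <- function(class_ap) {
  if (!length(class_ap)) gm_stop("macro-mAP of zero classes", "metric")
  if (anyNA(class_ap)) {
    gm_warn(sprintf("%d class(es) without positives excluded from macro-mAP",
                    sum(is.na(class_ap))), "missing_class")
    class_ap <- class_ap[!is.na(class_ap)]
    if (!length(class_ap))
      gm_stop("macro-mAP undefined: no class has positives", "metric")
  }
  mean(class_ap)
}

#' Ranked average precision for one class
#'
#' Samples are sorted by descending score (ties broken by stable input
#' order); AP is the mean of precision-at-k over the ranks k holding a
#' positive sample. AP is 1 exactly when every positive outranks every
#' negative, and is bounded below by the class prevalence.
#'
#' @param scores Per-sample scores (e.g. the class's softmax probability).
#' @param truths Binary relevance (1/TRUE = the sample belongs to the
#'   class).
#' @return AP in `(0, 1]`, or `NA` (with a warning) when the class has no
#'   positive samples.
#' @export
class_average_precision <- function(scores, truths) {
  if (length(scores) != length(truths))
    gm_stop("'scores' and 'truths' must have equal length", "contract")
  truths <- as.logical(truths)
  if (!any(truths)) {
    gm_warn("no positive samples: class AP undefined", "missing_class")
    return(NA_real_)
  }
  ord <- order(-scores, seq_along(scores))   # stable tie-break
  rel <- truths[ord]
  prec_at_k <- cumsum(rel) / seq_along(rel)
  mean(prec_at_k[rel])
}

#' Evaluate a model on a dataset split
#'
#' Assembles features, runs the forward pass in inference mode and fills an
#' evaluation report: confusion counts, per-class ranked AP and
#' confusion-based precision, micro-mAP and macro-mAP (the mean of the
#' ranked APs). When `x` is a `gait_run`, the feature configuration stored
#' in its manifest is used; passing a conflicting `feature_config` is an
#' error, so a model is never scored on a feature set it was not trained
#' on.
#'
#' @param x A `gait_run` or `gait_model`.
#' @param dataset The labeled [gait_dataset()] split to score.
#' @param feature_config A [feature_config()]; optional for a `gait_run`.
#' @return An object of class `eval_report` with fields `confusion`,
#'   `class_ap`, `class_precision`, `micro_map`, `macro_map`, `n_samples`.
#' @export
evaluate_model <- function(x, dataset, feature_config = NULL) {
  if (inherits(x, "gait_run")) {
    stored <- do.call(gaitmood::feature_config,
                      x$manifest$feature_config[
                        c("use_jra", "use_jrd", "relative_joint", "center")])
    keys <- c("use_jra", "use_jrd", "center")
    if (!is.null(feature_config) &&
        !identical(unclass(feature_config)[keys], unclass(stored)[keys]))
      gm_stop(paste("feature_config conflicts with the run manifest;",
                    "evaluate with the feature set the model was trained on"),
              "contract")
    feature_config <- stored
    model <- x$model
  } else {
    model <- x
    if (is.null(feature_config))
      gm_stop("'feature_config' required when evaluating a bare model",
              "contract")
  }
  labels <- dataset_labels(dataset)
  if (anyNA(labels))
    gm_stop("evaluation requires a fully labeled dataset", "contract")
  feats <- features_for_dataset(dataset, feature_config)
  probs <- forward(model, feats)
  cls <- model$class_names %||% dataset$class_names
  pred <- cls[apply(probs, 1L, which.max)]
  cm <- confusion_matrix(pred, labels, cls)
  ap <- vapply(seq_along(cls), function(k)
    suppressWarnings(
      class_average_precision(probs[, k], labels == cls[k])),
    numeric(1))
  names(ap) <- cls
  col_tot <- colSums(cm)
  prec <- ifelse(col_tot > 0, diag(cm) / col_tot, NA_real_)
  names(prec) <- cls
  structure(
    list(confusion = cm,
         class_ap = ap,
         class_precision = prec,
         micro_map = micro_map(cm),
         macro_map = suppressWarnings(macro_map(ap)),
         n_samples = length(labels)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  micro-mAP=%.4f  macro-mAP=%.4f\n",
              x$n_samples, x$micro_map, x$macro_map))
  cat("per-class ranked AP / precision:\n")
  for (k in seq_along(x$class_ap))
    cat(sprintf("  %-8s %.4f / %s\n", names(x$class_ap)[k], x$class_ap[k],
                ifelse(is.na(x$class_precision[k]), "NA",
                       sprintf("%.4f", x$class_precision[k]))))
  cat("confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

report_to_list <- function(report) {
  list(n_samples = report$n_samples,
       micro_map = report$micro_map,
       macro_map = report$macro_map,
       class_ap = as.list(report$class_ap),
       class_precision = as.list(report$class_precision),
       confusion = apply(report$confusion, 1L, as.list, simplify = FALSE))
}
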