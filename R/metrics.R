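## Binary-classification evaluation suite.
##
## Confusion counts (OKC positive), rate metrics, composite indices (MCC,
## Cohen's kappa, Youden's J, G-mean, balanced accuracy, Jaccard), Brier
## score, natural-log loss with probability clipping, and ROC/AUC built
## from sample-derived cutoffs with trapezoidal integration. Metrics with a
## zero denominator are reported as NA (undefined), never silently 0.

#' Confusion counts for binary labels
#'
#' @param truth,predicted Equal-length binary label vectors (factor,
#'   character with OKC/NONKC, or 0/1); OKC is the positive class.
#' @return A `kc_confusion` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) < 1L) {
    stop("`truth` and `predicted` must be equal-length, non-empty", call. = FALSE)
  }
  yt <- as_binary_labels(truth)
  yp <- as_binary_labels(predicted)
  structure(
    list(
      tp = sum(yt == 1 & yp == 1),
      fp = sum(yt == 0 & yp == 1),
      tn = sum(yt == 0 & yp == 0),
      fn = sum(yt == 1 & yp == 0)
    ),
    class = "kc_confusion"
  )
}

#' Confusion counts from explicit cells
#'
#' @param tp,fp,tn,fn Non-negative counts, at least one positive.
#' @return A `kc_confusion`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn >= 1)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn), class = "kc_confusion")
}

safe_div <- function(num, den) if (den > 0) num / den else NA_real_

#' Natural-log loss with probability clipping
#'
#' @param probabilities Predicted positive-class probabilities.
#' @param truth Binary labels.
#' @param eps Clipping bound; probabilities are clamped to `[eps, 1 - eps]`.
#' @return Mean negative log-likelihood (natural log).
#' @export
log_loss <- function(probabilities, truth, eps = 1e-15) {
  y <- as_binary_labels(truth)
  stopifnot(length(probabilities) == length(y))
  bce_loss(probabilities, y, eps = eps)
}

#' ROC curve points
#'
#' Cutoffs are the distinct predicted probabilities (plus a sentinel above
#' the maximum), so the curve starts at (0, 0) and ends at (1, 1) with
#' non-decreasing coordinates.
#'
#' @param probabilities Predicted positive-class probabilities.
#' @param truth Binary labels; both classes must be present.
#' @return A `kc_roc` tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(probabilities, truth) {
  y <- as_binary_labels(truth)
  stopifnot(length(probabilities) == length(y))
  if (length(unique(y)) < 2L) {
    stop("ROC requires both classes in `truth`", call. = FALSE)
  }
  cuts <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  pos <- sum(y == 1)
  neg <- sum(y == 0)
  pts <- purrr::map_dfr(cuts, function(ct) {
    pred <- probabilities >= ct
    tibble::tibble(
      threshold = ct,
      fpr = sum(pred & y == 0) / neg,
      tpr = sum(pred & y == 1) / pos
    )
  })
  class(pts) <- c("kc_roc", class(pts))
  pts
}

#' Area under the ROC curve by trapezoidal integration
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(probabilities, truth) {
  pts <- roc_points(probabilities, truth)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' Full metric report
#'
#' Computes the complete evaluation suite from confusion counts and,
#' when probabilities are supplied, the probability-based metrics (log
#' loss, Brier score, AUC and the ROC curve). With single-class truth the
#' AUC is undefined and reported as NA with an explanatory attribute.
#'
#' @param counts A `kc_confusion` (from [confusion()] or
#'   [confusion_counts()]).
#' @param probabilities Optional predicted probabilities aligned with
#'   `truth`.
#' @param truth Optional binary labels, required with `probabilities`.
#' @return A `kc_metric_report` list; see [tidy.kc_metric_report()].
#' @export
metric_report <- function(counts, probabilities = NULL, truth = NULL) {
  stopifnot(inherits(counts, "kc_confusion"))
  tp <- counts$tp
  fp <- counts$fp
  tn <- counts$tn
  fn <- counts$fn
  total <- tp + fp + tn + fn
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  acc <- safe_div(tp + tn, total)
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else {
    NA_real_
  }
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (mcc_den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den else NA_real_
  p_obs <- acc
  p_exp <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / total^2
  kappa <- if (!is.na(p_obs) && p_exp < 1) (p_obs - p_exp) / (1 - p_exp) else NA_real_
  jaccard <- safe_div(tp, tp + fp + fn)
  bal_acc <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  youden <- if (!is.na(sens) && !is.na(spec)) sens + spec - 1 else NA_real_
  gmean <- if (!is.na(sens) && !is.na(spec)) sqrt(sens * spec) else NA_real_

  ll <- brier <- auc <- NA_real_
  roc <- NULL
  auc_note <- NULL
  if (!is.null(probabilities)) {
    if (is.null(truth)) stop("`truth` is required with `probabilities`", call. = FALSE)
    y <- as_binary_labels(truth)
    ll <- log_loss(probabilities, y)
    brier <- mean((probabilities - y)^2)
    if (length(unique(y)) >= 2L) {
      roc <- roc_points(probabilities, y)
      auc <- auc_score(probabilities, y)
    } else {
      auc_note <- "AUC undefined: truth contains a single class"
    }
  }

  structure(
    list(
      counts = counts,
      accuracy = acc, precision = prec, recall = sens, sensitivity = sens,
      specificity = spec, f1 = f1, balanced_accuracy = bal_acc,
      mcc = mcc, kappa = kappa, jaccard = jaccard,
      youden_j = youden, g_mean = gmean,
      brier = brier, log_loss = ll, auc = auc,
      roc = roc, auc_note = auc_note
    ),
    class = "kc_metric_report"
  )
}

#' Tidy a metric report into a long tibble
#'
#' @param x A `kc_metric_report`.
#' @param ... Unused.
#' @return Tibble with `metric` and `value` (undefined metrics are NA).
#' @export
tidy.kc_metric_report <- function(x, ...) {
  nm <- c(
    "accuracy", "precision", "recall", "sensitivity", "specificity", "f1",
    "balanced_accuracy", "mcc", "kappa", "jaccard", "youden_j", "g_mean",
    "brier", "log_loss", "auc"
  )
  tibble::tibble(metric = nm, value = purrr::map_dbl(nm, ~ x[[.x]] %||% NA_real_))
}

#' @export
print.kc_metric_report <- function(x, ...) {
  print(tidy(x), n = Inf)
  if (!is.null(x$auc_note)) cat(x$auc_note, "\n")
  invisible(x)
}

#' Per-class classification report
#'
#' Text-style summary: precision, recall, F1 and support for each class.
#'
#' @param truth,predicted Binary label vectors; OKC positive.
#' @return Tibble with one row per class.
#' @export
classification_report <- function(truth, predicted) {
  cm <- confusion(truth, predicted)
  purrr::map_dfr(
    list(
      list(class = "OKC", tp = cm$tp, fp = cm$fp, fn = cm$fn, support = cm$tp + cm$fn),
      list(class = "NONKC", tp = cm$tn, fp = cm$fn, fn = cm$fp, support = cm$tn + cm$fp)
    ),
    function(r) {
      prec <- safe_div(r$tp, r$tp + r$fp)
      rec <- safe_div(r$tp, r$tp + r$fn)
      tibble::tibble(
        class = r$class, precision = prec, recall = rec,
        f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else NA_real_,
        support = r$support
      )
    }
  )
}
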