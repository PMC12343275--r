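# Evaluation machinery: confusion matrix, per-class precision/recall/F1
# with Wilson 95% confidence intervals, overall accuracy with CI, and
# one-vs-rest ROC curves with trapezoidal AUC.

#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the score test: with `z` the standard normal quantile at
#' `1 - alpha/2`, the interval has center `(p + z^2/2n) / (1 + z^2/n)` and
#' half-width `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`, clipped to
#' `[0, 1]`. Unlike the Wald interval it behaves sensibly at `k = 0` and
#' `k = n` (for `k = n` the lower bound is `1 / (1 + z^2/n)`).
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level, default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' wilson_interval(25, 27) # c(0.766, 0.979) at 3 dp
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n < 1) stop("wilson_interval requires n >= 1")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # at k = 0 / k = n the boundary is exact, not a rounding artifact
  low <- if (k == 0) 0 else max(0, center - half)
  high <- if (k == n) 1 else min(1, center + half)
  c(low = low, high = high)
}

#' Confusion matrix
#'
#' @param true_labels,predicted_labels Equal-length label vectors; every
#'   label must appear in `class_names`.
#' @param class_names Character vector fixing the row/column order.
#' @return A `num_classes x num_classes` integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_names) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  stopifnot(length(true_labels) == length(predicted_labels))
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), class_names)
  if (length(unknown))
    stop("label(s) not in class_names: ", paste(unknown, collapse = ", "))
  tf <- factor(true_labels, levels = class_names)
  pf <- factor(predicted_labels, levels = class_names)
  m <- table(true = tf, predicted = pf)
  matrix(as.integer(m), nrow = length(class_names),
         dimnames = list(true = class_names, predicted = class_names))
}

#' Per-class precision, recall and F1 with Wilson confidence intervals
#'
#' For class `c`: precision = `cm[c,c] / colsum(c)` (denominator = samples
#' predicted as `c`), recall = `cm[c,c] / rowsum(c)` (denominator = true
#' `c` samples), `F1 = 2PR/(P+R)`. Each proportion carries a Wilson
#' interval computed from its own `(k, n)`. A zero denominator yields a
#' 0 metric flagged `undefined` with a degenerate interval from
#' `(0, 0)` counts omitted (`NA` bounds); a 0/0 F1 is reported as 0.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @param confidence Confidence level for the intervals.
#' @return Data frame with one row per class: precision / recall (+ CI
#'   bounds, `k`, `n`) and F1.
#' @export
precision_recall_f1 <- function(cm, confidence = 0.95) {
  classes <- rownames(cm)
  out <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    npred <- sum(cm[, i])
    ntrue <- sum(cm[i, ])
    pr <- metric_with_ci(tp, npred, confidence)
    rc <- metric_with_ci(tp, ntrue, confidence)
    f1 <- if (pr$point + rc$point == 0) 0 else
      2 * pr$point * rc$point / (pr$point + rc$point)
    data.frame(class = classes[i],
               precision = pr$point, precision_low = pr$low,
               precision_high = pr$high, precision_k = pr$k,
               precision_n = pr$n, precision_undefined = pr$undefined,
               recall = rc$point, recall_low = rc$low,
               recall_high = rc$high, recall_k = rc$k, recall_n = rc$n,
               recall_undefined = rc$undefined,
               f1 = f1, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

metric_with_ci <- function(k, n, confidence = 0.95) {
  if (n == 0) {
    return(list(point = 0, low = NA_real_, high = NA_real_,
                k = 0L, n = 0L, undefined = TRUE))
  }
  ci <- wilson_interval(k, n, confidence)
  list(point = k / n, low = ci[["low"]], high = ci[["high"]],
       k = as.integer(k), n = as.integer(n), undefined = FALSE)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps the score assigned to the positive class over its unique values
#' (grouping ties), recording the false- and true-positive rates, and
#' integrates by the trapezoidal rule. Equals the tie-corrected
#' Mann-Whitney statistic `U / (n1 * n0)`.
#'
#' @param true_labels Label vector.
#' @param scores Numeric matrix, one row per sample, columns named (or
#'   ordered) by class — typically softmax probabilities.
#' @param positive_class The class treated as positive.
#' @param class_names Character vector mapping score columns to classes
#'   (defaults to `colnames(scores)`).
#' @return List with `points` (data frame of threshold, fpr, tpr) and
#'   `auc`. If the class is absent from `true_labels` the AUC is `NA` and
#'   `undefined` is `TRUE`.
#' @export
roc_ovr <- function(true_labels, scores, positive_class,
                    class_names = colnames(scores)) {
  true_labels <- as.character(true_labels)
  if (is.null(class_names)) stop("scores must have class names")
  ci <- match(positive_class, class_names)
  if (is.na(ci)) stop("unknown positive class: ", positive_class)
  s <- scores[, ci]
  y <- true_labels == positive_class
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    return(list(points = data.frame(threshold = numeric(), fpr = numeric(),
                                    tpr = numeric()),
                auc = NA_real_, undefined = TRUE))
  }
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(s >= t & y) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(s >= t & !y) / n0, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc, undefined = FALSE)
}

#' Evaluate a trained model on a test set
#'
#' Runs the model over the test images (in inference mode, so the result
#' is deterministic), assembles the confusion matrix, per-class
#' precision/recall/F1 with Wilson CIs, overall accuracy
#' (`trace / total`) with its Wilson CI, and one-vs-rest ROC/AUC per
#' class.
#'
#' @param model Trained `cytoattn_model`.
#' @param images Test images (list of pixel arrays or `image_sample`s).
#' @param labels True labels (taken from samples when omitted).
#' @param batch_size Forward-pass batch size.
#' @return An `eval_report`: list with `confusion`, `metrics`, `accuracy`
#'   (point + CI + k/n), `roc` (per class), `auc` (named vector),
#'   `n_test`, `predicted`, `probs`.
#' @export
evaluate_model <- function(model, images, labels = NULL, batch_size = 64L) {
  if (length(images) && inherits(images[[1L]], "image_sample")) {
    if (is.null(labels))
      labels <- vapply(images, `[[`, character(1), "label")
    images <- lapply(images, `[[`, "pixels")
  }
  if (length(images) == 0L) stop("empty test set")
  labels <- as.character(labels)
  cn <- model$config$class_names
  probs <- matrix(NA_real_, nrow = length(images), ncol = length(cn),
                  dimnames = list(NULL, cn))
  for (start in seq(1L, length(images), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(images))
    fw <- model_forward(model, images[idx])
    probs[idx, ] <- t(fw$probs)
  }
  predicted <- cn[apply(probs, 1L, which.max)]
  cm <- confusion_matrix(labels, predicted, cn)
  metrics <- precision_recall_f1(cm)
  acc <- metric_with_ci(sum(diag(cm)), sum(cm))
  roc <- lapply(cn, function(cls) roc_ovr(labels, probs, cls))
  names(roc) <- cn
  structure(list(confusion = cm, metrics = metrics, accuracy = acc,
                 roc = roc,
                 auc = vapply(roc, `[[`, numeric(1), "auc"),
                 n_test = length(images), predicted = predicted,
                 probs = probs),
            class = "eval_report")
}

# half-up rounding to `digits`, the convention used for report tables
round_half_up <- function(x, digits = 3L) {
  floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report>  n = %d,  accuracy %.4f (95%% CI %.3f, %.3f)\n",
              x$n_test, x$accuracy$point, x$accuracy$low, x$accuracy$high))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s P %.3f (%.3f, %.3f)  R %.3f (%.3f, %.3f)  F1 %.3f  AUC %s\n",
                m$class[i], m$precision[i], m$precision_low[i],
                m$precision_high[i], m$recall[i], m$recall_low[i],
                m$recall_high[i], m$f1[i],
                ifelse(is.na(x$auc[i]), "NA", sprintf("%.3f", x$auc[i]))))
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON, the confusion matrix and per-class ROC
#' points as CSVs, and (optionally) confusion-heatmap and ROC plots as
#' PNGs.
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @param plots Also write PNG plots.
#' @return Invisibly, the directory.
#' @export
write_eval_report <- function(report, dir, plots = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    accuracy = report$accuracy,
    metrics = report$metrics,
    confusion = report$confusion,
    auc = as.list(report$auc),
    n_test = report$n_test
  )
  jsonlite::write_json(payload, file.path(dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write.csv(report$confusion, file.path(dir, "confusion_matrix.csv"))
  for (cls in names(report$roc)) {
    safe <- gsub("[^A-Za-z0-9_-]", "_", cls)
    write.csv(report$roc[[cls]]$points,
              file.path(dir, paste0("roc_", safe, ".csv")),
              row.names = FALSE)
  }
  if (plots) {
    plot_confusion(report$confusion, file.path(dir, "confusion_matrix.png"))
    plot_roc(report, file.path(dir, "roc_curves.png"))
  }
  invisible(dir)
}

#' Confusion-matrix heatmap
#' @param cm Confusion matrix.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
plot_confusion <- function(cm, path) {
  grDevices::png(path, width = 640, height = 600)
  on.exit(grDevices::dev.off())
  k <- nrow(cm)
  par(mar = c(7, 7, 3, 1))
  # row 1 (true class) on top; lighter-to-darker blue with count
  image(seq_len(k), seq_len(k), t(cm[k:1, , drop = FALSE]),
        col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
        axes = FALSE, xlab = "", ylab = "")
  axis(1, at = seq_len(k), labels = colnames(cm), las = 2)
  axis(2, at = seq_len(k), labels = rev(rownames(cm)), las = 2)
  title("Confusion matrix (rows: true, cols: predicted)")
  for (i in seq_len(k)) for (j in seq_len(k))
    text(j, k + 1 - i, cm[i, j],
         col = if (cm[i, j] > max(cm) / 2) "white" else "black")
  invisible(path)
}

#' One-vs-rest ROC curves
#' @param report An `eval_report`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
plot_roc <- function(report, path) {
  grDevices::png(path, width = 640, height = 600)
  on.exit(grDevices::dev.off())
  cn <- names(report$roc)
  cols <- grDevices::hcl.colors(length(cn), "Dark 3")
  plot(c(0, 1), c(0, 1), type = "n", xlab = "False positive rate",
       ylab = "True positive rate", main = "One-vs-rest ROC")
  abline(0, 1, lty = 2, col = "grey")
  for (i in seq_along(cn)) {
    p <- report$roc[[cn[i]]]$points
    if (nrow(p)) lines(c(p$fpr, 1), c(p$tpr, 1), col = cols[i], lwd = 2)
  }
  legend("bottomright",
         legend = sprintf("%s (AUC %.3f)", cn, report$auc), col = cols,
         lwd = 2, cex = 0.8)
  invisible(path)
}
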