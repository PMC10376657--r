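#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (so 11.25 -> 11.3 at one decimal),
#' matching how reported percentages are conventionally printed; base R's
#' `round()` rounds ties to even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Confusion counts for the two tapping classes
#'
#' @param true_labels,pred_labels Vectors of labels from `{RHLF, RHTF}`.
#' @param classes Class ordering for the matrix.
#' @return 2x2 integer matrix, rows = true class, columns = predicted class.
#' @export
confusion <- function(true_labels, pred_labels, classes = c("RHLF", "RHTF")) {
  true_labels <- as.character(true_labels)
  pred_labels <- as.character(pred_labels)
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length", call. = FALSE)
  bad <- setdiff(unique(c(true_labels, pred_labels)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  m <- table(factor(true_labels, classes), factor(pred_labels, classes))
  out <- matrix(as.integer(m), 2, 2, dimnames = dimnames(m))
  names(dimnames(out)) <- c("true", "predicted")
  out
}

#' Per-class classification metrics from confusion counts
#'
#' For each class: TPR = 100 TP / (TP + FN), FNR = 100 FN / (TP + FN),
#' PPV = 100 TP / (TP + FP), FDR = 100 FP / (TP + FP), plus overall accuracy
#' 100 sum(TP) / N. Percentages are reported both exactly and rounded
#' half-up to one decimal. TPR + FNR = 100 and PPV + FDR = 100 exactly
#' before rounding.
#'
#' @param counts 2x2 confusion matrix from [confusion()] (rows = true).
#' @return An object of class `confusion_metrics`: data.frame `per_class`
#'   (TP, FN, FP, TPR, FNR, PPV, FDR and rounded variants), `accuracy`,
#'   `accuracy_rounded`, `n`, and `undefined` flags.
#' @examples
#' cm <- matrix(c(140, 16, 18, 142), 2, 2,
#'              dimnames = list(c("RHLF", "RHTF"), c("RHLF", "RHTF")))
#' eq1_metrics(cm)$accuracy_rounded  # 89.2
#' @export
eq1_metrics <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0))
  classes <- rownames(counts)
  if (is.null(classes)) classes <- c("RHLF", "RHTF")
  n <- sum(counts)
  tp <- diag(counts)
  fn <- rowSums(counts) - tp
  fp <- colSums(counts) - tp
  real_pos <- tp + fn
  pred_pos <- tp + fp
  undefined <- real_pos == 0 | pred_pos == 0
  if (any(undefined))
    warning("metrics undefined for class(es) with no real or no predicted positives: ",
            paste(classes[undefined], collapse = ", "), call. = FALSE)
  safe <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  per_class <- data.frame(
    class = classes, TP = tp, FN = fn, FP = fp,
    TPR = safe(tp, real_pos), FNR = safe(fn, real_pos),
    PPV = safe(tp, pred_pos), FDR = safe(fp, pred_pos),
    row.names = NULL)
  for (col in c("TPR", "FNR", "PPV", "FDR"))
    per_class[[paste0(col, "_rounded")]] <- round_half_up(per_class[[col]], 1)
  acc <- 100 * sum(tp) / n
  structure(list(per_class = per_class, accuracy = acc,
                 accuracy_rounded = round_half_up(acc, 1), n = n,
                 undefined = undefined),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat("Class  TP   FN   FP   TPR(%) FNR(%) PPV(%) FDR(%)\n")
  pc <- x$per_class
  for (i in seq_len(nrow(pc)))
    cat(sprintf("%-5s %4d %4d %4d   %5.1f  %5.1f  %5.1f  %5.1f\n",
                pc$class[i], pc$TP[i], pc$FN[i], pc$FP[i],
                pc$TPR_rounded[i], pc$FNR_rounded[i],
                pc$PPV_rounded[i], pc$FDR_rounded[i]))
  cat(sprintf("Overall accuracy: %.1f%% (n = %d)\n", x$accuracy_rounded, x$n))
  invisible(x)
}

#' ROC curve and AUC by the Mann-Whitney statistic
#'
#' AUC is the probability that a randomly chosen positive outscores a
#' randomly chosen negative, ties counted one half — computed from ranks, so
#' it equals exhaustive pair counting exactly.
#'
#' @param scores Classifier scores for the positive class.
#' @param true_labels Labels; `positive` names the positive class.
#' @param positive Positive class label.
#' @return List with `auc` and `roc` (data.frame of FPR/TPR points over all
#'   score thresholds).
#' @export
roc_auc <- function(scores, true_labels, positive = "RHTF") {
  true_labels <- as.character(true_labels)
  stopifnot(length(scores) == length(true_labels))
  pos <- true_labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    FPR = vapply(thr, function(th) sum(scores[!pos] >= th) / n0, numeric(1)),
    TPR = vapply(thr, function(th) sum(scores[pos] >= th) / n1, numeric(1)))
  list(auc = auc, roc = roc)
}

#' Write a metrics report as JSON and ROC points as CSV
#' @param metrics A `confusion_metrics`.
#' @param path JSON output path.
#' @param roc Optional ROC data.frame written next to it as `<path>.roc.csv`.
#' @export
write_metrics_json <- function(metrics, path, roc = NULL) {
  jsonlite::write_json(list(per_class = metrics$per_class,
                            accuracy = metrics$accuracy,
                            accuracy_rounded = metrics$accuracy_rounded,
                            n = metrics$n),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc))
    utils::write.csv(roc, paste0(path, ".roc.csv"), row.names = FALSE)
  invisible(path)
}
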