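## Evaluation suite: confusion matrices, accuracy/precision/recall, MCC
## (binary and generalized multi-class), one-vs-rest ROC with micro/macro
## AUC, and row-normalized heat-map matrices.

#' Confusion matrix of predictions
#'
#' @param truth,predicted Per-sample labels of equal length.
#' @param classes Optional ordered class labels; defaults to the sorted
#'   union of the observed labels.
#' @return Square integer matrix, rows = truth, columns = predicted.
#' @export
confusionMatrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (length(truth) == 0L) stop("no predictions to evaluate")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, classes), factor(predicted, classes))
  m <- matrix(as.integer(cm), length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

binaryCounts <- function(cm, positiveClass) {
  classes <- rownames(cm)
  if (!positiveClass %in% classes) stop("unknown positive class")
  p <- which(classes == positiveClass)
  tp <- cm[p, p]
  fn <- sum(cm[p, -p])
  fp <- sum(cm[-p, p])
  tn <- sum(cm[-p, -p])
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Accuracy, recall and precision for one positive class
#'
#' Exact count ratios: accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall
#' `TP/(TP+FN)`, precision `TP/(TP+FP)`. A precision with no positive
#' prediction (`TP+FP = 0`) is reported as 0 with
#' `precisionDefined = FALSE`.
#'
#' @param cm A square confusion matrix ([confusionMatrix()]).
#' @param positiveClass The class treated as positive (other classes are
#'   pooled as negative).
#' @return List with `accuracy`, `precision`, `recall`, `f1`,
#'   `precisionDefined`.
#' @export
basicMetrics <- function(cm, positiveClass) {
  if (sum(cm) == 0L) stop("empty confusion matrix")
  k <- binaryCounts(cm, positiveClass)
  acc <- (k$tp + k$tn) / (k$tp + k$tn + k$fp + k$fn)
  rec <- if (k$tp + k$fn == 0) 0 else k$tp / (k$tp + k$fn)
  precDefined <- (k$tp + k$fp) > 0
  prec <- if (precDefined) k$tp / (k$tp + k$fp) else 0
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       precisionDefined = precDefined)
}

#' Matthews correlation coefficient
#'
#' Binary matrices use
#' `((TP*TN) - (FP*FN)) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; any zero
#' factor in the denominator yields 0 by convention. Larger matrices use
#' the generalized multi-class coefficient
#' `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2))(s^2 - sum(t_k^2)))`
#' (with `c` the trace, `s` the total, `p_k`/`t_k` the predicted/true
#' column and row totals), which reduces to the binary form for two
#' classes. Range `[-1, +1]`; +1 is a perfect classifier.
#'
#' @param cm A square confusion matrix.
#' @param positiveClass Positive class for the binary form (defaults to
#'   the second class).
#' @return Scalar in `[-1, 1]`.
#' @export
mcc <- function(cm, positiveClass = NULL) {
  if (sum(cm) == 0L) stop("empty confusion matrix")
  if (nrow(cm) == 2L) {
    if (is.null(positiveClass)) positiveClass <- rownames(cm)[2L]
    k <- binaryCounts(cm, positiveClass)
    den2 <- (k$tp + k$fp) * (k$tp + k$fn) * (k$tn + k$fp) * (k$tn + k$fn)
    if (den2 == 0) return(0)
    return((k$tp * k$tn - k$fp * k$fn) / sqrt(den2))
  }
  s <- sum(cm)
  c0 <- sum(diag(cm))
  p <- colSums(cm)   # predicted totals
  t0 <- rowSums(cm)  # true totals
  den2 <- (s^2 - sum(p^2)) * (s^2 - sum(t0^2))
  if (den2 <= 0) return(0)
  (c0 * s - sum(p * t0)) / sqrt(den2)
}

## One-vs-rest ROC curve for a logical positive vector and scores:
## thresholds at distinct score values (descending), trapezoidal AUC.
binaryRoc <- function(positive, scores) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  nP <- sum(positive); nN <- sum(!positive)
  cuts <- which(diff(s) != 0)
  at <- c(cuts, length(s))
  tp <- cumsum(y)[at]; fp <- cumsum(!y)[at]
  tpr <- c(0, tp / nP); fpr <- c(0, fp / nN)
  thr <- c(Inf, s[at])
  keep <- !duplicated(cbind(fpr, tpr))
  curve <- data.frame(fpr = fpr[keep], tpr = tpr[keep],
                      threshold = thr[keep])
  auc <- sum(diff(curve$fpr) *
             (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' One-vs-rest ROC curves with micro/macro AUC
#'
#' For every class, samples of that class are the positives and the
#' class's score column is thresholded at its distinct values; AUC is the
#' trapezoidal area. The macro average is the unweighted mean of the
#' per-class AUCs; the micro average pools every (sample, class) binary
#' indicator with its score into one stream before computing a single
#' curve. Classes without both a positive and a negative sample are
#' skipped with a flag.
#'
#' @param truth Per-sample true labels.
#' @param scores Samples-by-classes score matrix with column names.
#' @return List with `perClass` (named list of curve + auc), `microAuc`,
#'   `macroAuc`, `skipped` (character).
#' @export
rocAuc <- function(truth, scores) {
  truth <- as.character(truth)
  scores <- as.matrix(scores)
  classes <- colnames(scores)
  if (is.null(classes)) stop("scores must have class column names")
  perClass <- list(); skipped <- character()
  poolY <- logical(); poolS <- numeric()
  for (cl in classes) {
    pos <- truth == cl
    poolY <- c(poolY, pos); poolS <- c(poolS, scores[, cl])
    if (!any(pos) || all(pos)) { skipped <- c(skipped, cl); next }
    perClass[[cl]] <- binaryRoc(pos, scores[, cl])
  }
  if (length(perClass) == 0L)
    stop("ROC undefined: no class has both positive and negative samples")
  macro <- mean(vapply(perClass, `[[`, numeric(1), "auc"))
  micro <- binaryRoc(poolY, poolS)$auc
  list(perClass = perClass, microAuc = micro, macroAuc = macro,
       skipped = skipped)
}

#' Row-normalized confusion heat map
#'
#' Divides every row of the confusion matrix by its total so rows sum to
#' 1; all-zero truth rows are emitted as zeros and listed in the
#' `zeroRows` attribute.
#'
#' @param cm A square confusion matrix.
#' @return Numeric matrix of row proportions.
#' @export
normalizedHeatmap <- function(cm) {
  rs <- rowSums(cm)
  out <- cm / ifelse(rs == 0, 1, rs)
  out <- matrix(out, nrow(cm), ncol(cm), dimnames = dimnames(cm))
  attr(out, "zeroRows") <- rownames(cm)[rs == 0]
  out
}

#' Full classification report
#'
#' Bundles the confusion matrix, per-class one-vs-rest accuracy /
#' precision / recall / F1, the overall accuracy, the Matthews correlation
#' coefficient, the row-normalized heat map and (when scores are given)
#' one-vs-rest ROC curves with micro/macro AUC.
#'
#' @param truth,predicted Per-sample labels.
#' @param scores Optional samples-by-classes score matrix.
#' @param classes Optional ordered class labels.
#' @return A [ClassificationReport-class].
#' @export
classificationReport <- function(truth, predicted, scores = NULL,
                                 classes = NULL) {
  cm <- confusionMatrix(truth, predicted, classes)
  classes <- rownames(cm)
  per <- do.call(rbind, lapply(classes, function(cl) {
    b <- basicMetrics(cm, cl)
    data.frame(class = cl, accuracy = b$accuracy, precision = b$precision,
               recall = b$recall, f1 = b$f1,
               precision_defined = b$precisionDefined)
  }))
  roc <- list(); micro <- NA_real_; macro <- NA_real_
  if (!is.null(scores)) {
    r <- rocAuc(truth, scores[, classes, drop = FALSE])
    roc <- r$perClass; micro <- r$microAuc; macro <- r$macroAuc
  }
  new("ClassificationReport", classes = classes, confusion = cm,
      perClass = per, overallAccuracy = sum(diag(cm)) / sum(cm),
      mcc = mcc(cm), heatmap = normalizedHeatmap(cm), roc = roc,
      microAuc = micro, macroAuc = macro)
}

#' Serialize a classification report
#'
#' Writes the report as a structured JSON document; optionally the ROC
#' points as TSV (class, fpr, tpr, threshold) and the heat map as CSV.
#'
#' @param report A [ClassificationReport-class].
#' @param file JSON output path.
#' @param rocFile,heatmapFile Optional TSV/CSV side files.
#' @export
writeReport <- function(report, file, rocFile = NULL, heatmapFile = NULL) {
  doc <- list(classes = report@classes,
              confusion = unclass(report@confusion),
              per_class = report@perClass,
              overall_accuracy = report@overallAccuracy,
              mcc = report@mcc,
              heatmap = matrix(report@heatmap, nrow(report@heatmap)),
              micro_auc = report@microAuc, macro_auc = report@macroAuc)
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(rocFile) && length(report@roc)) {
    rows <- do.call(rbind, lapply(names(report@roc), function(cl) {
      cbind(class = cl, report@roc[[cl]]$curve)
    }))
    utils::write.table(rows, rocFile, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(heatmapFile))
    utils::write.csv(as.data.frame(report@heatmap), heatmapFile)
  invisible(file)
}
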