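## Classification and cleavage-site performance measures.
##
## Conventions: confusion matrices are 5 x 5 with rows = predicted class
## and columns = observed class, class order tp_classes.  One-vs-rest
## metrics follow precision = tp/(tp+fp), recall = tp/(tp+fn),
## F1 = 2 pr / (p + r), MCC = (tp tn - fp fn) / sqrt((tp+fn)(tp+fp)(tn+fp)(tn+fn)),
## with any zero denominator yielding 0.

#' Confusion matrix of predicted vs observed classes
#'
#' @param predicted,observed character vectors of class labels
#'   (values in \code{\link{tp_classes}}).
#' @return 5 x 5 integer matrix, rows = predicted, columns = observed.
#' @export
confusion_matrix <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  if (!all(predicted %in% tp_classes)) stop("unknown predicted label")
  if (!all(observed %in% tp_classes)) stop("unknown observed label")
  tab <- table(factor(predicted, levels = tp_classes),
               factor(observed, levels = tp_classes))
  m <- matrix(as.integer(tab), 5, 5, dimnames = list(predicted = tp_classes,
                                                     observed = tp_classes))
  m
}

#' One-vs-rest reduction of a confusion matrix
#'
#' @param cm confusion matrix from \code{\link{confusion_matrix}}.
#' @param cls class name.
#' @return named vector with elements \code{tp}, \code{tn}, \code{fp},
#'   \code{fn}.
#' @export
binary_counts <- function(cm, cls) {
  stopifnot(cls %in% tp_classes)
  i <- match(cls, tp_classes)
  tp <- cm[i, i]
  fp <- sum(cm[i, -i])
  fn <- sum(cm[-i, i])
  tn <- sum(cm[-i, -i])
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Precision, recall, F1 and MCC from binary counts
#'
#' Zero denominators yield 0 for the affected measure.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return named numeric vector \code{precision}, \code{recall}, \code{f1},
#'   \code{mcc}.
#' @export
precision_recall_f1_mcc <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  tp <- as.numeric(tp); tn <- as.numeric(tn)   # avoid integer overflow in MCC
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  den <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  c(precision = precision, recall = recall, f1 = f1, mcc = mcc)
}

#' Per-class metrics report for a confusion matrix
#'
#' @param cm confusion matrix.
#' @return data.frame with one row per class: tp/tn/fp/fn counts,
#'   precision, recall, f1, mcc.
#' @export
classification_report <- function(cm) {
  rows <- lapply(tp_classes, function(cls) {
    b <- binary_counts(cm, cls)
    m <- precision_recall_f1_mcc(b["tp"], b["tn"], b["fp"], b["fn"])
    data.frame(class = cls, t(b), t(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Macro-averaged F1 over the five classes
#'
#' @param cm confusion matrix.
#' @return mean of the per-class F1 scores.
#' @export
macro_f1 <- function(cm) mean(classification_report(cm)$f1)

#' Windowed cleavage-site recall
#'
#' Among records of class \code{cls} that were also classified as
#' \code{cls}, the fraction whose predicted cleavage site lies within
#' \code{window} residues (two-sided) of the annotated one.  Restricting to
#' correctly classified records mirrors how cleavage-site accuracy is
#' normally reported for this task.
#'
#' @param predicted_class,predicted_cs vectors of predictions per record.
#' @param observed_class,observed_cs vectors of annotations per record.
#' @param cls one of SP, mTP, cTP, luTP.
#' @param window non-negative integer shift tolerance (0 to 5 typical).
#' @return fraction in [0, 1]; NA if no record of \code{cls} was correctly
#'   classified.
#' @export
cs_recall <- function(predicted_class, predicted_cs, observed_class, observed_cs,
                      cls, window = 0L) {
  stopifnot(cls %in% tp_cs_classes, window >= 0)
  sel <- observed_class == cls & predicted_class == cls
  if (!any(sel)) return(NA_real_)
  hit <- abs(predicted_cs[sel] - observed_cs[sel]) <= window
  hit[is.na(hit)] <- FALSE
  mean(hit)
}

#' One-vs-rest ROC curve by threshold sweep
#'
#' @param scores numeric scores in [0, 1] for class \code{cls} (higher =
#'   more confident).
#' @param labels observed class labels.
#' @param cls positive class.
#' @return data.frame with columns \code{fpr}, \code{tpr}, starting at
#'   (0, 0) and ending at (1, 1).
#' @export
roc_points <- function(scores, labels, cls) {
  pos <- labels == cls
  if (all(pos) || !any(pos)) stop("ROC needs both positive and negative records")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0)
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' Area under a ROC curve (trapezoidal)
#'
#' @param roc data.frame from \code{\link{roc_points}}.
#' @return scalar AUC.
#' @export
roc_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
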