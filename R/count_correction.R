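## Confusion-matrix based correction of proteome-level class counts.
##
## When a classifier annotates a whole proteome, the raw per-class tallies
## are biased by systematic mispredictions.  Given a labelled evaluation
## set one can estimate P(true class | predicted class) from the confusion
## matrix and redistribute each predicted pool accordingly: the estimated
## false predictions are deduced from a class and the estimated members
## mispredicted into other classes are added back.

#' Misprediction fractions from a confusion matrix
#'
#' Row-normalises the predicted-vs-observed confusion matrix into
#' \code{P[k, c] = P(true = c | predicted = k)}.
#'
#' @param cm 5 x 5 confusion matrix (rows = predicted, columns = observed).
#' @return 5 x 5 row-stochastic matrix; rows with zero predictions are
#'   left as NA with a warning.
#' @export
misprediction_fractions <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  rs <- rowSums(cm)
  P <- cm / ifelse(rs > 0, rs, NA)
  if (any(rs == 0))
    warning("no predictions for class(es): ",
            paste(rownames(cm)[rs == 0], collapse = ", "))
  P
}

#' Correct predicted per-class counts
#'
#' \code{corrected[c] = sum_k n[k] * P[k, c]}: each predicted pool is
#' redistributed over the estimated true classes.  Totals are conserved
#' exactly, and when \code{P} is estimated on the same labelled set whose
#' predicted counts are corrected, the corrected counts equal the true
#' per-class counts exactly.
#'
#' @param n length-5 vector of predicted counts (order
#'   \code{\link{tp_classes}}).
#' @param P row-stochastic matrix from \code{\link{misprediction_fractions}}.
#' @return named numeric vector of corrected (real-valued) counts.
#' @export
correct_counts <- function(n, P) {
  stopifnot(length(n) == nrow(P), ncol(P) == nrow(P))
  if (any(n < 0)) stop("predicted counts must be non-negative")
  na_row <- apply(is.na(P), 1, any)
  if (any(na_row)) {
    # no estimated fractions for these pools: leave their counts in place
    if (any(n[na_row] > 0))
      warning("no misprediction estimate for predicted class(es) ",
              paste(rownames(P)[na_row & n > 0], collapse = ", "),
              "; their counts are left uncorrected")
    P[na_row, ] <- diag(nrow(P))[na_row, , drop = FALSE]
  }
  out <- as.numeric(n %*% P)
  names(out) <- colnames(P)
  out
}
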