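## MLP-XX baseline: a feed-forward classifier on one-hot encodings of the
## first XX residues.  Classification only — the baseline never predicts a
## cleavage site.

#' One-hot encode the N-terminal residues of a record
#'
#' Per-position one-hot vector over the 20 standard residues, positions
#' concatenated; chains shorter than \code{n_residues} are zero-padded and
#' X contributes an all-zero block.
#'
#' @param records record data.frame.
#' @param n_residues number of N-terminal residues (the XX, 1 to 20).
#' @return matrix nrow(records) x (20 * n_residues).
#' @export
mlp_encode <- function(records, n_residues = 20L) {
  stopifnot(n_residues >= 1, n_residues <= 20)
  n <- nrow(records)
  out <- matrix(0, n, 20L * n_residues)
  for (i in seq_len(n)) {
    chars <- strsplit(substr(records$sequence[i], 1L, n_residues), "")[[1]]
    idx <- match(chars, tp_residues)
    for (p in seq_along(chars))
      if (!is.na(idx[p])) out[i, (p - 1L) * 20L + idx[p]] <- 1
  }
  out
}

#' Fit the MLP baseline
#'
#' A feed-forward network with one hidden ReLU layer (or none, when
#' \code{hidden_units = 0}: plain softmax regression) over the one-hot
#' encoding, trained with Adam on the class cross-entropy with early
#' stopping on validation loss.
#'
#' @param records labelled training records.
#' @param val_records validation records (held out from \code{records}
#'   when NULL).
#' @param n_residues N-terminal residues used (default 20).
#' @param hidden_units hidden-layer width (default 64; 0 for none).
#' @param lr,batch_size,max_epochs,patience optimiser settings.
#' @param val_frac,seed split fraction and seed.
#' @return object of class \code{targpep_mlp}.
#' @export
targpep_mlp <- function(records, val_records = NULL, n_residues = 20L,
                        hidden_units = 64L, lr = 1e-3, batch_size = 64L,
                        max_epochs = 100L, patience = 10L, val_frac = 0.1,
                        seed = 1L) {
  validate_records(records)
  if (anyNA(records$label)) stop("training requires labels")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (is.null(val_records)) {
    vi <- sample(nrow(records), max(1L, round(val_frac * nrow(records))))
    val_records <- records[vi, , drop = FALSE]
    records <- records[-vi, , drop = FALSE]
  }
  X <- mlp_encode(records, n_residues)
  y <- .class_index(records$label)
  Xv <- mlp_encode(val_records, n_residues)
  yv <- .class_index(val_records$label)
  d <- ncol(X)
  params <- if (hidden_units > 0)
    list(W1 = .glorot(d, hidden_units), b1 = rep(0, hidden_units),
         W2 = .glorot(hidden_units, 5L), b2 = rep(0, 5))
  else list(W2 = .glorot(d, 5L), b2 = rep(0, 5))
  state <- .adam_init(params)
  fwd <- function(p, X) {
    H <- if (hidden_units > 0) .relu(sweep(X %*% p$W1, 2, p$b1, "+")) else X
    Y <- sweep(H %*% p$W2, 2, p$b2, "+")
    Y <- Y - apply(Y, 1, max)
    P <- exp(Y); P <- P / rowSums(P)
    list(H = H, P = P)
  }
  ce <- function(P, y) mean(-log(pmax(P[cbind(seq_along(y), y)], 1e-12)))
  n <- nrow(X)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  for (epoch in seq_len(max_epochs)) {
    ord <- sample(n)
    tot <- 0; nb <- 0L
    for (s in seq(1, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      f <- fwd(params, Xb)
      dY <- f$P
      dY[cbind(seq_along(yb), yb)] <- dY[cbind(seq_along(yb), yb)] - 1
      dY <- dY / length(yb)
      grads <- list()
      grads$W2 <- t(f$H) %*% dY
      grads$b2 <- colSums(dY)
      if (hidden_units > 0) {
        dH <- (dY %*% t(params$W2)) * (f$H > 0)
        grads$W1 <- t(Xb) %*% dH
        grads$b1 <- colSums(dH)
      }
      upd <- .adam_update(params, grads[names(params)], state, lr = lr)
      params <- upd$params; state <- upd$state
      tot <- tot + ce(f$P, yb); nb <- nb + 1L
    }
    vl <- ce(fwd(params, Xv)$P, yv)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tot / nb,
                                         val_loss = vl))
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = params, epoch = epoch)
      wait <- 0L
    } else if ((wait <- wait + 1L) >= patience) break
  }
  structure(list(params = best$params, n_residues = n_residues,
                 hidden_units = hidden_units, history = history,
                 best_epoch = best$epoch, val_loss = best$loss,
                 call = match.call()),
            class = "targpep_mlp")
}

#' @export
predict.targpep_mlp <- function(object, newdata, ...) {
  X <- mlp_encode(newdata, object$n_residues)
  p <- object$params
  H <- if (object$hidden_units > 0) .relu(sweep(X %*% p$W1, 2, p$b1, "+")) else X
  Y <- sweep(H %*% p$W2, 2, p$b2, "+")
  Y <- Y - apply(Y, 1, max)
  P <- exp(Y); P <- P / rowSums(P)
  colnames(P) <- tp_classes
  rownames(P) <- newdata$id
  pred_i <- max.col(P, ties.method = "first")
  structure(list(table = data.frame(id = newdata$id,
                                    pred_class = tp_classes[pred_i], P,
                                    pred_cs = NA_integer_,
                                    row.names = NULL, check.names = FALSE),
                 class_probs = P, cs_probs = list(), attention = list(),
                 ids = newdata$id),
            class = "targpep_prediction")
}

#' @export
print.targpep_mlp <- function(x, ...) {
  cat(sprintf("MLP-%d baseline (%s), best epoch %d, val loss %.4f\n",
              x$n_residues,
              if (x$hidden_units > 0) paste0(x$hidden_units, " hidden units")
              else "softmax regression", x$best_epoch, x$val_loss))
  invisible(x)
}
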