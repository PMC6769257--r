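## Model fitting (Adam + early stopping) and the targpep S3 class.

.adam_init <- function(params)
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)

.adam_update <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  ct1 <- 1 - beta1^state$t
  ct2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / ct1) / (sqrt(state$v[[nm]] / ct2) + eps)
  }
  list(params = params, state = state)
}

## Assemble the compiled-kernel arguments for a subset of records.
.batch_args <- function(records, max_len) {
  enc <- encode_batch(records, max_len)
  list(X = enc$features, lengths = as.integer(enc$lengths),
       group = enc$group_vec,
       class0 = as.integer(enc$class_targets - 1L),
       cs0 = as.integer(ifelse(enc$cs_targets > 0, enc$cs_targets - 1L, -1L)),
       mask = enc$mask)
}

## Evaluation loss (no dropout, no gradients) on a record set.
.eval_loss <- function(params, records, max_len, batch_size = 128L) {
  n <- nrow(records)
  lc_sum <- 0; lcs_sum <- 0; npos <- 0L
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    a <- .batch_args(records[idx, , drop = FALSE], max_len)
    fw <- cpp_forward(params, a$X, a$lengths, a$group)
    pi <- fw$class_probs[cbind(seq_along(idx), a$class0 + 1L)]
    lc_sum <- lc_sum + sum(-log(pmax(pi, 1e-12)))
    pos <- which(a$cs0 >= 0)
    for (i in pos) {
      head <- a$class0[i]              # classes 2..5 are heads 1..4
      p <- fw$attention[i, head, a$cs0[i] + 1L]
      lcs_sum <- lcs_sum + -log(max(p, 1e-12))
    }
    npos <- npos + length(pos)
  }
  lc <- lc_sum / n
  if (npos == 0) return(lc)
  (lc + lcs_sum / npos) / 2
}

#' Fit the targeting-peptide network
#'
#' Trains the BiLSTM multi-attention model on labelled records with Adam
#' and joint cross-entropy over peptide class and cleavage-site position
#' (the two losses are averaged; noTP records contribute no cleavage-site
#' error).  Early stopping monitors the joint loss on a validation set
#' and the returned parameters are those of the best validation epoch.
#'
#' @param records labelled \code{\link{tp_records}} data.frame.
#' @param config a \code{\link{tp_config}}.
#' @param val_records optional validation records; when NULL a fraction
#'   \code{val_frac} of \code{records} is held out (deterministic under
#'   \code{seed}).
#' @param val_frac validation fraction when \code{val_records} is NULL;
#'   0 disables validation and early stopping (the final epoch is kept,
#'   useful for deliberate-overfit checks).
#' @param lr,batch_size,max_epochs,patience Adam learning rate, minibatch
#'   size, epoch cap and early-stopping patience.
#' @param max_len N-terminal window (default 200).
#' @param seed integer seed for the split, shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return object of class \code{targpep} with elements \code{params},
#'   \code{config}, \code{history}, \code{best_epoch}, \code{max_len}.
#' @export
targpep <- function(records, config = tp_config(), val_records = NULL,
                    val_frac = 0.1, lr = 1e-3, batch_size = 64L,
                    max_epochs = 50L, patience = 5L, max_len = 200L,
                    seed = config$seed, verbose = FALSE) {
  validate_records(records)
  if (anyNA(records$label)) stop("training requires a label for every record")
  records <- truncate_n_terminal(records, max_len)
  if (any(!records$valid)) {
    warning(sum(!records$valid), " record(s) dropped: cleavage site beyond the ",
            max_len, "-residue window")
    records <- records[records$valid, , drop = FALSE]
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (is.null(val_records) && val_frac <= 0) {
    # no validation: run max_epochs to completion and keep the final state
    val_records <- NULL
  } else if (is.null(val_records)) {
    vi <- sample(nrow(records), max(1L, round(val_frac * nrow(records))))
    val_records <- records[vi, , drop = FALSE]
    records <- records[-vi, , drop = FALSE]
  } else {
    val_records <- truncate_n_terminal(val_records, max_len)
    val_records <- val_records[val_records$valid, , drop = FALSE]
    if (any(val_records$id %in% records$id))
      stop("training and validation sets overlap")
  }
  params <- tp_init_params(config)
  state <- .adam_init(params)
  n <- nrow(records)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    ord <- sample(n)
    tot <- 0; nb <- 0L
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      a <- .batch_args(records[idx, , drop = FALSE], max_len)
      dseed <- sample.int(.Machine$integer.max, 1L)
      step <- cpp_train_step(params, a$X, a$lengths, a$group, a$class0, a$cs0,
                             config$dropout, dseed)
      if (!is.finite(step$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; lower the learning rate")
      upd <- .adam_update(params, step$grads, state, lr = lr)
      params <- upd$params; state <- upd$state
      tot <- tot + step$loss; nb <- nb + 1L
    }
    vl <- if (is.null(val_records)) NA_real_
          else .eval_loss(params, val_records, max_len)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tot / nb,
                                         val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, tot / nb, vl))
    if (is.null(val_records)) {
      best <- list(loss = tot / nb, params = params, epoch = epoch)
    } else if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(list(params = best$params, config = config, history = history,
                 best_epoch = best$epoch, val_loss = best$loss,
                 max_len = max_len, n_train = n, call = match.call()),
            class = "targpep")
}

#' Predict peptide classes and cleavage sites
#'
#' @param object fitted \code{\link{targpep}} model.
#' @param newdata record data.frame or path to a FASTA file.
#' @param group organism group used when \code{newdata} is a FASTA path.
#' @param batch_size records per forward batch.
#' @param ... unused.
#' @return object of class \code{targpep_prediction}: a list with
#'   \code{table} (one row per record: id, predicted class, the five class
#'   probabilities, predicted cleavage site — NA for noTP — and its
#'   probability), \code{class_probs}, \code{cs_probs} (per record, 4 x
#'   len matrix, head order SP/mTP/cTP/luTP) and \code{attention} (per
#'   record, n_attn x len).  Argmax ties break toward the lower index.
#' @export
predict.targpep <- function(object, newdata, group = "nonplant",
                            batch_size = 128L, ...) {
  records <- if (is.character(newdata)) read_fasta(newdata, group = group)
             else newdata
  records <- truncate_n_terminal(records, object$max_len)
  n <- nrow(records)
  class_probs <- matrix(0, n, 5, dimnames = list(records$id, tp_classes))
  attention <- vector("list", n)
  cs_probs <- vector("list", n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    a <- .batch_args(records[idx, , drop = FALSE], object$max_len)
    fw <- cpp_forward(object$params, a$X, a$lengths, a$group)
    class_probs[idx, ] <- fw$class_probs
    for (j in seq_along(idx)) {
      len <- a$lengths[j]
      A <- matrix(fw$attention[j, , seq_len(len)], object$config$n_attn, len)
      attention[[idx[j]]] <- A
      cs_probs[[idx[j]]] <- A[1:4, , drop = FALSE]
    }
  }
  pred_i <- max.col(class_probs, ties.method = "first")
  pred_class <- tp_classes[pred_i]
  pred_cs <- rep(NA_integer_, n)
  cs_prob <- rep(NA_real_, n)
  for (i in which(pred_i > 1)) {
    v <- cs_probs[[i]][pred_i[i] - 1L, ]
    pred_cs[i] <- which.max(v)
    cs_prob[i] <- v[pred_cs[i]]
  }
  tab <- data.frame(id = records$id, pred_class = pred_class,
                    class_probs, pred_cs = pred_cs, cs_prob = cs_prob,
                    row.names = NULL, check.names = FALSE)
  structure(list(table = tab, class_probs = class_probs, cs_probs = cs_probs,
                 attention = attention, ids = records$id),
            class = "targpep_prediction")
}

#' @export
print.targpep <- function(x, ...) {
  cfg <- x$config
  cat("Targeting-peptide BiLSTM/multi-attention model\n")
  cat(sprintf("  feature %d | lstm %d/dir | attention %d x %d heads | summary %d\n",
              cfg$feat_units, cfg$lstm_units, cfg$attn_units, cfg$n_attn,
              cfg$summary_units))
  cat(sprintf("  trained on %d records, best epoch %d (val loss %.4f)\n",
              x$n_train, x$best_epoch, x$val_loss))
  invisible(x)
}

#' @method summary targpep
#' @export
summary.targpep <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @method coef targpep
#' @export
coef.targpep <- function(object, ...) object$params

#' @method plot targpep
#' @export
plot.targpep <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "joint loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
print.targpep_prediction <- function(x, ...) {
  print(utils::head(x$table, 10), row.names = FALSE)
  if (nrow(x$table) > 10) cat("... (", nrow(x$table), " records)\n", sep = "")
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' Single-file checkpoint with the configuration embedded and a versioned
#' format string.
#'
#' @param object fitted model.
#' @param path checkpoint file.
#' @return \code{tp_load_model}: the model.
#' @export
tp_save_model <- function(object, path) {
  stopifnot(inherits(object, "targpep") || inherits(object, "targpep_mlp"))
  saveRDS(list(format = "targpep-checkpoint-1", model = object), path)
  invisible(path)
}

#' @rdname tp_save_model
#' @export
tp_load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "targpep-checkpoint-1"))
    stop("not a recognised checkpoint: ", path)
  x$model
}
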