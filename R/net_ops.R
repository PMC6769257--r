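## Layer-level reference implementation of the network.
##
## Architecture: BLOSUM62 input -> position-wise feature transform (ReLU)
## -> BiLSTM whose initial hidden and cell states in both directions are
## learned linear maps of the plant/nonplant flag -> multi-attention over
## the concatenated hidden states (shared tanh projection, one score
## vector per head) -> the first four attention heads are read out
## directly as the SP/mTP/cTP/luTP cleavage-site distributions -> the
## attention-weighted context matrix is flattened and summarised by a
## dense ReLU layer -> 5-way softmax over peptide classes.
##
## These functions are written for clarity, not speed: they are the
## ground truth against which the compiled training kernel is verified.
## Prediction and training go through the compiled path.

#' Model configuration
#'
#' Defaults follow the full-size architecture: a 32-unit feature
#' transform, 256 LSTM units per direction (512-dimensional concatenated
#' output), attention size 144 with 13 heads of which the first four are
#' the cleavage-site predictors, and a 256-unit summariser before the
#' 5-way softmax.
#'
#' @param feat_units feature-transform width.
#' @param lstm_units LSTM units per direction.
#' @param attn_units attention projection width.
#' @param n_attn number of attention heads (>= 4; heads 1-4 are the
#'   SP, mTP, cTP, luTP cleavage-site heads).
#' @param summary_units width of the dense summariser.
#' @param dropout dropout rate applied after the feature transform, the
#'   BiLSTM and the summariser during training.
#' @param seed integer seed for parameter initialisation.
#' @return list of class \code{tp_config}.
#' @export
tp_config <- function(feat_units = 32L, lstm_units = 256L, attn_units = 144L,
                      n_attn = 13L, summary_units = 256L, dropout = 0.25,
                      seed = 1L) {
  stopifnot(n_attn >= 4, feat_units >= 1, lstm_units >= 1, attn_units >= 1,
            summary_units >= 1, dropout >= 0, dropout < 1)
  structure(list(feat_units = as.integer(feat_units),
                 lstm_units = as.integer(lstm_units),
                 attn_units = as.integer(attn_units),
                 n_attn = as.integer(n_attn),
                 summary_units = as.integer(summary_units),
                 n_classes = 5L, dropout = dropout, seed = as.integer(seed)),
            class = "tp_config")
}

#' Reduced configuration for desk-scale experiments
#'
#' @param ... overrides passed to \code{\link{tp_config}}.
#' @export
tp_config_reduced <- function(...) {
  args <- list(feat_units = 16L, lstm_units = 64L, attn_units = 32L,
               n_attn = 8L, summary_units = 64L, dropout = 0.1)
  over <- list(...)
  args[names(over)] <- over
  do.call(tp_config, args)
}

## Glorot-uniform matrix.
.glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

#' Initialise network parameters
#'
#' Glorot-uniform weights, zero biases except a +1 LSTM forget-gate bias.
#' Gate order within the 4D-wide LSTM weight blocks is input, forget,
#' cell candidate, output.
#'
#' @param cfg a \code{\link{tp_config}}.
#' @return named list of weight matrices and bias vectors.
#' @export
tp_init_params <- function(cfg) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  F <- cfg$feat_units; D <- cfg$lstm_units; A <- cfg$attn_units
  K <- cfg$n_attn; S <- cfg$summary_units
  lstm_dir <- function() {
    b <- rep(0, 4 * D); b[(D + 1):(2 * D)] <- 1  # forget-gate bias
    list(Wx = .glorot(F, 4 * D), Wh = .glorot(D, 4 * D), b = b,
         wh0 = stats::rnorm(D, 0, 0.1), bh0 = rep(0, D),
         wc0 = stats::rnorm(D, 0, 0.1), bc0 = rep(0, D))
  }
  fwd <- lstm_dir(); bwd <- lstm_dir()
  p <- list(W1 = .glorot(20, F), b1 = rep(0, F),
            Wx_f = fwd$Wx, Wh_f = fwd$Wh, b_f = fwd$b,
            wh0_f = fwd$wh0, bh0_f = fwd$bh0, wc0_f = fwd$wc0, bc0_f = fwd$bc0,
            Wx_b = bwd$Wx, Wh_b = bwd$Wh, b_b = bwd$b,
            wh0_b = bwd$wh0, bh0_b = bwd$bh0, wc0_b = bwd$wc0, bc0_b = bwd$bc0,
            Wa = .glorot(2 * D, A), ba = rep(0, A), Va = .glorot(A, K),
            W2 = .glorot(K * 2 * D, S), b2 = rep(0, S),
            W3 = .glorot(S, 5L), b3 = rep(0, 5))
  p
}

.relu <- function(x) pmax(x, 0)
.sigmoid <- function(x) 1 / (1 + exp(-x))
.softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

#' Position-wise feature transform (reference)
#'
#' \code{c_t = relu(W x_t + b)} applied identically at every position.
#'
#' @param features batch x L x 20 array.
#' @param params,cfg network parameters and configuration.
#' @return batch x L x feat_units array.
#' @export
feature_transform <- function(features, params, cfg) {
  d <- dim(features)
  out <- array(0, c(d[1], d[2], cfg$feat_units))
  for (i in seq_len(d[1]))
    out[i, , ] <- .relu(features[i, , , drop = TRUE] %*% params$W1 +
                          rep(params$b1, each = d[2]))
  out
}

## One LSTM direction over a single sequence matrix (len x F).
.lstm_run <- function(cmat, Wx, Wh, b, h0, c0) {
  D <- length(h0)
  len <- nrow(cmat)
  H <- matrix(0, len, D)
  h <- h0; cc <- c0
  for (t in seq_len(len)) {
    z <- as.numeric(cmat[t, ] %*% Wx + h %*% Wh) + b
    i <- .sigmoid(z[1:D]); f <- .sigmoid(z[(D + 1):(2 * D)])
    g <- tanh(z[(2 * D + 1):(3 * D)]); o <- .sigmoid(z[(3 * D + 1):(4 * D)])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    H[t, ] <- h
  }
  H
}

#' BiLSTM encoding (reference)
#'
#' Both directions start from learned projections of the group flag; the
#' backward pass runs only over real residues.  Masked positions are zero.
#'
#' @param c batch x L x feat_units array from
#'   \code{\link{feature_transform}}.
#' @param group_vec numeric vector (1 = plant).
#' @param lengths integer vector of true sequence lengths.
#' @param params,cfg network parameters and configuration.
#' @return batch x L x (2 * lstm_units) array \code{[h_fwd ; h_bwd]}.
#' @export
bilstm_encode <- function(c, group_vec, lengths, params, cfg) {
  d <- dim(c); D <- cfg$lstm_units
  out <- array(0, c(d[1], d[2], 2 * D))
  for (i in seq_len(d[1])) {
    len <- lengths[i]
    g <- group_vec[i]
    cm <- matrix(c[i, seq_len(len), ], len, d[3])
    Hf <- .lstm_run(cm, params$Wx_f, params$Wh_f, params$b_f,
                    g * params$wh0_f + params$bh0_f,
                    g * params$wc0_f + params$bc0_f)
    Hb <- .lstm_run(cm[rev(seq_len(len)), , drop = FALSE],
                    params$Wx_b, params$Wh_b, params$b_b,
                    g * params$wh0_b + params$bh0_b,
                    g * params$wc0_b + params$bc0_b)
    out[i, seq_len(len), ] <- cbind(Hf, Hb[rev(seq_len(len)), , drop = FALSE])
  }
  out
}

#' Multi-attention (reference)
#'
#' Per head k the position score is \code{tanh(Wa h_t + ba) . v_k};
#' masked positions get -Inf before the softmax so each attention row is
#' a distribution over real residues.
#'
#' @param H batch x L x 2D array.
#' @param mask batch x L logical.
#' @param params,cfg network parameters and configuration.
#' @return batch x n_attn x L array of attention distributions.
#' @export
multi_attention <- function(H, mask, params, cfg) {
  d <- dim(H); K <- cfg$n_attn
  A <- array(0, c(d[1], K, d[2]))
  for (i in seq_len(d[1])) {
    if (!any(mask[i, ])) stop("all positions masked for record ", i)
    Tm <- tanh(matrix(H[i, , ], d[2], d[3]) %*% params$Wa +
                 rep(params$ba, each = d[2]))
    sc <- Tm %*% params$Va               # L x K
    sc[!mask[i, ], ] <- -Inf
    for (k in seq_len(K)) A[i, k, ] <- .softmax(sc[, k])
  }
  A
}

#' Cleavage-site distributions (reference)
#'
#' The cleavage-site read-out is the identity on attention heads 1-4
#' (order SP, mTP, cTP, luTP), so cleavage-site training shapes the
#' attention itself.
#'
#' @param A batch x n_attn x L attention array.
#' @return batch x 4 x L array.
#' @export
predict_cs <- function(A) A[, 1:4, , drop = FALSE]

#' Attention-weighted context encoding (reference)
#'
#' \code{e_k = sum_t A[k, t] h_t} per head.
#'
#' @param A batch x n_attn x L array.
#' @param H batch x L x 2D array.
#' @return batch x n_attn x 2D array.
#' @export
encode_context <- function(A, H) {
  d <- dim(H); K <- dim(A)[2]
  E <- array(0, c(d[1], K, d[3]))
  for (i in seq_len(d[1]))
    E[i, , ] <- matrix(A[i, , ], K, d[2]) %*% matrix(H[i, , ], d[2], d[3])
  E
}

#' Peptide-type probabilities (reference)
#'
#' Flattens the context matrix (head-major), summarises it with a dense
#' ReLU layer and applies the 5-way softmax.
#'
#' @param E batch x n_attn x 2D context array.
#' @param params,cfg network parameters and configuration.
#' @return batch x 5 matrix of class probabilities.
#' @export
predict_type <- function(E, params, cfg) {
  d <- dim(E)
  P <- matrix(0, d[1], 5)
  for (i in seq_len(d[1])) {
    e <- as.numeric(t(matrix(E[i, , ], d[2], d[3])))  # head-major flatten
    u <- .relu(as.numeric(e %*% params$W2) + params$b2)
    P[i, ] <- .softmax(as.numeric(u %*% params$W3) + params$b3)
  }
  colnames(P) <- tp_classes
  P
}

#' Full forward pass (reference implementation)
#'
#' Composes the layer functions above without dropout.  Used for testing;
#' \code{\link{predict.targpep}} uses the compiled equivalent.
#'
#' @param batch encoded batch from \code{\link{encode_batch}}.
#' @param params,cfg network parameters and configuration.
#' @return list with \code{class_probs} (batch x 5), \code{attention}
#'   (batch x n_attn x L), \code{cs_probs} (batch x 4 x L).
#' @export
tp_forward_ref <- function(batch, params, cfg) {
  C <- feature_transform(batch$features, params, cfg)
  H <- bilstm_encode(C, batch$group_vec, batch$lengths, params, cfg)
  A <- multi_attention(H, batch$mask, params, cfg)
  E <- encode_context(A, H)
  list(class_probs = predict_type(E, params, cfg),
       attention = A, cs_probs = predict_cs(A))
}

#' Joint classification / cleavage-site loss (reference)
#'
#' Mean class cross-entropy over the batch, averaged with the mean
#' cleavage-site cross-entropy over records that carry a cleavage site
#' (the head matching the true class scores the annotated position).  A
#' batch with no positive record yields the class term alone: for noTPs
#' there is no cleavage-site error to propagate.
#'
#' @param fwd output of \code{\link{tp_forward_ref}}.
#' @param class_targets integer vector (1-based index into
#'   \code{\link{tp_classes}}).
#' @param cs_targets integer vector of 1-based cleavage sites, -1 for noTP.
#' @param lengths sequence lengths (to validate the targets).
#' @return scalar loss.
#' @export
tp_loss_ref <- function(fwd, class_targets, cs_targets, lengths) {
  n <- length(class_targets)
  eps <- 1e-12
  lc <- -mean(log(pmax(fwd$class_probs[cbind(seq_len(n), class_targets)], eps)))
  pos <- which(cs_targets > 0)
  if (!length(pos)) return(lc)
  if (any(cs_targets[pos] > lengths[pos])) stop("cleavage site beyond sequence end")
  lcs <- mean(vapply(pos, function(i) {
    head <- class_targets[i] - 1L   # SP..luTP are classes 2..5 -> heads 1..4
    -log(max(fwd$cs_probs[i, head, cs_targets[i]], eps))
  }, 0))
  (lc + lcs) / 2
}
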