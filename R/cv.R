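## Homology-aware partitioning and nested five-fold cross-validation.

## Positions of all k-mers of a string, as a named list kmer -> start set.
.kmer_starts <- function(chars, k = 3L) {
  n <- length(chars)
  if (n < k) return(list())
  km <- vapply(seq_len(n - k + 1L),
               function(s) paste(chars[s:(s + k - 1L)], collapse = ""), "")
  split(seq_along(km), km)
}

## Ungapped identity between two char vectors along the diagonals seeded
## by shared k-mers; returns the best (identity, overlap) pair satisfying
## the coverage constraint, or NULL.
.diagonal_identity <- function(a, b, ka, kb, coverage) {
  shared <- intersect(names(ka), names(kb))
  if (!length(shared)) return(NULL)
  diags <- unique(unlist(lapply(shared, function(m)
    as.vector(outer(ka[[m]], kb[[m]], "-")))))
  la <- length(a); lb <- length(b)
  need <- coverage * min(la, lb)
  best <- NULL
  for (d in diags) {
    ## positions i in a aligned to i - d in b, ungapped
    from <- max(1L, 1L + d); to <- min(la, lb + d)
    ov <- to - from + 1L
    if (ov < need) next
    ident <- sum(a[from:to] == b[(from:to) - d]) / ov
    if (is.null(best) || ident > best$identity)
      best <- list(identity = ident, overlap = ov, diag = d)
  }
  best
}

#' Greedy single-linkage homology clustering
#'
#' A lightweight stand-in for profile-based clustering: records are taken
#' in order of decreasing length and join the first existing cluster whose
#' representative they match with an ungapped, 3-mer-seeded alignment of
#' identity at least \code{identity_threshold} over at least
#' \code{coverage} of the shorter sequence (first \code{window} residues
#' only); otherwise they found a new cluster.  A precomputed cluster file
#' (two-column TSV id, cluster) can be supplied instead wherever a plan is
#' built.
#'
#' @param records record data.frame.
#' @param identity_threshold minimum fractional identity (default 0.2).
#' @param coverage minimum aligned fraction of the shorter sequence
#'   (default 0.8).
#' @param window residues considered from the N terminus (default 200).
#' @return named integer vector: record id -> cluster id.
#' @export
cluster_greedy <- function(records, identity_threshold = 0.2, coverage = 0.8,
                           window = 200L) {
  stopifnot(nrow(records) > 0)
  seqs <- substr(records$sequence, 1L, window)
  chars <- strsplit(seqs, "")
  kmers <- lapply(chars, .kmer_starts)
  ord <- order(-nchar(seqs))
  cluster <- integer(nrow(records))
  names(cluster) <- records$id
  reps <- integer(0)             # record index of each cluster representative
  for (i in ord) {
    assigned <- FALSE
    for (cl in seq_along(reps)) {
      r <- reps[cl]
      hit <- .diagonal_identity(chars[[i]], chars[[r]], kmers[[i]], kmers[[r]],
                                coverage)
      if (!is.null(hit) && hit$identity >= identity_threshold) {
        cluster[i] <- cl
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  cluster
}

#' Build a nested cross-validation plan
#'
#' Whole clusters are dealt to the five outer folds (largest first, to the
#' fold currently smallest for the cluster's majority class), so homologous
#' records never straddle folds.  Each outer test fold pairs with four
#' inner rotations (train 3 folds / validate 1), yielding 5 x 4 = 20
#' train/validation/test triples.
#'
#' @param records labelled record data.frame.
#' @param clusters named vector id -> cluster from
#'   \code{\link{cluster_greedy}} (or a precomputed equivalent).
#' @param n_outer number of outer folds (default 5).
#' @param seed shuffle seed.
#' @return list of class \code{tp_cv_plan}: \code{assignment} (named fold
#'   index 1..n_outer per record id), \code{triples} (list of 20 lists
#'   with \code{test_fold}, \code{val_fold}, \code{train_folds}).
#' @export
make_cv_plan <- function(records, clusters, n_outer = 5L, seed = 1L) {
  stopifnot(all(records$id %in% names(clusters)))
  cl <- clusters[records$id]
  ucl <- unique(cl)
  if (length(ucl) < n_outer)
    stop("fewer clusters (", length(ucl), ") than folds (", n_outer, ")")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  ucl <- sample(ucl)
  sizes <- vapply(ucl, function(u) sum(cl == u), 0L)
  ucl <- ucl[order(-sizes)]
  maj <- vapply(ucl, function(u) {
    labs <- records$label[cl == u]
    names(which.max(table(labs)))
  }, "")
  per_class <- matrix(0L, n_outer, length(tp_classes),
                      dimnames = list(NULL, tp_classes))
  totals <- integer(n_outer)
  assignment <- integer(nrow(records))
  names(assignment) <- records$id
  for (j in seq_along(ucl)) {
    cand <- which(per_class[, maj[j]] == min(per_class[, maj[j]]))
    fold <- cand[which.min(totals[cand])]
    members <- which(cl == ucl[j])
    assignment[members] <- fold
    per_class[fold, maj[j]] <- per_class[fold, maj[j]] + length(members)
    totals[fold] <- totals[fold] + length(members)
  }
  triples <- list()
  for (test in seq_len(n_outer)) {
    inner <- setdiff(seq_len(n_outer), test)
    for (val in inner)
      triples[[length(triples) + 1L]] <-
        list(test_fold = test, val_fold = val,
             train_folds = setdiff(inner, val))
  }
  structure(list(assignment = assignment, n_outer = n_outer, triples = triples),
            class = "tp_cv_plan")
}

#' Read / write cluster tables
#'
#' Two-column TSV (id, cluster) interchangeable with
#' \code{\link{cluster_greedy}} output.
#'
#' @param clusters named vector id -> cluster.
#' @param path TSV file.
#' @export
write_clusters <- function(clusters, path) {
  utils::write.table(data.frame(id = names(clusters), cluster = clusters),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer"))
  stats::setNames(tab$cluster, tab$id)
}

#' Run nested cross-validation
#'
#' Trains one model per (outer test fold, inner validation fold) pair —
#' 20 models for five outer folds.  The out-of-fold prediction for each
#' test record is the average of its four inner models' class and
#' cleavage-site probability vectors (a convex combination, so all
#' distributions stay normalised); every record is predicted exactly once.
#'
#' @param records labelled record data.frame.
#' @param plan a \code{\link{make_cv_plan}} plan.
#' @param config model configuration.
#' @param trainer fitting function: \code{function(train, val)} returning
#'   an object with a \code{predict} method; defaults to
#'   \code{\link{targpep}} with the supplied config and \code{...}.
#' @param ... passed to \code{\link{targpep}} (lr, max_epochs, ...).
#' @return list of class \code{tp_cv_result}: \code{models} (length 20),
#'   \code{prediction} (a \code{targpep_prediction}-like list covering all
#'   records, in \code{records} order), \code{plan}.
#' @export
run_nested_cv <- function(records, plan, config = tp_config_reduced(),
                          trainer = NULL, ...) {
  stopifnot(inherits(plan, "tp_cv_plan"))
  fold <- plan$assignment[records$id]
  if (is.null(trainer))
    trainer <- function(train, val)
      targpep(train, config = config, val_records = val, ...)
  models <- vector("list", length(plan$triples))
  n <- nrow(records)
  class_probs <- matrix(0, n, 5, dimnames = list(records$id, tp_classes))
  cs_probs <- vector("list", n)
  attention <- vector("list", n)
  n_pred <- integer(n)
  for (j in seq_along(plan$triples)) {
    tr <- plan$triples[[j]]
    train <- records[fold %in% tr$train_folds, , drop = FALSE]
    val <- records[fold == tr$val_fold, , drop = FALSE]
    test_idx <- which(fold == tr$test_fold)
    fit <- trainer(train, val)
    models[[j]] <- fit
    pred <- predict(fit, records[test_idx, , drop = FALSE])
    class_probs[test_idx, ] <- class_probs[test_idx, ] + pred$class_probs / 4
    has_cs <- length(pred$cs_probs) > 0
    for (m in seq_along(test_idx)) {
      i <- test_idx[m]
      if (!has_cs) {
        n_pred[i] <- n_pred[i] + 1L
        next
      }
      if (is.null(cs_probs[[i]])) {
        cs_probs[[i]] <- pred$cs_probs[[m]] / 4
        attention[[i]] <- pred$attention[[m]] / 4
      } else {
        cs_probs[[i]] <- cs_probs[[i]] + pred$cs_probs[[m]] / 4
        attention[[i]] <- attention[[i]] + pred$attention[[m]] / 4
      }
      n_pred[i] <- n_pred[i] + 1L
    }
  }
  stopifnot(all(n_pred == 4L))
  pred_i <- max.col(class_probs, ties.method = "first")
  pred_cs <- rep(NA_integer_, n)
  cs_prob <- rep(NA_real_, n)
  for (i in which(pred_i > 1)) {
    if (is.null(cs_probs[[i]])) next
    v <- cs_probs[[i]][pred_i[i] - 1L, ]
    pred_cs[i] <- which.max(v)
    cs_prob[i] <- v[pred_cs[i]]
  }
  prediction <- structure(
    list(table = data.frame(id = records$id, pred_class = tp_classes[pred_i],
                            class_probs, pred_cs = pred_cs, cs_prob = cs_prob,
                            row.names = NULL, check.names = FALSE),
         class_probs = class_probs, cs_probs = cs_probs,
         attention = attention, ids = records$id),
    class = "targpep_prediction")
  structure(list(models = models, prediction = prediction, plan = plan),
            class = "tp_cv_result")
}
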