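# Clustering, CV-plan construction and the optimisation loop, exercised at
# miniature scale.

test_that("identical sequences cluster together, seedless pairs apart", {
  recs <- tp_records(c("a", "b", "c"),
                     c("MAGKLLVRSTPQWENMAGKLLVRSTPQWEN",
                       "MAGKLLVRSTPQWENMAGKLLVRSTPQWEN",
                       "MCHIDFYVWCHIDFYVWCHIDFYVWCHIDW"))
  cl <- cluster_greedy(recs)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_false(cl[["c"]] == cl[["a"]])
})

test_that("a planted mutated family clusters as one, verified by exhaustive identity", {
  anc <- synth_generate(synth_spec(n = c(noTP = 1), mature_len = c(150L, 150L),
                                   seed = 47L))
  fam <- synth_family(anc, n_copies = 5, rate = 0.1, seed = 53L)
  cl <- cluster_greedy(fam)
  expect_equal(length(unique(cl)), 1L)
  # oracle: every pair really is above the identity threshold, ungapped
  chars <- strsplit(fam$sequence, "")
  for (i in 1:5) for (j in (i + 1):6) {
    n <- min(length(chars[[i]]), length(chars[[j]]))
    ident <- mean(chars[[i]][1:n] == chars[[j]][1:n])
    expect_gt(ident, 0.2)
  }
})

test_that("unrelated random records mostly found their own clusters", {
  recs <- synth_generate(synth_spec(n = c(noTP = 30), seed = 59L))
  cl <- cluster_greedy(recs)
  expect_gt(length(unique(cl)), 25)
})

test_that("CV plan keeps clusters whole and yields 20 triples", {
  recs <- synth_generate(synth_spec(n = c(noTP = 40, SP = 20, mTP = 15,
                                          cTP = 10, luTP = 8), seed = 61L))
  fam <- synth_family(recs[1, , drop = FALSE], n_copies = 4, rate = 0.05,
                      seed = 2L)
  recs <- rbind(recs, fam[-1, ])
  clusters <- cluster_greedy(recs)
  plan <- make_cv_plan(recs, clusters, seed = 3L)
  expect_equal(length(plan$triples), 20L)
  expect_true(all(sort(unique(plan$assignment)) == 1:5))
  # cluster co-membership implies fold co-membership
  for (u in unique(clusters))
    expect_equal(length(unique(plan$assignment[names(clusters)[clusters == u]])), 1L)
  # each triple partitions the folds
  for (tr in plan$triples) {
    expect_equal(sort(c(tr$test_fold, tr$val_fold, tr$train_folds)), 1:5)
  }
  # five singleton clusters deal one per fold
  tiny <- synth_generate(synth_spec(n = c(noTP = 5), seed = 67L))
  cl5 <- stats::setNames(1:5, tiny$id)
  p5 <- make_cv_plan(tiny, cl5, seed = 1L)
  expect_equal(sort(unname(p5$assignment)), 1:5)
  expect_error(make_cv_plan(tiny[1:3, ], cl5[1:3], seed = 1L), "fewer clusters")
})

test_that("fold sizes differ by at most the largest cluster size", {
  set.seed(71)
  for (rep in 1:100) {
    n <- sample(30:60, 1)
    ids <- sprintf("r%03d", seq_len(n))
    labels <- sample(tp_classes, n, replace = TRUE)
    recs <- data.frame(id = ids, sequence = "MA", group = "nonplant",
                       label = labels,
                       cs = ifelse(labels == "noTP", NA_integer_, 1L),
                       stringsAsFactors = FALSE)
    clusters <- stats::setNames(sample(ceiling(n / 2), n, replace = TRUE), ids)
    if (length(unique(clusters)) < 5) next
    plan <- make_cv_plan(recs, clusters, seed = rep)
    sizes <- table(factor(plan$assignment, levels = 1:5))
    expect_lte(max(sizes) - min(sizes), max(table(clusters)))
  }
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  recs <- synth_generate(synth_spec(n = c(noTP = 30, SP = 20, mTP = 15,
                                          cTP = 10, luTP = 5), seed = 73L))
  cfg <- tp_config(feat_units = 8L, lstm_units = 12L, attn_units = 8L,
                   n_attn = 5L, summary_units = 16L, dropout = 0.1, seed = 5L)
  f1 <- targpep(recs, config = cfg, max_epochs = 4L, batch_size = 32L)
  expect_lt(f1$history$train_loss[4], f1$history$train_loss[1])
  f2 <- targpep(recs, config = cfg, max_epochs = 4L, batch_size = 32L)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("early stopping returns the best-validation checkpoint, not the last", {
  recs <- synth_generate(synth_spec(n = c(noTP = 30, SP = 20), seed = 79L))
  cfg <- tp_config(feat_units = 6L, lstm_units = 8L, attn_units = 6L,
                   n_attn = 4L, summary_units = 8L, dropout = 0.3, seed = 7L)
  fit <- targpep(recs, config = cfg, max_epochs = 8L, patience = 2L,
                 batch_size = 16L, lr = 5e-3)
  expect_equal(fit$val_loss, min(fit$history$val_loss))
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
})

test_that("a reduced model overfits a small separable set", {
  recs <- synth_generate(synth_spec(n = c(noTP = 60, SP = 50, mTP = 40,
                                          cTP = 30, luTP = 20), seed = 83L))
  cfg <- tp_config(feat_units = 8L, lstm_units = 16L, attn_units = 8L,
                   n_attn = 5L, summary_units = 16L, dropout = 0, seed = 11L)
  fit <- targpep(recs, config = cfg, val_frac = 0, lr = 2e-3,
                 max_epochs = 50L, batch_size = 50L)
  # ~200 parameter updates (4 batches x 50 epochs) on the training set itself,
  # validation disabled so the final state is kept
  expect_true(all(is.na(fit$history$val_loss)))
  pred <- predict(fit, recs)
  acc <- mean(pred$table$pred_class == recs$label)
  expect_gte(acc, 0.95)
})

test_that("nested CV trains 20 models and predicts each record exactly once", {
  recs <- synth_generate(synth_spec(n = c(noTP = 30, SP = 20, mTP = 15,
                                          cTP = 12, luTP = 8), seed = 89L))
  clusters <- stats::setNames(seq_len(nrow(recs)), recs$id)
  plan <- make_cv_plan(recs, clusters, seed = 13L)
  cfg <- tp_config(feat_units = 4L, lstm_units = 6L, attn_units = 4L,
                   n_attn = 4L, summary_units = 8L, dropout = 0, seed = 17L)
  cv <- run_nested_cv(recs, plan, config = cfg, max_epochs = 1L,
                      batch_size = 32L)
  expect_equal(length(cv$models), 20L)
  expect_equal(cv$prediction$ids, recs$id)
  expect_equal(unname(rowSums(cv$prediction$class_probs)), rep(1, nrow(recs)),
               tolerance = 1e-6)
  # no record appears in both train and test of any triple
  fold <- plan$assignment[recs$id]
  for (tr in plan$triples)
    expect_length(intersect(recs$id[fold %in% tr$train_folds],
                            recs$id[fold == tr$test_fold]), 0)
  # averaged CS distributions stay normalised
  pos <- which(cv$prediction$table$pred_class != "noTP")
  for (i in pos[seq_len(min(3, length(pos)))])
    expect_equal(rowSums(cv$prediction$cs_probs[[i]]), rep(1, 4),
                 tolerance = 1e-6)
})

test_that("checkpoints round-trip through save and load", {
  recs <- synth_generate(synth_spec(n = c(noTP = 15, SP = 10), seed = 97L))
  cfg <- tp_config(feat_units = 4L, lstm_units = 4L, attn_units = 4L,
                   n_attn = 4L, summary_units = 4L, dropout = 0, seed = 19L)
  fit <- targpep(recs, config = cfg, max_epochs = 1L)
  path <- tempfile(fileext = ".rds")
  tp_save_model(fit, path)
  back <- tp_load_model(path)
  expect_identical(back$params, fit$params)
  p1 <- predict(fit, recs)
  p2 <- predict(back, recs)
  expect_identical(p1$table, p2$table)
  saveRDS(list(format = "other"), path)
  expect_error(tp_load_model(path), "not a recognised checkpoint")
})
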