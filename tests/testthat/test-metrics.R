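# Brute-force oracles coded independently of the package implementation.
oracle_binary <- function(pred, obs, cls) {
  c(tp = sum(pred == cls & obs == cls), tn = sum(pred != cls & obs != cls),
    fp = sum(pred == cls & obs != cls), fn = sum(pred != cls & obs == cls))
}
oracle_metrics <- function(tp, tn, fp, fn) {
  p <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  r <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fp) * sqrt(tn + fn)
  m <- ifelse(den == 0, 0, (tp * tn - fp * fn) / den)
  c(p, r, f, m)
}
oracle_auc <- function(scores, pos) {   # Mann-Whitney formulation
  s1 <- scores[pos]; s0 <- scores[!pos]
  cmp <- outer(s1, s0, ">") + 0.5 * outer(s1, s0, "==")
  mean(cmp)
}

test_that("confusion matrix counts predicted rows vs observed columns", {
  pred <- c("SP", "mTP", "noTP", "SP")
  obs <- c("SP", "SP", "noTP", "SP")
  cm <- confusion_matrix(pred, obs)
  expect_equal(sum(cm), 4L)
  expect_equal(cm["mTP", "SP"], 1L)
  expect_equal(cm["SP", "SP"], 2L)
  expect_equal(unname(rowSums(cm)[c("SP", "mTP", "noTP")]), c(2L, 1L, 1L))
  expect_error(confusion_matrix(c("SP", "bogus"), c("SP", "SP")), "unknown")
  all_right <- confusion_matrix(tp_classes, tp_classes)
  expect_equal(unname(diag(all_right)), rep(1L, 5))
  expect_equal(sum(all_right) - sum(diag(all_right)), 0L)
})

test_that("binary_counts is the one-vs-rest reduction", {
  cm <- confusion_matrix(tp_classes, tp_classes)
  for (cls in tp_classes)
    expect_equal(binary_counts(cm, cls), c(tp = 1L, tn = 4L, fp = 0L, fn = 0L))
  cm2 <- confusion_matrix(c("mTP"), c("SP"))
  expect_equal(binary_counts(cm2, "SP")[["fn"]], 1L)
  expect_equal(binary_counts(cm2, "SP")[["tp"]], 0L)
  # partition: tp+tn+fp+fn = total for every class
  set.seed(1)
  pred <- sample(tp_classes, 100, replace = TRUE)
  obs <- sample(tp_classes, 100, replace = TRUE)
  cm3 <- confusion_matrix(pred, obs)
  for (cls in tp_classes) expect_equal(sum(binary_counts(cm3, cls)), 100L)
})

test_that("precision/recall/F1/MCC match the brute-force oracle on random tuples", {
  expect_equal(precision_recall_f1_mcc(3, 0, 1, 0)[["precision"]], 0.75)
  expect_equal(precision_recall_f1_mcc(5, 5, 0, 0)[["mcc"]], 1)
  expect_equal(unname(precision_recall_f1_mcc(0, 10, 0, 0)),
               c(0, 0, 0, 0))     # zero-denominator conventions
  set.seed(42)
  for (i in 1:200) {
    x <- sample(0:30, 4, replace = TRUE)
    got <- precision_recall_f1_mcc(x[1], x[2], x[3], x[4])
    expect_equal(unname(got), oracle_metrics(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-12)
  }
})

test_that("metric symmetry: swapping fp and fn swaps precision and recall", {
  set.seed(7)
  for (i in 1:25) {
    x <- sample(1:30, 4, replace = TRUE)
    a <- precision_recall_f1_mcc(x[1], x[2], x[3], x[4])
    b <- precision_recall_f1_mcc(x[1], x[2], x[4], x[3])
    expect_equal(a[["precision"]], b[["recall"]])
    expect_equal(a[["recall"]], b[["precision"]])
  }
})

test_that("windowed CS recall counts shifts within the window, among correct classifications", {
  pred_class <- c("SP", "SP", "SP", "mTP", "SP")
  pred_cs <- c(10L, 13L, 8L, 10L, 20L)
  obs_class <- c("SP", "SP", "SP", "SP", "noTP")
  obs_cs <- c(10L, 10L, 10L, 10L, NA)
  expect_equal(cs_recall(pred_class, pred_cs, obs_class, obs_cs, "SP", 0), 1 / 3)
  expect_equal(cs_recall(pred_class, pred_cs, obs_class, obs_cs, "SP", 2), 2 / 3)
  expect_equal(cs_recall(pred_class, pred_cs, obs_class, obs_cs, "SP", 3), 1)
  # the misclassified record (row 4) never counts, at any window
  expect_equal(cs_recall(pred_class, pred_cs, obs_class, obs_cs, "SP", 5), 1)
})

test_that("CS recall is non-decreasing in the window on random prediction sets", {
  set.seed(11)
  for (i in 1:100) {
    n <- 40
    obs_class <- sample(tp_classes, n, replace = TRUE)
    obs_cs <- ifelse(obs_class == "noTP", NA, sample(5:50, n, replace = TRUE))
    pred_class <- sample(tp_classes, n, replace = TRUE)
    pred_cs <- ifelse(pred_class == "noTP", NA, sample(5:50, n, replace = TRUE))
    for (cls in c("SP", "mTP")) {
      r <- vapply(0:5, function(w)
        cs_recall(pred_class, pred_cs, obs_class, obs_cs, cls, w), 0)
      r <- r[!is.na(r)]
      if (length(r) > 1) expect_true(all(diff(r) >= 0))
    }
  }
})

test_that("ROC points and AUC match independent oracles", {
  lab <- c("SP", "SP", "noTP", "noTP")
  perfect <- roc_points(c(0.9, 0.8, 0.2, 0.1), lab, "SP")
  expect_equal(roc_auc(perfect), 1)
  flat <- roc_points(rep(0.5, 4), lab, "SP")
  expect_equal(roc_auc(flat), 0.5)
  expect_error(roc_points(c(0.4, 0.6), c("SP", "SP"), "SP"), "positive and negative")
  set.seed(13)
  for (i in 1:50) {
    n <- 30
    lab <- sample(c("SP", "noTP"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    sc <- round(runif(n), 2)          # ties included
    roc <- roc_points(sc, lab, "SP")
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_equal(roc_auc(roc), oracle_auc(sc, lab == "SP"), tolerance = 1e-12)
  }
})

test_that("ROC area agrees with pROC on a random score set", {
  skip_if_not_installed("pROC")
  set.seed(17)
  lab <- sample(c("SP", "noTP"), 60, replace = TRUE)
  sc <- runif(60)
  ours <- roc_auc(roc_points(sc, lab, "SP"))
  theirs <- as.numeric(pROC::auc(pROC::roc(lab == "SP", sc, quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})
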