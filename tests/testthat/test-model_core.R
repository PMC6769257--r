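# The pure-R layer functions are the semantic reference; the compiled
# kernel must agree with them, and its analytic gradients must agree with
# finite differences of its own loss.

test_that("layer shapes follow the configuration (full-size and tiny)", {
  cfg <- tiny_config()
  params <- tp_init_params(cfg)
  recs <- tiny_records()
  enc <- encode_batch(recs, 60L)
  C <- feature_transform(enc$features, params, cfg)
  expect_equal(dim(C)[3], cfg$feat_units)
  H <- bilstm_encode(C, enc$group_vec, enc$lengths, params, cfg)
  expect_equal(dim(H)[3], 2L * cfg$lstm_units)
  A <- multi_attention(H, enc$mask, params, cfg)
  expect_equal(dim(A)[2], cfg$n_attn)
  E <- encode_context(A, H)
  expect_equal(dim(E), c(nrow(recs), cfg$n_attn, 2L * cfg$lstm_units))
  P <- predict_type(E, params, cfg)
  expect_equal(dim(P), c(nrow(recs), 5L))
  # full-size architecture constants
  full <- tp_config()
  expect_equal(full$feat_units, 32L)
  expect_equal(2L * full$lstm_units, 512L)
  expect_equal(full$attn_units, 144L)
  expect_equal(full$n_attn, 13L)
  fp <- tp_init_params(full)
  expect_equal(dim(fp$W1), c(20L, 32L))
  expect_equal(dim(fp$Wa), c(512L, 144L))
  expect_equal(dim(fp$Va), c(144L, 13L))
  expect_equal(dim(fp$W2), c(512L * 13L, 256L))
  expect_equal(dim(fp$W3), c(256L, 5L))
})

test_that("feature transform maps zero rows through the bias and is batch-equivariant", {
  cfg <- tiny_config()
  params <- tp_init_params(cfg)
  x <- array(0, c(2, 3, 20))
  x[2, 1, ] <- rnorm(20)
  C <- feature_transform(x, params, cfg)
  expect_equal(C[1, 1, ], pmax(params$b1, 0))     # zero input -> relu(b)
  perm <- feature_transform(x[2:1, , , drop = FALSE], params, cfg)
  expect_equal(perm[1, , ], C[2, , ])
})

test_that("probability outputs normalise with zero mass on padding", {
  cfg <- tiny_config()
  params <- tp_init_params(cfg)
  recs <- tiny_records()
  enc <- encode_batch(recs, 60L)
  fw <- tp_forward_ref(enc, params, cfg)
  expect_equal(rowSums(fw$class_probs), rep(1, nrow(recs)), tolerance = 1e-6)
  for (i in seq_len(nrow(recs))) {
    rows <- fw$attention[i, , ]
    expect_equal(rowSums(rows), rep(1, cfg$n_attn), tolerance = 1e-6)
    pad <- !enc$mask[i, ]
    if (any(pad)) expect_true(all(rows[, pad] == 0))
  }
  expect_equal(fw$cs_probs, fw$attention[, 1:4, , drop = FALSE])
})

test_that("group flag reaches the encoder through the initial states", {
  cfg <- tiny_config()
  params <- tp_init_params(cfg)
  recs <- tiny_records()[1:2, ]
  e1 <- encode_batch(recs, 60L); e1$group_vec <- c(0, 0)
  e2 <- encode_batch(recs, 60L); e2$group_vec <- c(1, 1)
  f1 <- tp_forward_ref(e1, params, cfg)
  f2 <- tp_forward_ref(e2, params, cfg)
  expect_gt(max(abs(f1$class_probs - f2$class_probs)), 0)
})

test_that("attention on a single-residue sequence puts weight 1 there", {
  cfg <- tiny_config()
  params <- tp_init_params(cfg)
  recs <- tp_records("one", "M")
  enc <- encode_batch(recs, 10L)
  fw <- tp_forward_ref(enc, params, cfg)
  expect_equal(as.numeric(fw$attention[1, , 1]), rep(1, cfg$n_attn))
})

test_that("delta and uniform attention give the expected context vectors", {
  H <- array(0, c(1, 2, 4))
  H[1, 1, ] <- c(1, 2, 3, 4)
  H[1, 2, ] <- c(1, 2, 3, 4)
  A <- array(0, c(1, 5, 2))
  A[1, , ] <- 0.5                       # uniform over two identical vectors
  E <- encode_context(A, H)
  for (k in 1:5) expect_equal(E[1, k, ], c(1, 2, 3, 4))
  A2 <- array(0, c(1, 5, 2)); A2[1, , 2] <- 1   # one-hot at t = 2
  H[1, 2, ] <- c(9, 8, 7, 6)
  E2 <- encode_context(A2, H)
  expect_equal(E2[1, 1, ], c(9, 8, 7, 6))
})

test_that("compiled forward equals the R reference to numerical precision", {
  cfg <- tiny_config()
  params <- tp_init_params(cfg)
  recs <- tiny_records()
  enc <- encode_batch(recs, 60L)
  ref <- tp_forward_ref(enc, params, cfg)
  a <- targpep:::.batch_args(recs, 60L)
  fw <- targpep:::cpp_forward(params, a$X, a$lengths, a$group)
  expect_equal(fw$class_probs, unname(ref$class_probs), tolerance = 1e-12)
  expect_equal(fw$attention, ref$attention, tolerance = 1e-12)
})

test_that("compiled loss equals the reference loss, including the all-noTP case", {
  cfg <- tiny_config()
  params <- tp_init_params(cfg)
  recs <- tiny_records()
  enc <- encode_batch(recs, 100L)
  a <- targpep:::.batch_args(recs, 100L)
  st <- targpep:::cpp_train_step(params, a$X, a$lengths, a$group, a$class0,
                                 a$cs0, 0, 1L)
  ref <- tp_forward_ref(enc, params, cfg)
  expect_equal(st$loss, tp_loss_ref(ref, enc$class_targets, enc$cs_targets,
                                    enc$lengths), tolerance = 1e-10)
  # all-noTP batch: loss reduces to the class term alone
  noTP <- recs[recs$label == "noTP", , drop = FALSE]
  an <- targpep:::.batch_args(noTP, 100L)
  st2 <- targpep:::cpp_train_step(params, an$X, an$lengths, an$group,
                                  an$class0, an$cs0, 0, 1L)
  encn <- encode_batch(noTP, 100L)
  refn <- tp_forward_ref(encn, params, cfg)
  pc <- refn$class_probs[cbind(seq_len(nrow(noTP)), encn$class_targets)]
  expect_equal(st2$loss, mean(-log(pc)), tolerance = 1e-10)
  expect_true(is.na(st2$cs_loss))
})

test_that("hand-computed cross-entropy on a toy batch matches the loss", {
  # two records, lengths 3 and 2; independent log-sum computation
  cfg <- tiny_config()
  params <- tp_init_params(cfg)
  recs <- tp_records(c("a", "b"), c("MAG", "MK"),
                     label = c("SP", "noTP"), cs = c(2L, NA))
  enc <- encode_batch(recs, 10L)
  fw <- tp_forward_ref(enc, params, cfg)
  lc <- -(log(fw$class_probs[1, "SP"]) + log(fw$class_probs[2, "noTP"])) / 2
  lcs <- -log(fw$cs_probs[1, 1, 2])       # SP head, position 2
  expect_equal(tp_loss_ref(fw, enc$class_targets, enc$cs_targets, enc$lengths),
               unname((lc + lcs) / 2), tolerance = 1e-12)
  expect_error(tp_loss_ref(fw, enc$class_targets, c(5L, -1L), enc$lengths),
               "beyond")
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_config()
  params <- tp_init_params(cfg)
  recs <- tiny_records()
  a <- targpep:::.batch_args(recs, 100L)
  fl <- function(p) targpep:::cpp_train_step(p, a$X, a$lengths, a$group,
                                             a$class0, a$cs0, 0, 1L)$loss
  st <- targpep:::cpp_train_step(params, a$X, a$lengths, a$group, a$class0,
                                 a$cs0, 0, 1L)
  eps <- 1e-5
  set.seed(9)
  for (nm in names(params)) {
    for (j in sample(length(params[[nm]]), min(2, length(params[[nm]])))) {
      up <- params; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- params; dn[[nm]][j] <- dn[[nm]][j] - eps
      num <- (fl(up) - fl(dn)) / (2 * eps)
      expect_equal(st$grads[[nm]][j], num, tolerance = 1e-4,
                   label = paste("grad", nm, j))
    }
  }
})

test_that("the CS term back-propagates nothing on an all-noTP batch", {
  # on noTP-only input the kernel's gradients must be exactly those of the
  # plain class cross-entropy: finite differences of an independently
  # computed class CE (via the R reference forward) match the analytic
  # gradients, so the CS path contributes zero.
  cfg <- tiny_config()
  params <- tp_init_params(cfg)
  noTP <- synth_generate(synth_spec(n = c(noTP = 4), seed = 3L))
  a <- targpep:::.batch_args(noTP, 40L)
  enc <- encode_batch(noTP, 40L)
  st <- targpep:::cpp_train_step(params, a$X, a$lengths, a$group, a$class0,
                                 a$cs0, 0, 1L)
  expect_true(is.na(st$cs_loss))
  class_ce <- function(p) {
    fw <- tp_forward_ref(enc, p, cfg)
    mean(-log(fw$class_probs[cbind(seq_len(nrow(noTP)), enc$class_targets)]))
  }
  expect_equal(st$loss, class_ce(params), tolerance = 1e-10)
  eps <- 1e-5
  for (nm in c("Va", "Wa", "wh0_f")) {
    j <- 1L
    up <- params; up[[nm]][j] <- up[[nm]][j] + eps
    dn <- params; dn[[nm]][j] <- dn[[nm]][j] - eps
    expect_equal(st$grads[[nm]][j], (class_ce(up) - class_ce(dn)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("forward is invariant to the amount of padding", {
  cfg <- tiny_config()
  params <- tp_init_params(cfg)
  recs <- tiny_records()[1:3, ]
  a1 <- targpep:::.batch_args(recs, 50L)
  pad <- array(0, c(3, 120, 20))
  pad[, seq_len(dim(a1$X)[2]), ] <- a1$X
  f1 <- targpep:::cpp_forward(params, a1$X, a1$lengths, a1$group)
  f2 <- targpep:::cpp_forward(params, pad, a1$lengths, a1$group)
  expect_equal(f1$class_probs, f2$class_probs, tolerance = 1e-5)
  L1 <- dim(a1$X)[2]
  expect_equal(f1$attention, f2$attention[, , seq_len(L1)], tolerance = 1e-5)
  expect_true(all(f2$attention[, , (L1 + 1):120] == 0))
})

test_that("forward is deterministic and batch-order equivariant", {
  cfg <- tiny_config()
  params <- tp_init_params(cfg)
  recs <- tiny_records()
  a <- targpep:::.batch_args(recs, 60L)
  f1 <- targpep:::cpp_forward(params, a$X, a$lengths, a$group)
  f2 <- targpep:::cpp_forward(params, a$X, a$lengths, a$group)
  expect_identical(f1, f2)
})
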