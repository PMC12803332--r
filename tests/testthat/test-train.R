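# Distillation losses, schedule, training loop, evaluation

test_that("cross-entropy loss matches hand values and Gibbs' inequality", {
  # one-hot teacher, student 0.99 at the true class
  P <- matrix(0, 4, 8); P[cbind(1:4, c(1, 2, 5, 8))] <- 1
  Q <- matrix((1 - 0.99) / 7, 4, 8); Q[cbind(1:4, c(1, 2, 5, 8))] <- 0.99
  expect_equal(cross_entropy_loss(P, Q), -log(0.99), tolerance = 1e-12)
  # uniform teacher and student
  U <- matrix(1 / 8, 6, 8)
  expect_equal(cross_entropy_loss(U, U), log(8), tolerance = 1e-12)
  # Gibbs: CE(P, Q) >= H(P), equality iff Q = P
  set.seed(19)
  for (k in 1:25) {
    P <- softmax_rows_ref(matrix(rnorm(40), 5, 8))
    Q <- softmax_rows_ref(matrix(rnorm(40), 5, 8))
    HP <- -mean(rowSums(P * log(P)))
    expect_gte(cross_entropy_loss(P, Q), HP - 1e-12)
    expect_equal(cross_entropy_loss(P, P), HP, tolerance = 1e-12)
  }
  expect_error(cross_entropy_loss(P, Q[1:3, ]), "mismatch")
})

test_that("total loss composes the two terms", {
  set.seed(20)
  P <- softmax_rows_ref(matrix(rnorm(24), 3, 8))
  Y <- matrix(0, 3, 8); Y[cbind(1:3, c(2, 2, 5))] <- 1
  Q <- softmax_rows_ref(matrix(rnorm(24), 3, 8))
  expect_equal(total_loss(P, Y, Q),
               cross_entropy_loss(P, Q) + cross_entropy_loss(Y, Q), tolerance = 1e-12)
  # identical terms when the teacher is the DSSP matrix itself
  expect_equal(total_loss(Y, Y, Q), 2 * cross_entropy_loss(Y, Q), tolerance = 1e-12)
  expect_equal(total_loss(P, Y, Q, weights = c(1, 0)), cross_entropy_loss(P, Q),
               tolerance = 1e-12)
})

test_that("the learning-rate schedule decays by 0.9 every three epochs", {
  tc <- training_config()
  for (e in 0:40)
    expect_equal(lr_at_epoch(tc, e), 1e-3 * 0.9^(e %/% 3), tolerance = 1e-15)
  # epoch 7 sits in the third block: lr = 1e-3 * 0.9^2
  expect_equal(lr_at_epoch(tc, 7), 1e-3 * 0.9^2, tolerance = 1e-15)
})

test_that("training reduces the loss and is bit-deterministic", {
  ds <- make_dataset(6, seed = 31)
  mc <- model_config(n_rbf = 8, hidden_dim = 12, head_dims = c(12, 12), seed = 2)
  tc <- training_config(epochs = 3, batch_size = 2, learning_rate = 3e-3,
                        seed = 5, val_fraction = 0.2)
  fit1 <- train(ds, mc, tc)
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  expect_named(fit1$history,
               c("epoch", "lr", "train_loss", "val_loss", "val_correct_prob"))
  expect_equal(fit1$history$lr, lr_at_epoch(tc, fit1$history$epoch))
  fit2 <- train(ds, mc, tc)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_error(train(list(), mc, tc), "empty")
})

test_that("dihedral-noise augmentation is reproducible and label-consistent", {
  rec <- teacher_record(fix_helix(10))
  aug1 <- sspot:::augment_record(rec, 8, seed = 3)
  aug2 <- sspot:::augment_record(rec, 8, seed = 3)
  expect_identical(aug1$structure$coords, aug2$structure$coords)
  expect_false(identical(aug1$structure$coords, rec$structure$coords))
  # labels recomputed from the perturbed geometry
  expect_equal(aug1$dssp, one_hot(assign_ss8(aug1$structure)))
})

test_that("teacher CSV loading handles probabilities, logits and bad shapes", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  probs <- softmax_rows_ref(matrix(rnorm(32), 4, 8))
  colnames(probs) <- SS8_CLASSES
  f1 <- file.path(dir, "probs.csv")
  write.csv(as.data.frame(probs), f1, row.names = FALSE)
  M <- load_teacher_matrix(f1, n_res = 4)
  expect_equal(dim(M), c(12L, 8L))
  expect_equal(unname(rowSums(M)), rep(1, 12), tolerance = 1e-6)
  expect_equal(M[1, ], M[3, ])  # triplicated residue rows
  # logits of zero become exactly uniform
  zeros <- matrix(0, 3, 8); colnames(zeros) <- SS8_CLASSES
  f2 <- file.path(dir, "logits.csv")
  write.csv(as.data.frame(zeros), f2, row.names = FALSE)
  M2 <- load_teacher_matrix(f2, n_res = 3, type = "logit")
  expect_true(all(abs(M2 - 1 / 8) < 1e-12))
  # wrong column count
  f3 <- file.path(dir, "bad.csv")
  write.csv(as.data.frame(probs[, 1:7]), f3, row.names = FALSE)
  expect_error(load_teacher_matrix(f3), "8 columns")
  expect_error(load_teacher_matrix(f1, n_res = 7), "neither")
})

test_that("file-mode training consumes soft teacher labels", {
  ds <- make_dataset(4, seed = 41)
  recs <- lapply(ds, function(d) {
    n <- n_res(d$structure)
    soft <- softmax_rows_ref(matrix(rnorm(8 * n, sd = 2), n, 8))
    teacher_record(d$structure, teacher = soft)
  })
  mc <- model_config(n_rbf = 4, hidden_dim = 8, head_dims = c(8, 8), seed = 1)
  tc <- training_config(epochs = 2, batch_size = 2, seed = 1,
                        teacher_mode = "files", val_fraction = 0)
  fit <- train(recs, mc, tc)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1] + 1e-9)
  # missing teacher in files mode is an error
  expect_error(train(list(teacher_record(ds[[1]]$structure)), mc, tc), "teacher")
})

test_that("confusion evaluation matches closed-form predictors", {
  s <- fix_helix(10)
  # uniform predictor: every entry 1/8
  repu <- evaluate_confusion(fix_zero_model(), list(s))
  sup <- repu$support > 0
  expect_true(all(abs(repu$confusion[sup, ] - 0.125) < 1e-9))
  expect_equal(repu$diag_mean, 0.125, tolerance = 1e-9)
  expect_equal(repu$mean_correct_prob, 0.125, tolerance = 1e-9)
  # biased predictor: huge final bias on class H -> p(H) ~ 1 everywhere
  mH <- fix_zero_model()
  mH$params$head$b3 <- c(0, 50, 0, 0, 0, 0, 0, 0)
  repH <- evaluate_confusion(mH, list(s))
  expect_true(all(abs(repH$confusion[sup, "H"] - 1) < 1e-9))
  # diagonal mean averages over supported classes only (H -> 1, others -> 0)
  truth <- ss8_letters(assign_ss8(s))
  n_classes <- length(unique(truth))
  expect_equal(repH$diag_mean, 1 / n_classes, tolerance = 1e-9)
  expect_equal(repH$mean_correct_prob, mean(truth == "H"), tolerance = 1e-9)
})
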