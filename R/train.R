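# Knowledge-distillation training: Adam on the summed cross-entropy between
# teacher SS8 likelihoods (file-supplied soft labels, or DSSP one-hot labels
# as the built-in teacher) and the student GNN's predictions, with the
# stated step-decay learning-rate schedule and L2 weight decay.

#' Training configuration
#'
#' Defaults follow the reference training procedure: 120 epochs, batches of
#' 50 proteins, Adam at 1e-3 decayed by 0.9 every three epochs, weight decay
#' 1e-6. Epoch indices are 0-based, so the learning rate at epoch e is
#' `learning_rate * lr_decay_factor^(e %/% lr_decay_every)`.
#'
#' @param epochs Number of passes over the training set (default 120).
#' @param batch_size Proteins per mini-batch (default 50).
#' @param learning_rate Initial Adam learning rate (default 1e-3).
#' @param lr_decay_factor Multiplicative decay (default 0.9).
#' @param lr_decay_every Epochs between decays (default 3).
#' @param weight_decay L2 coefficient added to the gradient as
#'   `weight_decay * theta` (default 1e-6).
#' @param seed Seed for the split, shuffling and any augmentation.
#' @param teacher_mode `"dssp"` (built-in one-hot teacher; the distillation
#'   and anchor terms coincide, so the total loss is twice the DSSP term) or
#'   `"files"` (external soft-label teacher supplied per record).
#' @param loss_weights Weights of the (teacher, DSSP) cross-entropy terms.
#' @param val_fraction Held-out fraction of proteins (default 0.2).
#' @param augment_noise_deg Dihedral-noise augmentation: when > 0, each
#'   training copy of a protein is rebuilt each epoch with independent
#'   Gaussian (phi, psi) noise of this standard deviation (degrees) and its
#'   DSSP labels recomputed; sequence-conditioned teacher matrices are kept
#'   as-is. Off (0) by default.
#' @return A `training_config` object.
#' @export
training_config <- function(epochs = 120L, batch_size = 50L, learning_rate = 1e-3,
                            lr_decay_factor = 0.9, lr_decay_every = 3L,
                            weight_decay = 1e-6, seed = 1L,
                            teacher_mode = c("dssp", "files"),
                            loss_weights = c(1, 1), val_fraction = 0.2,
                            augment_noise_deg = 0) {
  teacher_mode <- match.arg(teacher_mode)
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            lr_decay_factor > 0, lr_decay_factor <= 1,
            length(loss_weights) == 2L, val_fraction >= 0, val_fraction < 1,
            augment_noise_deg >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 weight_decay = weight_decay, seed = as.integer(seed),
                 teacher_mode = teacher_mode, loss_weights = loss_weights,
                 val_fraction = val_fraction,
                 augment_noise_deg = augment_noise_deg),
            class = "training_config")
}

# Rebuild a record's structure with Gaussian dihedral noise and fresh DSSP
# labels. The teacher matrix (sequence-conditioned) is retained.
augment_record <- function(rec, sd_deg, seed) {
  s <- rec$structure
  n <- n_res(s)
  dh <- backbone_dihedrals(s)
  noise <- with_seed(seed, matrix(stats::rnorm(2L * n, sd = sd_deg), ncol = 2))
  phi <- dh$phi + noise[, 1]; psi <- dh$psi + noise[, 2]
  phi[1] <- 0; psi[n] <- 0
  s2 <- build_from_dihedrals(s$sequence, phi, psi, chain_id = s$chain_id)
  structure(list(structure = s2, teacher = rec$teacher,
                 dssp = one_hot(assign_ss8(s2))),
            class = "teacher_record")
}

#' Learning rate at a (0-based) epoch
#' @param tc A [training_config()].
#' @param epoch 0-based epoch index.
#' @return The scheduled learning rate.
#' @export
lr_at_epoch <- function(tc, epoch) {
  tc$learning_rate * tc$lr_decay_factor^(epoch %/% tc$lr_decay_every)
}

#' Averaged cross-entropy between teacher and student SS8 matrices
#'
#' Mean over atoms of `-sum_j P_ij log Q_ij`. Averaging is per atom within a
#' protein; [train()] then averages over the proteins of a batch.
#'
#' @param P Teacher matrix (`3*n_res x 8`, row-stochastic or one-hot).
#' @param Q Student matrix (same shape, strictly positive rows from softmax).
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!identical(dim(P), dim(Q))) stop("teacher/student shape mismatch")
  -mean(rowSums(P * log(Q)))
}

#' Total distillation loss
#'
#' Weighted sum of the teacher-distillation and DSSP-anchor cross-entropy
#' terms (default weights 1, 1).
#'
#' @param P_teacher Teacher SS8 matrix.
#' @param Y_dssp DSSP one-hot SS8 matrix.
#' @param Q Student SS8 matrix.
#' @param weights Length-2 weights for the two terms.
#' @return Scalar loss.
#' @export
total_loss <- function(P_teacher, Y_dssp, Q, weights = c(1, 1)) {
  weights[1] * cross_entropy_loss(P_teacher, Q) +
    weights[2] * cross_entropy_loss(Y_dssp, Q)
}

#' Bundle a structure with its teacher/reference label matrices
#'
#' @param structure A `backbone`.
#' @param teacher Optional teacher SS8 matrix (`n_res x 8` or `3*n_res x 8`;
#'   residue-level rows are triplicated).
#' @param dssp Optional DSSP one-hot matrix; computed from the structure via
#'   [assign_ss8()] when omitted.
#' @return A `teacher_record`.
#' @export
teacher_record <- function(structure, teacher = NULL, dssp = NULL) {
  n_atoms <- 3L * n_res(structure)
  if (is.null(dssp)) dssp <- one_hot(assign_ss8(structure))
  dssp <- as.matrix(dssp)
  if (nrow(dssp) == n_atoms / 3L) dssp <- triplicate(dssp)
  if (nrow(dssp) != n_atoms) stop("dssp matrix rows match neither n_res nor 3*n_res")
  if (!is.null(teacher)) {
    teacher <- as.matrix(teacher)
    if (nrow(teacher) == n_atoms / 3L) teacher <- triplicate(teacher)
    if (nrow(teacher) != n_atoms) stop("teacher matrix rows match neither n_res nor 3*n_res")
  }
  structure(list(structure = structure, teacher = teacher, dssp = dssp),
            class = "teacher_record")
}

#' Load a teacher SS8 matrix from CSV
#'
#' Expects 8 columns headed G,H,I,T,E,B,S,C, one row per residue or per atom.
#' Residue-level rows are triplicated to atoms. Probability rows (summing to
#' 1) pass through; anything else is treated as logits and sent through a
#' row-wise softmax.
#'
#' @param path CSV file path.
#' @param n_res Optional expected residue count (validated when given).
#' @param type `"auto"` (default), `"prob"` or `"logit"`.
#' @return A `3*n_res x 8` row-stochastic matrix.
#' @export
load_teacher_matrix <- function(path, n_res = NULL, type = c("auto", "prob", "logit")) {
  type <- match.arg(type)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) != 8L)
    stop(sprintf("teacher file must have 8 columns (G,H,I,T,E,B,S,C), found %d", ncol(df)))
  if (!identical(toupper(names(df)), SS8_CLASSES))
    warning("teacher columns are not headed G,H,I,T,E,B,S,C; assuming canonical order")
  M <- as.matrix(df)
  if (!is.null(n_res)) {
    if (nrow(M) != n_res && nrow(M) != 3L * n_res)
      stop("teacher rows match neither n_res nor 3*n_res")
  }
  is_prob <- all(M >= 0) && all(abs(rowSums(M) - 1) < 1e-4)
  if (type == "logit" || (type == "auto" && !is_prob)) M <- softmax_rows(M)
  if (nrow(M) %% 3L != 0L || (!is.null(n_res) && nrow(M) == n_res)) M <- triplicate(M)
  dimnames(M) <- list(NULL, SS8_CLASSES)
  M
}

# Loss and gradient-on-logits for one record. Returns loss value and dlogits.
record_loss_terms <- function(Q, rec, tc) {
  n_atoms <- nrow(Q)
  w <- tc$loss_weights
  if (tc$teacher_mode == "dssp" || is.null(rec$teacher)) {
    P_list <- list(rec$dssp, rec$dssp)
  } else {
    P_list <- list(rec$teacher, rec$dssp)
  }
  loss <- w[1] * cross_entropy_loss(P_list[[1]], Q) +
          w[2] * cross_entropy_loss(P_list[[2]], Q)
  dlogits <- (w[1] * (Q - P_list[[1]]) + w[2] * (Q - P_list[[2]])) / n_atoms
  list(loss = loss, dlogits = dlogits)
}

#' Train the GNN by knowledge distillation
#'
#' Adam with the step-decay schedule and L2 weight decay of
#' [training_config()], over shuffled mini-batches of whole proteins
#' (gradients averaged per protein, never mixing edges across proteins).
#' Deterministic given the seeds.
#'
#' @param dataset A list of [teacher_record()]s, or of `make_protein()`
#'   results / bare `backbone`s (DSSP labels computed automatically).
#' @param mc A [model_config()].
#' @param tc A [training_config()].
#' @param model Optional pre-initialized `schake_model` to continue training.
#' @param verbose Print per-epoch progress to stderr.
#' @return A list: `model` (trained `schake_model`) and `history` (data.frame
#'   with columns epoch, lr, train_loss, val_loss, val_correct_prob).
#' @export
train <- function(dataset, mc = model_config(), tc = training_config(),
                  model = NULL, verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty dataset")
  records <- lapply(dataset, function(d) {
    if (inherits(d, "teacher_record")) d
    else if (inherits(d, "backbone")) teacher_record(d)
    else if (is.list(d) && inherits(d$structure, "backbone")) teacher_record(d$structure)
    else stop("dataset elements must be teacher_records or backbones")
  })
  if (tc$teacher_mode == "files" &&
      any(vapply(records, function(r) is.null(r$teacher), logical(1))))
    stop("teacher_mode='files' requires a teacher matrix in every record")
  n <- length(records)
  idx <- with_seed(tc$seed, sample.int(n))
  n_val <- floor(tc$val_fraction * n)
  val_idx <- if (n_val > 0L) idx[seq_len(n_val)] else integer(0)
  train_idx <- setdiff(idx, val_idx)
  if (length(train_idx) == 0L) stop("no training proteins after split")
  if (is.null(model)) model <- init_model(mc)
  theta <- flatten_params(model$params)
  m1 <- numeric(length(theta)); v1 <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; t_step <- 0L
  history <- data.frame()
  batch_orders <- with_seed(tc$seed + 1L, {
    lapply(seq_len(tc$epochs), function(e) sample(train_idx))
  })
  aug_seeds <- if (tc$augment_noise_deg > 0)
    with_seed(tc$seed + 2L, matrix(sample.int(2^30, tc$epochs * n, replace = TRUE),
                                   tc$epochs, n))
  else NULL
  for (epoch in seq_len(tc$epochs) - 1L) {
    lr <- lr_at_epoch(tc, epoch)
    order_e <- batch_orders[[epoch + 1L]]
    batches <- split(order_e, ceiling(seq_along(order_e) / tc$batch_size))
    ep_loss <- 0; ep_n <- 0L
    for (b in batches) {
      grad <- numeric(length(theta))
      bloss <- 0
      for (k in b) {
        rec <- records[[k]]
        if (!is.null(aug_seeds))
          rec <- augment_record(rec, tc$augment_noise_deg, aug_seeds[epoch + 1L, k])
        fw <- schake_forward(model, rec$structure, need_cache = TRUE)
        Q <- softmax_rows(fw$logits)
        lt <- record_loss_terms(Q, rec, tc)
        if (!is.finite(lt$loss)) stop("training diverged: non-finite loss")
        bk <- schake_backward(model, fw$cache, lt$dlogits, wrt = "params")
        grad <- grad + flatten_params(bk$dparams)
        bloss <- bloss + lt$loss
      }
      grad <- grad / length(b) + tc$weight_decay * theta
      bloss <- bloss / length(b)
      ep_loss <- ep_loss + bloss * length(b); ep_n <- ep_n + length(b)
      t_step <- t_step + 1L
      m1 <- b1 * m1 + (1 - b1) * grad
      v1 <- b2 * v1 + (1 - b2) * grad^2
      mhat <- m1 / (1 - b1^t_step)
      vhat <- v1 / (1 - b2^t_step)
      theta <- theta - lr * mhat / (sqrt(vhat) + adam_eps)
      model$params <- unflatten_params(theta, model$params)
    }
    val <- if (length(val_idx) > 0L) {
      evaluate_split(model, records[val_idx], tc)
    } else list(loss = NA_real_, correct = NA_real_)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss / ep_n,
      val_loss = val$loss, val_correct_prob = val$correct))
    if (verbose)
      message(sprintf("epoch %3d lr %.2e train %.4f val %.4f acc %.3f",
                      epoch, lr, ep_loss / ep_n, val$loss, val$correct))
  }
  list(model = model, history = history,
       split = list(train = train_idx, val = val_idx))
}

evaluate_split <- function(model, records, tc) {
  losses <- numeric(0); correct_num <- 0; correct_den <- 0L
  for (rec in records) {
    Q <- predict_ss8(model, rec$structure)
    lt <- record_loss_terms(Q, rec, tc)
    losses <- c(losses, lt$loss)
    truth <- max.col(rec$dssp)
    correct_num <- correct_num + sum(Q[cbind(seq_len(nrow(Q)), truth)])
    correct_den <- correct_den + nrow(Q)
  }
  list(loss = mean(losses), correct = correct_num / correct_den)
}

#' Confusion-style evaluation report
#'
#' Entry (a, b) of the matrix is the mean predicted likelihood of class b
#' over atoms whose true class is a. Reports the macro average along the
#' diagonal over classes with support (`diag_mean`) and the atom-level mean
#' predicted likelihood of the true class (`mean_correct_prob`).
#'
#' @param model A `schake_model`.
#' @param dataset List of records accepted by [train()] (DSSP labels used as
#'   truth).
#' @return An `eval_report`: list with `confusion` (8x8), `support`,
#'   `diag_mean`, `mean_correct_prob`.
#' @export
evaluate_confusion <- function(model, dataset) {
  records <- lapply(dataset, function(d) {
    if (inherits(d, "teacher_record")) d
    else if (inherits(d, "backbone")) teacher_record(d)
    else teacher_record(d$structure)
  })
  acc <- matrix(0, 8, 8, dimnames = list(SS8_CLASSES, SS8_CLASSES))
  support <- stats::setNames(integer(8), SS8_CLASSES)
  correct_num <- 0; correct_den <- 0L
  for (rec in records) {
    Q <- predict_ss8(model, rec$structure)
    truth <- max.col(rec$dssp)
    for (a in seq_len(8)) {
      rows <- which(truth == a)
      if (length(rows) == 0L) next
      acc[a, ] <- acc[a, ] + colSums(Q[rows, , drop = FALSE])
      support[a] <- support[a] + length(rows)
    }
    correct_num <- correct_num + sum(Q[cbind(seq_len(nrow(Q)), truth)])
    correct_den <- correct_den + nrow(Q)
  }
  confusion <- acc / ifelse(support > 0L, support, NA_real_)
  structure(list(
    confusion = confusion, support = support,
    diag_mean = mean(diag(confusion)[support > 0L]),
    mean_correct_prob = correct_num / correct_den
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  mean correct-motif probability (atoms): %.3f\n", x$mean_correct_prob))
  cat(sprintf("  diagonal mean (classes with support):   %.3f\n", x$diag_mean))
  cat("  support:", paste(sprintf("%s=%d", names(x$support), x$support), collapse = " "), "\n")
  invisible(x)
}
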