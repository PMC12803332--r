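# Likelihood-derived energies and forces

test_that("local motif energy has the right closed-form values", {
  expect_equal(local_motif_energy(1), -log(1 + 1e-8))
  expect_lt(abs(local_motif_energy(1)), 1e-7)
  expect_equal(local_motif_energy(1 / 8), log(8), tolerance = 1e-6)
  e0 <- local_motif_energy(0)
  expect_true(is.finite(e0))
  expect_equal(e0, -log(1e-8), tolerance = 1e-12)
})

test_that("uniform likelihoods give the closed-form one-state energy", {
  m <- fix_zero_model()   # all-zero parameters -> exactly uniform likelihoods
  s <- fix_helix(4)
  ref <- ss8_labels(rep(1L, 4))
  ep <- energy_params(gamma = 1, temperature = 300)
  r <- energy_one_state(m, s, ref, ep)
  expect_equal(r$total, 12 * 0.008314 * 300 * log(8), tolerance = 1e-6)
  expect_equal(sum(r$per_atom), r$total, tolerance = 1e-9)
  # gamma linearity and temperature proportionality
  r25 <- energy_one_state(m, s, ref, energy_params(gamma = 2.5, temperature = 300))
  expect_equal(r25$total / r$total, 2.5, tolerance = 1e-12)
  r150 <- energy_one_state(m, s, ref, energy_params(gamma = 1, temperature = 150))
  expect_equal(r150$total / r$total, 0.5, tolerance = 1e-12)
})

test_that("uniform likelihoods give the closed-form multi-state energy", {
  m <- fix_zero_model()
  s <- fix_helix(4)
  # E = 3n * kB * T * (ln 8 - ln(8)/beta) for equal entries under LogSumExp
  for (beta in c(4, 16, 64)) {
    ep <- energy_params(gamma = 1, temperature = 300, beta_smooth = beta)
    r <- energy_multi_state(m, s, ep)
    expect_equal(r$total, 12 * 0.008314 * 300 * (log(8) - log(8) / beta),
                 tolerance = 1e-5)
  }
})

test_that("smooth max obeys the LogSumExp bounds and converges monotonically", {
  set.seed(14)
  V <- matrix(log(softmax_rows_ref(matrix(rnorm(8000), 1000, 8))), 1000, 8)
  for (row in sample(1000, 50)) {
    v <- V[row, ]
    prev <- Inf
    for (beta in c(1, 4, 16, 64, 256)) {
      sm <- smooth_max(v, beta)
      expect_gte(sm, max(v))
      expect_lte(sm, max(v) + log(8) / beta + 1e-12)
      expect_lte(sm, prev + 1e-12)
      prev <- sm
    }
  }
})

test_that("hard-max multi-state energy never exceeds the one-state energy", {
  # per-atom: -log(max_j q_j) <= -log(q_ref) for any reference, since max >= q_ref
  set.seed(15)
  Q <- softmax_rows_ref(matrix(rnorm(8000), 1000, 8))
  e_ms <- -log(apply(Q, 1, max) + 1e-8)
  for (k in 1:20) {
    ref <- sample.int(8, 1000, replace = TRUE)
    e_os <- -log(Q[cbind(1:1000, ref)] + 1e-8)
    expect_true(all(e_ms <= e_os + 1e-12))
  }
  # and through the model-level functions
  m <- fix_small_model()
  s <- fix_mixed()
  ep <- energy_params(gamma = 2.5)
  ms_hard <- energy_multi_state(m, s, ep, hard = TRUE)$total
  set.seed(16)
  for (k in 1:5) {
    ref <- ss8_labels(sample.int(8, n_res(s), replace = TRUE) - 1L)
    expect_lte(ms_hard, energy_one_state(m, s, ref, ep)$total + 1e-9)
  }
  expect_error(energy_multi_state(m, s, ep, hard = TRUE, forces = TRUE), "smooth")
})

test_that("energies are invariant and forces equivariant under rigid motions", {
  m <- fix_small_model()
  s <- fix_mixed()
  lab <- assign_ss8(s)
  ep <- energy_params(gamma = 2.5)
  r0 <- energy_one_state(m, s, lab, ep, forces = TRUE)
  set.seed(17)
  for (k in 1:5) {
    R <- random_rotation(); tr <- rnorm(3)
    rk <- energy_one_state(m, rigid_move(s, R, tr), lab, ep, forces = TRUE)
    expect_lt(abs(rk$total - r0$total), 1e-6)
    F0 <- forces_as_matrix(r0$forces) %*% R
    expect_lt(max(abs(forces_as_matrix(rk$forces) - F0)), 1e-6)
  }
  rms0 <- energy_multi_state(m, s, ep)
  expect_lt(abs(energy_multi_state(m, rigid_move(s), ep)$total - rms0$total), 1e-6)
})

test_that("net force and net torque vanish", {
  m <- fix_small_model()
  s <- fix_mixed()
  for (mode in c("os", "ms")) {
    F <- gnn_forces(mode, m, s, ref = assign_ss8(s), ep = energy_params(gamma = 2.5))
    Fm <- forces_as_matrix(F)
    expect_lt(max(abs(colSums(Fm))), 1e-6)
    X <- atom_matrix(s)
    cen <- sweep(X, 2, colMeans(X))
    tq <- colSums(cbind(cen[, 2] * Fm[, 3] - cen[, 3] * Fm[, 2],
                        cen[, 3] * Fm[, 1] - cen[, 1] * Fm[, 3],
                        cen[, 1] * Fm[, 2] - cen[, 2] * Fm[, 1]))
    expect_lt(max(abs(tq)), 1e-6)
  }
})

test_that("analytic forces match central finite differences", {
  m <- fix_small_model()
  s <- fix_helix(10)
  lab <- assign_ss8(s)
  ep <- energy_params(gamma = 2.5)
  X <- atom_matrix(s)
  h <- 1e-5
  set.seed(18)
  idx <- cbind(sample(nrow(X), 8, replace = TRUE), sample(3, 8, replace = TRUE))
  for (mode in c("os", "ms")) {
    efun <- function(Xp) {
      sp <- set_atom_matrix(s, Xp)
      if (mode == "os") energy_one_state(m, sp, lab, ep)$total
      else energy_multi_state(m, sp, ep)$total
    }
    g <- -forces_as_matrix(gnn_forces(mode, m, s, ref = lab, ep = ep))
    for (k in seq_len(nrow(idx))) {
      Xp <- X; Xp[idx[k, 1], idx[k, 2]] <- Xp[idx[k, 1], idx[k, 2]] + h
      Xm <- X; Xm[idx[k, 1], idx[k, 2]] <- Xm[idx[k, 1], idx[k, 2]] - h
      fd <- (efun(Xp) - efun(Xm)) / (2 * h)
      expect_lt(abs(fd - g[idx[k, 1], idx[k, 2]]) / max(abs(fd), 1e-6), 1e-3)
    }
  }
})

test_that("reference label plumbing validates shapes", {
  m <- fix_small_model()
  s <- fix_helix(5)
  ep <- energy_params()
  lab <- assign_ss8(s)
  # residue-level one-hot is triplicated automatically
  res_oh <- matrix(0, 5, 8); res_oh[cbind(1:5, as.integer(lab) + 1L)] <- 1
  expect_equal(energy_one_state(m, s, res_oh, ep)$total,
               energy_one_state(m, s, lab, ep)$total, tolerance = 1e-12)
  expect_error(energy_one_state(m, s, res_oh[1:3, ], ep), "match")
  expect_error(energy_one_state(m, s, res_oh * 2, ep), "one-hot|stochastic")
})
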