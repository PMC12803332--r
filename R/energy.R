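# Likelihood-derived energies: the one-state energy reads the reference
# (folded) motif's likelihood at each backbone atom, the multi-state energy
# reads the smooth maximum over all eight motifs. Both are -gamma*kB*T times
# a sum of per-atom log-likelihood terms, with an epsilon floor inside the
# log for numerical stability, and support exact reverse-mode forces.

#' Energy-function parameters
#'
#' @param gamma Dimensionless scaling of the GNN energy (2.5 is the
#'   standalone-potential setting; combined with a Generalized-Born
#'   electrostatics engine a much smaller value such as 0.175 is appropriate).
#' @param temperature Temperature in K.
#' @param k_B Boltzmann constant, kJ/mol/K (fixed at 0.008314).
#' @param epsilon Likelihood floor inside the log (default 1e-8).
#' @param beta_smooth LogSumExp sharpness for the multi-state smooth max
#'   (default 16; the smoothing error per atom is bounded by log(8)/beta).
#' @return An `energy_params` object.
#' @export
energy_params <- function(gamma = 1, temperature = 300, k_B = 0.008314,
                          epsilon = 1e-8, beta_smooth = 16) {
  stopifnot(gamma >= 0, temperature > 0, beta_smooth > 0, epsilon >= 0)
  structure(list(gamma = gamma, temperature = temperature, k_B = k_B,
                 epsilon = epsilon, beta_smooth = beta_smooth),
            class = "energy_params")
}

#' Local motif energy of a likelihood
#'
#' `-log(q + epsilon)`: zero (up to epsilon) at full confidence, finite at
#' q = 0 thanks to the epsilon floor.
#'
#' @param q Likelihood value(s) in `[0, 1]`.
#' @param epsilon Stability floor (default 1e-8).
#' @return Dimensionless energy, same shape as `q`.
#' @export
local_motif_energy <- function(q, epsilon = 1e-8) -log(q + epsilon)

#' Smooth maximum via LogSumExp
#'
#' `(1/beta) * log(sum(exp(beta * v)))`, satisfying
#' `max(v) <= smooth_max(v) <= max(v) + log(length(v))/beta`.
#'
#' @param v Numeric vector.
#' @param beta Sharpness (> 0).
#' @return Scalar smooth maximum.
#' @export
smooth_max <- function(v, beta) {
  m <- max(v)
  m + log(sum(exp(beta * (v - m)))) / beta
}

energy_result <- function(total, per_atom, forces = NULL) {
  structure(list(total = total, per_atom = per_atom, forces = forces),
            class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("<energy_result> total %.4f kJ/mol over %d atoms%s\n",
              x$total, length(x$per_atom),
              if (is.null(x$forces)) "" else " (with forces)"))
  invisible(x)
}

# Reference one-hot matrix from flexible input
as_reference_onehot <- function(ref, n_atoms) {
  Y <- if (inherits(ref, "ss8_labels")) one_hot(ref) else as.matrix(ref)
  if (ncol(Y) != 8L) stop("reference matrix must have 8 columns")
  if (nrow(Y) == n_atoms / 3L) Y <- triplicate(Y)
  if (nrow(Y) != n_atoms) stop("reference rows match neither n_res nor 3*n_res")
  if (any(abs(rowSums(Y) - 1) > 1e-6) || any(Y < 0))
    stop("reference must be one-hot / row-stochastic")
  Y
}

# Core: per-atom energies and (optionally) the coordinate gradient dE/dX
# (atom-matrix layout) from a function giving (per-atom energy, dE/dlogits).
# When forces are wanted, the standard energy modes take a one-call compiled
# path (forward + per-atom energy + backward fused, no cache allocation
# surviving the call) — important in the MD loop.
gnn_energy_core <- function(model, X, meta, per_atom_fn, forces) {
  mode <- attr(per_atom_fn, "cpp_mode")
  if (forces && use_compiled() && !is.null(mode)) {
    if (!all(is.finite(X))) stop("non-finite coordinates")
    ep <- attr(per_atom_fn, "ep")
    Y <- attr(per_atom_fn, "Y") %||% matrix(0, 1, 1)
    out <- cpp_energy_force(model$params, unclass(model$config), X,
                            meta$aa, meta$at, meta$res, meta$ca_rows,
                            mode, Y, ep$gamma * ep$k_B * ep$temperature,
                            ep$epsilon, ep$beta_smooth)
    return(list(total = out$total, per_atom = drop(out$per_atom), dX = out$dX))
  }
  fw <- schake_forward_core(model, X, meta, need_cache = forces)
  Q <- softmax_rows(fw$logits)
  pa <- per_atom_fn(Q)
  out <- list(total = sum(pa$e), per_atom = pa$e, dX = NULL)
  if (forces)
    out$dX <- schake_backward(model, fw$cache, pa$dlogits, wrt = "coords")$dX
  out
}

# Public driver: wraps the core, reshaping -dE/dX into the n_res x 3 x 3
# force array convention.
gnn_energy_driver <- function(model, s, ep, per_atom_fn, forces) {
  core <- gnn_energy_core(model, atom_matrix(s), atom_meta(s), per_atom_fn, forces)
  F <- if (forces) -aperm(array(core$dX, dim = c(3L, n_res(s), 3L)), c(2, 1, 3))
  energy_result(core$total, core$per_atom, F)
}

# Per-atom energy + dE/dlogits closures for the two energy modes
per_atom_os_fn <- function(Y, ep) {
  pref <- ep$gamma * ep$k_B * ep$temperature
  structure(function(Q) {
    qref <- rowSums(Q * Y)
    e <- pref * local_motif_energy(qref, ep$epsilon)
    dqref <- -pref / (qref + ep$epsilon)
    A <- dqref * Y * Q
    list(e = e, dlogits = A - Q * rowSums(A))
  }, cpp_mode = 0L, Y = Y, ep = ep)
}

per_atom_ms_fn <- function(ep, hard = FALSE) {
  pref <- ep$gamma * ep$k_B * ep$temperature
  beta <- ep$beta_smooth
  fn <- function(Q) {
    V <- log(Q + ep$epsilon)
    mx <- rowmax(V)
    if (hard) return(list(e = -pref * mx, dlogits = NULL))
    W <- exp(beta * (V - mx))
    sw <- rowSums(W)
    e <- -pref * (mx + log(sw) / beta)
    dv <- -pref * (W / sw)
    list(e = e, dlogits = dlogits_from_dv(Q, dv, ep$epsilon))
  }
  if (!hard) fn <- structure(fn, cpp_mode = 1L, ep = ep)
  fn
}

# softmax jacobian contraction: given dE/dv where v = log(Q + eps),
# return dE/dlogits. Q row-stochastic, dv same shape.
dlogits_from_dv <- function(Q, dv, epsilon) {
  A <- dv * Q / (Q + epsilon)       # dE/dv * dv/dq * q  (first term factor)
  A - Q * rowSums(A)
}

#' One-state GNN energy
#'
#' `E = -gamma * kB * T * sum_i log(q_i(ref_i) + eps)`: at each backbone atom
#' the likelihood the model assigns to the motif present in the reference
#' (folded) structure. Minimal when the model is fully confident in the
#' reference motifs everywhere, so the energy selectively stabilizes the
#' reference state.
#'
#' @param model A `schake_model`.
#' @param s A `backbone` (the configuration to evaluate).
#' @param ref Reference labels: an `ss8_labels` object, an `n_res x 8` or
#'   `3*n_res x 8` one-hot matrix.
#' @param ep An [energy_params()].
#' @param forces If `TRUE`, also compute exact forces `-dE/dx`
#'   (`n_res x 3 x 3` array, kJ/mol/nm, atom order N, CA, C).
#' @return An `energy_result` with `total` (kJ/mol), `per_atom` and
#'   optionally `forces`.
#' @export
energy_one_state <- function(model, s, ref, ep = energy_params(), forces = FALSE) {
  Y <- as_reference_onehot(ref, 3L * n_res(s))
  gnn_energy_driver(model, s, ep, per_atom_os_fn(Y, ep), forces)
}

#' Multi-state GNN energy
#'
#' `E = -gamma * kB * T * sum_i smooth_max_j log(q_i(j) + eps)`: rewards any
#' structurally plausible motif at each atom, without privileging a reference
#' state. The hard max is smoothly approximated by LogSumExp with sharpness
#' `beta_smooth`, keeping the energy differentiable.
#'
#' @inheritParams energy_one_state
#' @param hard If `TRUE`, use the exact (non-smooth) max instead of LogSumExp
#'   (no forces available in that mode).
#' @return An `energy_result`.
#' @export
energy_multi_state <- function(model, s, ep = energy_params(), forces = FALSE,
                               hard = FALSE) {
  if (hard && forces) stop("forces require the smooth (LogSumExp) max")
  gnn_energy_driver(model, s, ep, per_atom_ms_fn(ep, hard), forces)
}

#' Exact GNN forces for an energy mode
#'
#' Convenience wrapper returning the force array of [energy_one_state()] or
#' [energy_multi_state()].
#'
#' @param mode `"os"` or `"ms"`.
#' @param model A `schake_model`.
#' @param s A `backbone`.
#' @param ref Reference labels (required for `"os"`).
#' @param ep An [energy_params()].
#' @return `n_res x 3 x 3` force array (kJ/mol/nm).
#' @export
gnn_forces <- function(mode = c("os", "ms"), model, s, ref = NULL,
                       ep = energy_params()) {
  mode <- match.arg(mode)
  r <- if (mode == "os") energy_one_state(model, s, ref, ep, forces = TRUE)
       else energy_multi_state(model, s, ep, forces = TRUE)
  if (!all(is.finite(r$forces))) {
    bad <- which(!is.finite(apply(r$forces, 1, sum)))[1]
    stop("non-finite force at residue ", bad)
  }
  r$forces
}
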