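# Minimal Langevin MD engine: harmonic bonded surrogate (keeps the chain
# covalently intact at backbone resolution) plus the GNN likelihood energy,
# integrated with BAOAB splitting. Desk-scale analogue of long ML/MD
# stability runs. Units: nm, ps, kJ/mol, K; masses in amu
# (kJ/mol = amu nm^2 / ps^2, so the unit system is consistent).

#' Harmonic bonded terms for a backbone chain
#'
#' Bonds N-CA, CA-C and C-N(i+1) at the generator's ideal lengths with
#' spring constant `k_bond`; angles N-CA-C, CA-C-N(i+1) and C-N(i+1)-CA(i+1)
#' at ideal values with constant `k_angle`. A single chain of n residues has
#' 3n-1 bonds and 3n-2 angles.
#'
#' @param s A `backbone` (only its length is used).
#' @param k_bond Bond spring constant, kJ/mol/nm^2 (default 1e5).
#' @param k_angle Angle spring constant, kJ/mol/rad^2 (default 500).
#' @return A `bonded_terms` object with `bonds` (i, j, r0, k) and `angles`
#'   (i, j, k, theta0, ka) data.frames over atom indices.
#' @export
bonded_terms <- function(s, k_bond = 1e5, k_angle = 500) {
  n <- n_res(s)
  g <- IDEAL_GEOM
  at <- function(res, a) 3L * (res - 1L) + a  # atom index in storage order
  res <- seq_len(n)
  bonds <- rbind(
    data.frame(i = at(res, 1L), j = at(res, 2L), r0 = g$b_N_CA),
    data.frame(i = at(res, 2L), j = at(res, 3L), r0 = g$b_CA_C),
    if (n > 1L) data.frame(i = at(res[-n], 3L), j = at(res[-1L], 1L), r0 = g$b_C_N)
  )
  bonds$k <- k_bond
  angles <- rbind(
    data.frame(i = at(res, 1L), j = at(res, 2L), k = at(res, 3L), theta0 = g$a_N_CA_C),
    if (n > 1L) data.frame(i = at(res[-n], 2L), j = at(res[-n], 3L), k = at(res[-1L], 1L),
                           theta0 = g$a_CA_C_N),
    if (n > 1L) data.frame(i = at(res[-n], 3L), j = at(res[-1L], 1L), k = at(res[-1L], 2L),
                           theta0 = g$a_C_N_CA)
  )
  angles$theta0 <- angles$theta0 * pi / 180
  angles$ka <- k_angle
  bonds <- bonds[order(bonds$i, bonds$j), ]
  angles <- angles[order(angles$j, angles$i), ]
  structure(list(bonds = bonds, angles = angles), class = "bonded_terms")
}

#' Harmonic bonded energy and forces
#'
#' `E = sum k (r - r0)^2 + sum ka (theta - theta0)^2` with exact analytic
#' forces.
#'
#' @param s A `backbone`, or a `3*n_res x 3` atom matrix.
#' @param bt A [bonded_terms()] object.
#' @param forces If `TRUE`, return forces as an attribute-free matrix.
#' @return An `energy_result`; `forces` (when requested) is stored as a
#'   `3*n_res x 3` matrix in atom storage order.
#' @export
bonded_energy <- function(s, bt, forces = FALSE) {
  X <- if (inherits(s, "backbone")) atom_matrix(s) else s
  nb <- nrow(bt$bonds)
  vi <- X[bt$bonds$i, , drop = FALSE] - X[bt$bonds$j, , drop = FALSE]
  r <- row_norms(vi)
  dr <- r - bt$bonds$r0
  e_bond <- bt$bonds$k * dr^2
  F <- if (forces) matrix(0, nrow(X), 3) else NULL
  if (forces) {
    # dE/dxi = 2 k dr * u
    gb <- (2 * bt$bonds$k * dr / r) * vi
    F <- F - scatter_add(gb, bt$bonds$i, nrow(X)) + scatter_add(gb, bt$bonds$j, nrow(X))
  }
  A <- X[bt$angles$i, , drop = FALSE]
  B <- X[bt$angles$j, , drop = FALSE]
  C <- X[bt$angles$k, , drop = FALSE]
  u <- A - B; v <- C - B
  nu <- row_norms(u); nv <- row_norms(v)
  cth <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rowSums(u * v) / (nu * nv)))
  th <- acos(cth)
  dth <- th - bt$angles$theta0
  e_ang <- bt$angles$ka * dth^2
  if (forces) {
    sth <- sqrt(1 - cth^2)
    coef <- 2 * bt$angles$ka * dth       # dE/dtheta
    # dtheta/dA = (cth * u/nu - v/nv) / (nu * sth); symmetric for C
    dthA <- (cth * u / nu - v / nv) / (nu * sth)
    dthC <- (cth * v / nv - u / nu) / (nv * sth)
    gA <- coef * dthA; gC <- coef * dthC; gB <- -(gA + gC)
    F <- F - scatter_add(gA, bt$angles$i, nrow(X)) -
      scatter_add(gB, bt$angles$j, nrow(X)) -
      scatter_add(gC, bt$angles$k, nrow(X))
  }
  per_atom <- numeric(nrow(X))
  # attribute each term's energy to its central/first atom for reporting
  per_atom <- per_atom + drop(scatter_add(matrix(e_bond), bt$bonds$i, nrow(X)))
  per_atom <- per_atom + drop(scatter_add(matrix(e_ang), bt$angles$j, nrow(X)))
  res <- energy_result(sum(e_bond) + sum(e_ang), per_atom)
  res$forces <- F
  res
}

#' Simulation configuration
#'
#' @param n_steps Number of integration steps.
#' @param timestep Timestep in ps (default 0.002).
#' @param temperature Thermostat temperature in K (default 300).
#' @param friction Langevin friction in 1/ps (default 1.0).
#' @param seed Seed for the thermal noise stream.
#' @param potential_mode `"os"`, `"ms"` or `"bonded_only"`.
#' @param gamma GNN energy scaling (default 2.5).
#' @param report_every Record a frame every this many steps (default 100).
#' @param mass Pseudo-atom mass in amu (default 12, all backbone atoms).
#' @param beta_smooth LogSumExp sharpness for `"ms"` (default 16).
#' @param max_step_nm Abort threshold on per-step atom displacement (default 10).
#' @param auto_dt_retries On a NaN/displacement guard trip, restart the run
#'   with the timestep halved, at most this many times (default 2; 0 aborts
#'   immediately).
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_steps, timestep = 0.002, temperature = 300,
                       friction = 1.0, seed = 1L,
                       potential_mode = c("bonded_only", "os", "ms"),
                       gamma = 2.5, report_every = 100L, mass = 12,
                       beta_smooth = 16, max_step_nm = 10,
                       auto_dt_retries = 2L) {
  potential_mode <- match.arg(potential_mode)
  stopifnot(timestep > 0, n_steps >= 1L, friction >= 0, temperature >= 0)
  structure(list(n_steps = as.integer(n_steps), timestep = timestep,
                 temperature = temperature, friction = friction,
                 seed = as.integer(seed), potential_mode = potential_mode,
                 gamma = gamma, report_every = as.integer(report_every),
                 mass = mass, beta_smooth = beta_smooth,
                 max_step_nm = max_step_nm,
                 auto_dt_retries = as.integer(auto_dt_retries)),
            class = "sim_config")
}

# Total potential energy and forces (atom-matrix layout) for a configuration.
# `gnn_fn` is a prebuilt per-atom energy closure (NULL for bonded_only) and
# `meta` the cached atom metadata, so the MD loop avoids per-step rebuilds.
md_potential <- function(X, bt, model, gnn_fn, meta) {
  bonded <- bonded_energy(X, bt, forces = TRUE)
  e_gnn <- 0; f_gnn <- 0
  if (!is.null(gnn_fn)) {
    core <- gnn_energy_core(model, X, meta, gnn_fn, forces = TRUE)
    e_gnn <- core$total
    f_gnn <- -core$dX
  }
  list(E_total = bonded$total + e_gnn, E_gnn = e_gnn, E_bonded = bonded$total,
       F = bonded$forces + f_gnn)
}

# Build the per-atom GNN energy closure for a sim_config (NULL if bonded only)
md_gnn_fn <- function(sc, s0, ref, ep) {
  switch(sc$potential_mode,
         bonded_only = NULL,
         os = per_atom_os_fn(as_reference_onehot(ref, 3L * n_res(s0)), ep),
         ms = per_atom_ms_fn(ep))
}

#' Run Langevin dynamics under bonded + GNN potential
#'
#' BAOAB splitting: half kick, half drift, Ornstein-Uhlenbeck velocity
#' update, half drift, half kick. With `friction = 0` and `temperature = 0`
#' this reduces to velocity Verlet. Velocities start from the Maxwell
#' distribution at the thermostat temperature. The noise stream is seeded,
#' so trajectories are reproducible on a single thread.
#'
#' @param s0 Initial `backbone`.
#' @param sc A [sim_config()].
#' @param model A `schake_model` (required unless `potential_mode` is
#'   `"bonded_only"`).
#' @param ref Reference labels for the one-state potential (defaults to the
#'   DSSP assignment of `s0`).
#' @param bt Optional [bonded_terms()] (defaults to ideal-geometry terms).
#' @return A `trajectory`: list with `frames` (list of `backbone`, frame 0
#'   first) and `records` (data.frame: step, E_total, E_gnn, E_bonded,
#'   rmsd_nm, temp_K).
#' @export
run_md <- function(s0, sc, model = NULL, ref = NULL, bt = NULL) {
  if (sc$potential_mode != "bonded_only" && is.null(model))
    stop("model required for GNN potential modes")
  if (sc$potential_mode == "os" && is.null(ref)) ref <- assign_ss8(s0)
  if (is.null(bt)) bt <- bonded_terms(s0)
  ep <- energy_params(gamma = sc$gamma, temperature = max(sc$temperature, 1),
                      beta_smooth = sc$beta_smooth)
  dt <- sc$timestep
  for (attempt in 0:sc$auto_dt_retries) {
    out <- tryCatch(
      run_md_once(s0, sc, model, ref, bt, ep, dt),
      md_blowup = function(e) e
    )
    if (!inherits(out, "condition")) return(out)
    if (attempt == sc$auto_dt_retries)
      stop("dynamics unstable at step ", out$step,
           " even after timestep reduction to ", dt, " ps")
    dt <- dt / 2
    warning(sprintf("instability at step %d; retrying with timestep %g ps",
                    out$step, dt))
  }
}

run_md_once <- function(s0, sc, model, ref, bt, ep, dt) {
  X <- atom_matrix(s0)
  n_atoms <- nrow(X)
  kB <- 0.008314
  m <- sc$mass
  meta <- atom_meta(s0)
  gnn_fn <- md_gnn_fn(sc, s0, ref, ep)
  pot <- md_potential(X, bt, model, gnn_fn, meta)
  c1 <- exp(-sc$friction * dt)
  c2 <- sqrt(kB * sc$temperature / m * (1 - c1^2))
  blowup <- function(step) {
    cond <- structure(class = c("md_blowup", "condition"),
                      list(message = "blow-up", call = NULL, step = step))
    stop(cond)
  }
  V <- with_seed(sc$seed, {
    if (sc$temperature > 0)
      matrix(stats::rnorm(n_atoms * 3, sd = sqrt(kB * sc$temperature / m)), n_atoms, 3)
    else matrix(0, n_atoms, 3)
  })
  # pre-draw the thermal noise stream deterministically
  all_noise <- with_seed(sc$seed + 1L, {
    if (sc$temperature > 0) stats::rnorm(sc$n_steps * n_atoms * 3) else numeric(0)
  })
  frames <- list(s0)
  rec <- function(step, X, V, pot) {
    ke <- 0.5 * m * sum(V^2)
    data.frame(step = step, E_total = pot$E_total, E_gnn = pot$E_gnn,
               E_bonded = pot$E_bonded,
               rmsd_nm = kabsch_rmsd(atom_matrix(s0), X),
               temp_K = 2 * ke / (3 * n_atoms * kB))
  }
  records <- rec(0L, X, V, pot)
  for (step in seq_len(sc$n_steps)) {
    V <- V + 0.5 * dt * pot$F / m
    X_half <- X + 0.5 * dt * V
    if (sc$temperature > 0) {
      xi <- matrix(all_noise[((step - 1L) * n_atoms * 3 + 1L):(step * n_atoms * 3)],
                   n_atoms, 3)
      V <- c1 * V + c2 * xi
    } else if (sc$friction > 0) {
      V <- c1 * V
    }
    X_new <- X_half + 0.5 * dt * V
    if (!all(is.finite(X_new)) || max(abs(X_new - X)) > sc$max_step_nm) blowup(step)
    X <- X_new
    pot <- md_potential(X, bt, model, gnn_fn, meta)
    if (!all(is.finite(pot$F))) blowup(step)
    V <- V + 0.5 * dt * pot$F / m
    if (step %% sc$report_every == 0L || step == sc$n_steps) {
      frames[[length(frames) + 1L]] <- set_atom_matrix(s0, X)
      records <- rbind(records, rec(step, X, V, pot))
    }
  }
  structure(list(frames = frames, records = records, config = sc, timestep_used = dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %d steps, mode %s\n",
              length(x$frames), max(x$records$step), x$config$potential_mode))
  invisible(x)
}

#' Energy minimization by gradient descent with backtracking
#'
#' The overdamped zero-temperature limit: every accepted step strictly
#' decreases the potential energy.
#'
#' @param s0 Initial `backbone`.
#' @param sc A [sim_config()] (its `potential_mode`, `gamma` are used).
#' @param model,ref,bt As in [run_md()].
#' @param max_iter Maximum accepted steps.
#' @param step0 Initial step size along the force direction (nm per unit
#'   normalized force).
#' @return A `trajectory` whose records carry the accepted-step energies.
#' @export
minimize_energy <- function(s0, sc, model = NULL, ref = NULL, bt = NULL,
                            max_iter = 200L, step0 = 1e-4) {
  if (sc$potential_mode == "os" && is.null(ref)) ref <- assign_ss8(s0)
  if (is.null(bt)) bt <- bonded_terms(s0)
  ep <- energy_params(gamma = sc$gamma, temperature = max(sc$temperature, 1),
                      beta_smooth = sc$beta_smooth)
  X <- atom_matrix(s0)
  meta <- atom_meta(s0)
  gnn_fn <- md_gnn_fn(sc, s0, ref, ep)
  pot <- md_potential(X, bt, model, gnn_fn, meta)
  frames <- list(s0)
  records <- data.frame(step = 0L, E_total = pot$E_total, E_gnn = pot$E_gnn,
                        E_bonded = pot$E_bonded, rmsd_nm = 0, temp_K = 0)
  step <- step0
  for (it in seq_len(max_iter)) {
    fmax <- max(row_norms(pot$F))
    if (fmax < 1e-10) break
    dirn <- pot$F / fmax
    accepted <- FALSE
    for (try in 1:20) {
      X_new <- X + step * dirn
      pot_new <- md_potential(X_new, bt, model, gnn_fn, meta)
      if (is.finite(pot_new$E_total) && pot_new$E_total < pot$E_total) {
        accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted) break
    X <- X_new; pot <- pot_new
    step <- step * 1.5
    frames[[length(frames) + 1L]] <- set_atom_matrix(s0, X)
    records <- rbind(records, data.frame(
      step = it, E_total = pot$E_total, E_gnn = pot$E_gnn,
      E_bonded = pot$E_bonded, rmsd_nm = kabsch_rmsd(atom_matrix(s0), X),
      temp_K = 0))
  }
  structure(list(frames = frames, records = records, config = sc),
            class = "trajectory")
}

#' Per-frame energy/RMSD analysis of a trajectory or path
#'
#' Computes, for every frame, the RMSD to the native structure and the
#' one-state and multi-state GNN energies, plus the Pearson and Spearman
#' correlations of the one-state energy with RMSD across frames (the
#' energy-versus-unfoldedness trace).
#'
#' @param t A `trajectory`, a `perturbation_path`, or a list of `backbone`s.
#' @param native Reference `backbone` for RMSD.
#' @param ref Reference SS8 labels (defaults to DSSP of `native`).
#' @param model A `schake_model`.
#' @param ep An [energy_params()].
#' @return A data.frame (frame, rmsd_nm, E_os, E_ms) with attributes
#'   `pearson`, `spearman` (NA with a `constant` flag when a column has zero
#'   variance).
#' @export
analyze_trajectory <- function(t, native, ref = NULL, model,
                               ep = energy_params(gamma = 2.5)) {
  frames <- if (inherits(t, "trajectory") || inherits(t, "perturbation_path"))
    t$frames else t
  if (length(frames) == 0L) stop("empty trajectory")
  if (is.null(ref)) ref <- assign_ss8(native)
  rows <- lapply(seq_along(frames), function(k) {
    fr <- frames[[k]]
    data.frame(
      frame = k - 1L,
      rmsd_nm = kabsch_rmsd(native, fr),
      E_os = energy_one_state(model, fr, ref, ep)$total,
      E_ms = energy_multi_state(model, fr, ep)$total)
  })
  out <- do.call(rbind, rows)
  const <- stats::sd(out$rmsd_nm) == 0 || stats::sd(out$E_os) == 0
  attr(out, "pearson") <- if (const) NA_real_ else stats::cor(out$rmsd_nm, out$E_os)
  attr(out, "spearman") <- if (const) NA_real_ else
    stats::cor(out$rmsd_nm, out$E_os, method = "spearman")
  attr(out, "constant") <- const
  out
}

#' Write a trajectory as multi-model PDB text
#' @param t A `trajectory` (or list of backbones).
#' @return PDB text with one MODEL per frame.
#' @export
write_trajectory <- function(t) {
  frames <- if (inherits(t, "trajectory")) t$frames else t
  paste(vapply(seq_along(frames),
               function(k) write_backbone(frames[[k]], model_index = k),
               character(1)), collapse = "")
}
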