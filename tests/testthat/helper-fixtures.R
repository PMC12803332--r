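# Shared fixtures. Everything is generated in code; expensive artifacts (the
# trained desk model) are built once per test run and cached in this
# environment so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

# A small idealized helix
fix_helix <- function(len = 12, seed = 1) {
  make_protein(segment_spec("helix", len), seed = seed)$structure
}

# Mixed-fold structure used across tests
fix_mixed <- function(seed = 2) {
  make_protein(list(segment_spec("helix", 8), segment_spec("coil", 4),
                    segment_spec("strand", 5)), seed = seed)$structure
}

# Tiny untrained model (fast forward/backward; no training involved)
fix_small_model <- function(seed = 3) {
  init_model(model_config(n_rbf = 8, hidden_dim = 12, head_dims = c(12, 12),
                          seed = seed))
}

# Model whose parameters are all zero: logits are identically zero, so the
# predicted likelihoods are exactly uniform (1/8) — handy closed-form oracle.
fix_zero_model <- function() {
  m <- init_model(model_config(n_rbf = 4, hidden_dim = 8, head_dims = c(8, 8)))
  flat <- numeric(count_parameters(m))
  m$params <- utils::relist(flat, m$params)
  m
}

# The desk-scale experiment configuration: 80 mixed synthetic proteins, DSSP
# teacher, 30 epochs. Trained lazily, once per session. Width 48 puts the
# model at the ~45k-parameter scale.
desk_model_config <- function() model_config(hidden_dim = 48, head_dims = c(48, 48), seed = 1)

desk_training_config <- function() {
  training_config(epochs = 30, batch_size = 5, learning_rate = 3e-3, seed = 1,
                  val_fraction = 0.2)
}

desk_fit <- function() {
  if (is.null(.fixture_env$desk_fit)) {
    ds <- make_dataset(80, seed = 101)
    .fixture_env$desk_fit <- train(ds, desk_model_config(), desk_training_config())
  }
  .fixture_env$desk_fit
}

desk_heldout <- function() {
  if (is.null(.fixture_env$heldout)) .fixture_env$heldout <- make_dataset(20, seed = 202)
  .fixture_env$heldout
}

# A uniformly random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid motion to a backbone
rigid_move <- function(s, R = random_rotation(), t = stats::rnorm(3)) {
  m <- atom_matrix(s) %*% R
  m <- sweep(m, 2, t, "+")
  set_atom_matrix(s, m)
}

# Forces array -> atom-matrix layout
forces_as_matrix <- function(F) matrix(aperm(F, c(2, 1, 3)), nrow = dim(F)[1] * 3L)

# Reference DSSP via mdtraj (python), the independent oracle. Writes each
# structure (with reconstructed O atoms) as PDB, runs one python process for
# the whole batch, and returns per-structure label strings ('NA'/' ' -> C).
mdtraj_dssp <- function(structures) {
  dir <- tempfile("dssp_oracle_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  for (k in seq_along(structures)) {
    writeLines(write_backbone(structures[[k]], include_O = TRUE),
               file.path(dir, sprintf("s%03d.pdb", k)))
  }
  script <- file.path(dir, "run_dssp.py")
  writeLines(c(
    "import glob, os, sys",
    "import mdtraj as md",
    sprintf("d = %s", deparse(dir)),
    "for f in sorted(glob.glob(os.path.join(d, 's*.pdb'))):",
    "    t = md.load(f)",
    "    ss = md.compute_dssp(t, simplified=False)[0]",
    "    out = ''.join('C' if c in (' ', 'NA') else c for c in ss)",
    "    print(os.path.basename(f) + ',' + out)"
  ), script)
  out <- suppressWarnings(system2("python", script, stdout = TRUE, stderr = FALSE))
  if (length(out) != length(structures))
    stop("mdtraj oracle returned ", length(out), " records for ",
         length(structures), " structures")
  vapply(strsplit(out, ","), `[`, character(1), 2)
}

ss8_string <- function(labels) paste(ss8_letters(labels), collapse = "")

# Independent row-softmax (oracle-side, not the package's implementation)
softmax_rows_ref <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

vnorm <- function(v) sqrt(sum(v * v))
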