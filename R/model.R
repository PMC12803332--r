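# Backbone-only multiscale GNN ("student" of the distillation).
#
# Architecture: per-atom embeddings (amino-acid identity + backbone atom
# type, 16 dims each by default, Eq.-style concatenation) -> n_layers stacks
# of (short-range message passing over all backbone atoms within
# r_cut_short, with RBF-expanded distances, a cosine cutoff envelope and
# distance-based attention; long-range continuous-filter convolution over CA
# atoms only within r_cut_long, broadcast back to that residue's N and C
# atoms) -> a three-layer feedforward head producing 8 SS8 logits per atom.
# All features are invariant (distances only), so logits are exactly
# invariant to rigid motions; forces follow by reverse-mode differentiation.

#' Model hyperparameter configuration
#'
#' @param embed_dim_seq Amino-acid embedding width (default 16).
#' @param embed_dim_atom Backbone-atom-type embedding width (default 16).
#' @param r_cut_short Short-range cutoff over all backbone atoms, nm (default 1.0).
#' @param r_cut_long Long-range CA-only cutoff, nm (default 2.5).
#' @param n_rbf Number of Gaussian radial basis functions (default 32).
#' @param hidden_dim Hidden feature width (default 32).
#' @param n_layers Number of (short + long) message-passing stacks (default 2).
#' @param head_dims Widths of the two hidden head layers (default c(32, 32)).
#' @param seed Initialization seed.
#' @return A `model_config` object.
#' @export
model_config <- function(embed_dim_seq = 16L, embed_dim_atom = 16L,
                         r_cut_short = 1.0, r_cut_long = 2.5,
                         n_rbf = 32L, hidden_dim = 32L, n_layers = 2L,
                         head_dims = c(32L, 32L), seed = 1L) {
  stopifnot(r_cut_short > 0, r_cut_long >= r_cut_short,
            n_rbf >= 2L, hidden_dim >= 1L, n_layers >= 1L,
            length(head_dims) == 2L)
  structure(list(
    embed_dim_seq = as.integer(embed_dim_seq),
    embed_dim_atom = as.integer(embed_dim_atom),
    r_cut_short = r_cut_short, r_cut_long = r_cut_long,
    n_rbf = as.integer(n_rbf), hidden_dim = as.integer(hidden_dim),
    n_layers = as.integer(n_layers), head_dims = as.integer(head_dims),
    seed = as.integer(seed)
  ), class = "model_config")
}

glorot <- function(nout, nin) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -s, s), nout, nin)
}

conv_block_params <- function(h, n_rbf, attention) {
  p <- list(
    Wf1 = glorot(h, n_rbf), bf1 = numeric(h),
    Wf2 = glorot(h, h), bf2 = numeric(h),
    Wv = glorot(h, h), bv = numeric(h),
    Wo = glorot(h, h), bo = numeric(h)
  )
  if (attention) {
    p$att_w <- stats::rnorm(n_rbf, sd = 1 / sqrt(n_rbf))
    p$att_b <- 0
  }
  p
}

#' Initialize model parameters
#'
#' Deterministic given `config$seed`: Glorot-uniform weights, zero biases,
#' zero-initialized final head bias.
#'
#' @param config A [model_config()].
#' @return A `schake_model`: list with `config` and `params`.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  h <- config$hidden_dim
  params <- with_seed(config$seed, {
    p <- list(
      E_aa = matrix(stats::rnorm(20 * config$embed_dim_seq, sd = 1), 20, config$embed_dim_seq),
      E_at = matrix(stats::rnorm(3 * config$embed_dim_atom, sd = 1), 3, config$embed_dim_atom),
      W_in = glorot(h, config$embed_dim_seq + config$embed_dim_atom),
      b_in = numeric(h),
      short = vector("list", config$n_layers),
      long = vector("list", config$n_layers),
      head = list(
        W1 = glorot(config$head_dims[1], h), b1 = numeric(config$head_dims[1]),
        W2 = glorot(config$head_dims[2], config$head_dims[1]), b2 = numeric(config$head_dims[2]),
        W3 = glorot(8L, config$head_dims[2]), b3 = numeric(8L)
      )
    )
    for (l in seq_len(config$n_layers)) {
      p$short[[l]] <- conv_block_params(h, config$n_rbf, attention = TRUE)
      p$long[[l]] <- conv_block_params(h, config$n_rbf, attention = FALSE)
    }
    p
  })
  structure(list(config = config, params = params), class = "schake_model")
}

#' @export
print.schake_model <- function(x, ...) {
  cat(sprintf("<schake_model> %d parameters, hidden %d, %d layer stack(s), cutoffs %.2f/%.2f nm\n",
              count_parameters(x), x$config$hidden_dim, x$config$n_layers,
              x$config$r_cut_short, x$config$r_cut_long))
  invisible(x)
}

#' Count trainable parameters
#' @param model A `schake_model` (or its `params` list).
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  p <- if (inherits(model, "schake_model")) model$params else model
  length(unlist(p, use.names = FALSE))
}

# Flatten / restore parameter lists (order is deterministic)
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(flat, skeleton) {
  utils::relist(flat, skeleton = skeleton)
}

# Zero-valued copy of a parameter list
zero_like <- function(p) utils::relist(numeric(length(unlist(p, use.names = FALSE))), p)

# Per-atom metadata for a backbone: amino-acid index (1..20), atom-type index
# (1 N, 2 CA, 3 C), residue index per atom, CA atom rows.
atom_meta <- function(s) {
  n <- n_res(s)
  list(
    aa = rep(match(s$sequence, AA1), each = 3L),
    at = rep(1:3, n),
    res = rep(seq_len(n), each = 3L),
    ca_rows = seq(2L, 3L * n, by = 3L),
    n_atoms = 3L * n
  )
}

# Directed edge list within cutoff (both directions), excluding self-edges.
# X: n x 3 coordinates. Returns i, j, d, u (unit vectors x_i - x_j).
edge_list <- function(X, r_cut) {
  n <- nrow(X)
  if (n < 2L) return(list(i = integer(0), j = integer(0),
                          d = numeric(0), u = matrix(0, 0, 3)))
  d2 <- outer(rowSums(X^2), rep(1, n)) + outer(rep(1, n), rowSums(X^2)) -
    2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  dm <- sqrt(d2)
  sel <- which(dm <= r_cut & upper.tri(dm), arr.ind = TRUE)
  i <- c(sel[, 1], sel[, 2]); j <- c(sel[, 2], sel[, 1])
  d <- dm[cbind(i, j)]
  u <- (X[i, , drop = FALSE] - X[j, , drop = FALSE]) / d
  list(i = i, j = j, d = d, u = u)
}

# Gaussian RBF expansion with centers uniform on [0, r_cut]; sigma = spacing.
# D (the center-offset matrix) is kept for the gradient.
rbf_expand <- function(d, n_rbf, r_cut) {
  mu <- seq(0, r_cut, length.out = n_rbf)
  sigma <- mu[2] - mu[1]
  D <- outer(d, mu, "-")
  R <- exp(-D^2 / (2 * sigma^2))
  list(R = R, D = D, sigma = sigma)
}

# d/dd of the RBF rows (same shape as R)
rbf_grad <- function(rb) -rb$R * rb$D / rb$sigma^2

cutoff_env <- function(d, r_cut) 0.5 * (cos(pi * d / r_cut) + 1)
cutoff_env_grad <- function(d, r_cut) -0.5 * pi / r_cut * sin(pi * d / r_cut)

# One continuous-filter convolution block. Returns the additive output
# `O = ssp(M) %*% t(Wo) + bo` plus a cache for the backward pass.
conv_forward <- function(bp, H, edges, n_rbf, r_cut, attention) {
  n <- nrow(H)
  hdim <- ncol(H)
  if (length(edges$i) == 0L) {
    M <- matrix(0, n, hdim)
    U <- ssp(M)
    O <- addrow(U %*% t(bp$Wo), bp$bo)
    return(list(O = O, cache = list(empty = TRUE, H = H, M = M, U = U)))
  }
  rb <- rbf_expand(edges$d, n_rbf, r_cut)
  env <- cutoff_env(edges$d, r_cut)
  A1f <- addrow(rb$R %*% t(bp$Wf1), bp$bf1)
  F1 <- ssp(A1f)
  Wmat <- addrow(F1 %*% t(bp$Wf2), bp$bf2)
  V <- addrow(H %*% t(bp$Wv), bp$bv)
  Vj <- V[edges$j, , drop = FALSE]
  if (attention) {
    z <- drop(rb$R %*% bp$att_w) + bp$att_b
    att <- 1 / (1 + exp(-z))
    s_e <- env * att
  } else {
    z <- NULL; att <- NULL
    s_e <- env
  }
  msg <- s_e * (Wmat * Vj)
  M <- scatter_add(msg, edges$i, n)
  U <- ssp(M)
  O <- addrow(U %*% t(bp$Wo), bp$bo)
  list(O = O, cache = list(
    empty = FALSE, H = H, edges = edges, rb = rb, env = env, A1f = A1f,
    F1 = F1, Wmat = Wmat, V = V, Vj = Vj, z = z, att = att, s_e = s_e,
    M = M, U = U, attention = attention, r_cut = r_cut
  ))
}

# Backward through one conv block. dO: gradient on the block output.
# Returns dH (gradient on block input H), dX contributions per node
# (n x 3, distance-mediated), and dbp (parameter gradients).
conv_backward <- function(bp, cache, dO) {
  dbp <- list(
    Wf1 = matrix(0, nrow(bp$Wf1), ncol(bp$Wf1)), bf1 = numeric(length(bp$bf1)),
    Wf2 = matrix(0, nrow(bp$Wf2), ncol(bp$Wf2)), bf2 = numeric(length(bp$bf2)),
    Wv = matrix(0, nrow(bp$Wv), ncol(bp$Wv)), bv = numeric(length(bp$bv)),
    Wo = matrix(0, nrow(bp$Wo), ncol(bp$Wo)), bo = numeric(length(bp$bo))
  )
  if (cache$attention %||% FALSE) { dbp$att_w <- numeric(length(bp$att_w)); dbp$att_b <- 0 }
  n <- nrow(cache$H)
  dbp$Wo <- crossprod(dO, cache$U)
  dbp$bo <- colSums(dO)
  dU <- dO %*% bp$Wo
  dM <- dU * ssp_grad(cache$M)
  if (isTRUE(cache$empty)) {
    return(list(dH = matrix(0, n, ncol(cache$H)), dX = matrix(0, n, 3), dbp = dbp))
  }
  edges <- cache$edges
  dmsg <- dM[edges$i, , drop = FALSE]
  WV <- cache$Wmat * cache$Vj
  dWmat <- cache$s_e * dmsg * cache$Vj
  dVj <- cache$s_e * dmsg * cache$Wmat
  ds_e <- rowSums(dmsg * WV)
  dV <- scatter_add(dVj, edges$j, n)
  dH <- dV %*% bp$Wv
  dbp$Wv <- crossprod(dV, cache$H)
  dbp$bv <- colSums(dV)
  dF1 <- dWmat %*% bp$Wf2
  dbp$Wf2 <- crossprod(dWmat, cache$F1)
  dbp$bf2 <- colSums(dWmat)
  dA1f <- dF1 * ssp_grad(cache$A1f)
  dR <- dA1f %*% bp$Wf1
  dbp$Wf1 <- crossprod(dA1f, cache$rb$R)
  dbp$bf1 <- colSums(dA1f)
  if (cache$attention) {
    datt <- ds_e * cache$env
    denv <- ds_e * cache$att
    dz <- datt * cache$att * (1 - cache$att)
    dR <- dR + outer(dz, bp$att_w)
    dbp$att_w <- drop(crossprod(cache$rb$R, dz))
    dbp$att_b <- sum(dz)
  } else {
    denv <- ds_e
  }
  dd <- rowSums(dR * rbf_grad(cache$rb)) +
    denv * cutoff_env_grad(edges$d, cache$r_cut)
  dXe <- dd * edges$u
  dX <- scatter_add(dXe, edges$i, n) - scatter_add(dXe, edges$j, n)
  list(dH = dH, dX = dX, dbp = dbp)
}

# Full forward pass. Returns logits (3n x 8) and, if need_cache, everything
# required for the backward pass.
schake_forward <- function(model, s, need_cache = FALSE) {
  schake_forward_core(model, atom_matrix(s), atom_meta(s), need_cache)
}

# Whether to use the compiled (RcppArmadillo) network core. The pure-R
# reference path stays available for cross-checking.
use_compiled <- function() isTRUE(getOption("sspot.use_compiled", TRUE))

# Core forward on a bare atom matrix + precomputed metadata (fast path for
# the MD loop, where sequence/topology never change). Dispatches to the
# compiled kernel unless options(sspot.use_compiled = FALSE).
schake_forward_core <- function(model, X, meta, need_cache = FALSE) {
  if (use_compiled()) {
    if (!all(is.finite(X))) stop("non-finite coordinates")
    out <- cpp_schake_forward(model$params, unclass(model$config), X,
                              meta$aa, meta$at, meta$res, meta$ca_rows,
                              need_cache)
    if (need_cache) return(list(logits = out$logits,
                                cache = list(cpp = out$cache, meta = meta)))
    return(list(logits = out$logits))
  }
  schake_forward_core_r(model, X, meta, need_cache)
}

# Pure-R reference forward
schake_forward_core_r <- function(model, X, meta, need_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  if (!all(is.finite(X))) stop("non-finite coordinates")
  H0raw <- cbind(p$E_aa[meta$aa, , drop = FALSE], p$E_at[meta$at, , drop = FALSE])
  H <- addrow(H0raw %*% t(p$W_in), p$b_in)
  edges_s <- edge_list(X, cfg$r_cut_short)
  X_ca <- X[meta$ca_rows, , drop = FALSE]
  edges_l <- edge_list(X_ca, cfg$r_cut_long)
  layer_caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    cs <- conv_forward(p$short[[l]], H, edges_s, cfg$n_rbf, cfg$r_cut_short, attention = TRUE)
    H <- H + cs$O
    H_ca <- H[meta$ca_rows, , drop = FALSE]
    cl <- conv_forward(p$long[[l]], H_ca, edges_l, cfg$n_rbf, cfg$r_cut_long, attention = FALSE)
    ctx <- cl$O                      # n_res x hidden
    H <- H + ctx[meta$res, , drop = FALSE]
    layer_caches[[l]] <- list(short = cs$cache, long = cl$cache)
  }
  hd <- p$head
  A1 <- addrow(H %*% t(hd$W1), hd$b1); Z1 <- ssp(A1)
  A2 <- addrow(Z1 %*% t(hd$W2), hd$b2); Z2 <- ssp(A2)
  logits <- addrow(Z2 %*% t(hd$W3), hd$b3)
  if (!need_cache) return(list(logits = logits))
  list(logits = logits, cache = list(
    meta = meta, X = X, H0raw = H0raw, layers = layer_caches,
    A1 = A1, Z1 = Z1, A2 = A2, Z2 = Z2, H_final = H
  ))
}

# Reverse pass. dlogits: 3n x 8 upstream gradient. Returns dX (3n x 3) and,
# if wrt includes params, the parameter-gradient list (same shape as params).
schake_backward <- function(model, cache, dlogits, wrt = c("both", "coords", "params")) {
  wrt <- match.arg(wrt)
  if (!is.null(cache$cpp)) {
    out <- cpp_schake_backward(cache$cpp, dlogits,
                               wrt %in% c("both", "coords"),
                               wrt %in% c("both", "params"))
    return(list(dX = out$dX, dparams = out$dparams))
  }
  schake_backward_r(model, cache, dlogits, wrt)
}

# Pure-R reference backward
schake_backward_r <- function(model, cache, dlogits, wrt = c("both", "coords", "params")) {
  wrt <- match.arg(wrt)
  cfg <- model$config
  p <- model$params
  meta <- cache$meta
  hd <- p$head
  want_p <- wrt %in% c("both", "params")
  want_x <- wrt %in% c("both", "coords")
  dparams <- if (want_p) zero_like(p) else NULL
  dZ2 <- dlogits %*% hd$W3
  if (want_p) {
    dparams$head$W3 <- crossprod(dlogits, cache$Z2)
    dparams$head$b3 <- colSums(dlogits)
  }
  dA2 <- dZ2 * ssp_grad(cache$A2)
  dZ1 <- dA2 %*% hd$W2
  if (want_p) {
    dparams$head$W2 <- crossprod(dA2, cache$Z1)
    dparams$head$b2 <- colSums(dA2)
  }
  dA1 <- dZ1 * ssp_grad(cache$A1)
  dH <- dA1 %*% hd$W1
  if (want_p) {
    dparams$head$W1 <- crossprod(dA1, cache$H_final)
    dparams$head$b1 <- colSums(dA1)
  }
  dX <- matrix(0, meta$n_atoms, 3)
  for (l in rev(seq_len(cfg$n_layers))) {
    lc <- cache$layers[[l]]
    # long block: H_out = H_mid + broadcast(O_long(H_mid[ca]))
    dctx <- rowsum(dH, meta$res)                     # n_res x hidden
    bl <- conv_backward(p$long[[l]], lc$long, dctx)
    dH[meta$ca_rows, ] <- dH[meta$ca_rows, ] + bl$dH
    if (want_x) dX[meta$ca_rows, ] <- dX[meta$ca_rows, ] + bl$dX
    if (want_p) dparams$long[[l]] <- bl$dbp
    # short block: H_mid = H_in + O_short(H_in)
    bs <- conv_backward(p$short[[l]], lc$short, dH)
    dH <- dH + bs$dH
    if (want_x) dX <- dX + bs$dX
    if (want_p) dparams$short[[l]] <- bs$dbp
  }
  if (want_p) {
    dparams$W_in <- crossprod(dH, cache$H0raw)
    dparams$b_in <- colSums(dH)
    dH0raw <- dH %*% p$W_in
    ds <- cfg$embed_dim_seq
    dparams$E_aa <- scatter_add(dH0raw[, seq_len(ds), drop = FALSE], meta$aa, 20L)
    dparams$E_at <- scatter_add(dH0raw[, ds + seq_len(cfg$embed_dim_atom), drop = FALSE],
                                meta$at, 3L)
  }
  list(dX = if (want_x) dX else NULL, dparams = dparams)
}

#' Per-atom SS8 logits
#'
#' Runs the multiscale GNN on a backbone structure and returns the matrix of
#' SS8 pseudo-energies, one row per backbone atom in storage order (N, CA, C
#' per residue), one column per class (G, H, I, T, E, B, S, C).
#'
#' @param model A `schake_model`.
#' @param s A `backbone`.
#' @return A `3*n_res x 8` numeric matrix.
#' @export
forward_logits <- function(model, s) {
  out <- schake_forward(model, s, need_cache = FALSE)
  dimnames(out$logits) <- list(NULL, SS8_CLASSES)
  out$logits
}

#' Row-wise softmax likelihoods from logits
#'
#' @param S A logits matrix (rows = atoms, 8 columns).
#' @return A row-stochastic matrix of SS8 likelihoods.
#' @export
likelihoods <- function(S) {
  if (!all(is.finite(S))) stop("logits must be finite")
  Q <- softmax_rows(as.matrix(S))
  dimnames(Q) <- list(NULL, SS8_CLASSES)
  Q
}

#' Predict SS8 likelihoods for a structure
#' @param model A `schake_model`.
#' @param s A `backbone`.
#' @return A `3*n_res x 8` row-stochastic matrix.
#' @export
predict_ss8 <- function(model, s) likelihoods(forward_logits(model, s))

#' Save a model checkpoint (JSON: config + flattened parameters)
#' @param model A `schake_model`.
#' @param path Output file path.
#' @export
save_model <- function(model, path) {
  obj <- list(config = unclass(model$config),
              flat = flatten_params(model$params))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path Checkpoint path.
#' @return A `schake_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config)
  m <- init_model(cfg)
  m$params <- unflatten_params(as.numeric(obj$flat), m$params)
  m
}
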