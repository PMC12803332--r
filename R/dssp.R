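# Kabsch-Sander secondary-structure assignment (DSSP SS8), self-contained.
#
# Class order is fixed package-wide as (G, H, I, T, E, B, S, C), i.e.
# 3_10 helix, alpha helix, pi helix, hydrogen-bonded turn, beta sheet,
# beta bridge, bend, other. Indices are 0-based (0..7) to match the matrix
# column convention used by the model and energies.

#' SS8 class letters in canonical column order
#' @export
SS8_CLASSES <- c("G", "H", "I", "T", "E", "B", "S", "C")

#' Kabsch-Sander electrostatic hydrogen-bond energy
#'
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol with
#' distances in Angstrom; a hydrogen bond exists when E < -0.5 kcal/mol.
#' Inputs are in nm (package convention) and converted internally. Distances
#' below 0.05 nm clamp the energy to a large negative sentinel with a warning.
#'
#' @param donor List with `N` and `H` coordinates (nm) and optional
#'   `h_defined` flag.
#' @param acceptor List with `C` and `O` coordinates (nm) and optional
#'   `o_defined` flag.
#' @return Energy in kcal/mol, with attribute `bond` (logical). If the donor H
#'   or acceptor O is undefined the result is `NA` with `bond = FALSE`.
#' @export
hbond_energy <- function(donor, acceptor) {
  if (isFALSE(donor$h_defined) || isFALSE(acceptor$o_defined) ||
      anyNA(donor$H) || anyNA(acceptor$O))
    return(structure(NA_real_, bond = FALSE))
  r <- c(ON = vnorm(acceptor$O - donor$N), CH = vnorm(acceptor$C - donor$H),
         OH = vnorm(acceptor$O - donor$H), CN = vnorm(acceptor$C - donor$N))
  if (any(r < 0.05)) {
    warning("atoms closer than 0.05 nm in hbond_energy; clamping")
    return(structure(-9999, bond = TRUE))
  }
  r <- r * 10  # nm -> Angstrom
  e <- 0.084 * 332 * (1 / r["ON"] + 1 / r["CH"] - 1 / r["OH"] - 1 / r["CN"])
  structure(unname(e), bond = unname(e < -0.5))
}

# n x n logical matrix: hb[d, a] TRUE iff N-H of residue d donates to C=O of
# residue a (Kabsch-Sander energy < -0.5 kcal/mol). Vectorized.
hbond_matrix <- function(e) {
  n <- n_res(e)
  N <- e$coords[, 1, , drop = FALSE]; dim(N) <- c(n, 3)
  C <- e$coords[, 3, , drop = FALSE]; dim(C) <- c(n, 3)
  H <- e$H; O <- e$O
  dist2 <- function(A, B) {
    # rows of A vs rows of B -> n x n distance matrix (Angstrom)
    d2 <- outer(rowSums(A^2), rep(1, n)) + outer(rep(1, n), rowSums(B^2)) -
      2 * A %*% t(B)
    sqrt(pmax(d2, 0)) * 10
  }
  rON <- dist2(N, O); rCH <- dist2(H, C); rOH <- dist2(H, O); rCN <- dist2(N, C)
  E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  E[!e$h_defined, ] <- Inf
  E[, !e$o_defined] <- Inf
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  E[sep < 1L] <- Inf
  hb <- E < -0.5
  hb[is.na(hb)] <- FALSE
  hb
}

#' Assign DSSP SS8 classes from backbone geometry
#'
#' Implements the Kabsch-Sander decision rules on the reconstructed-H/O
#' backbone: n-turns (n = 3, 4, 5) from i -> i+n hydrogen bonds; two
#' consecutive n-turns give helices (G/H/I); parallel and antiparallel bridge
#' patterns give B, ladders of two or more consecutive bridges give E;
#' remaining turn residues give T; a bend S where the angle between
#' CA(i)-CA(i-2) and CA(i+2)-CA(i) exceeds 70 degrees; everything else C.
#' Overlaps resolve by the priority H > E > B > G > I > T > S.
#' Pi-helix detection uses the classic 5-turn rule (no modern pi-preference).
#'
#' @param e An `extended_backbone` from [reconstruct_O_H()], or a `backbone`
#'   (reconstructed automatically).
#' @return An `ss8_labels` object: integer vector of 0-based class indices
#'   with a `letters` attribute.
#' @export
assign_ss8 <- function(e) {
  if (!inherits(e, "extended_backbone")) e <- reconstruct_O_H(e)
  n <- n_res(e)
  if (n < 3L) return(ss8_labels(rep(7L, max(n, 0L))))
  hb <- hbond_matrix(e)
  # chain breaks sever turn/helix patterns spanning the break
  pb <- peptide_bond_lengths(e)
  broken_after <- which(pb > 0.25)  # break between residue k and k+1
  span_ok <- function(i, j) {  # no break strictly inside [i, j]
    if (length(broken_after) == 0L) return(TRUE)
    !any(broken_after >= i & broken_after < j)
  }
  turn <- list()
  for (m in 3:5) {
    t_m <- rep(FALSE, n)
    for (i in seq_len(n - m)) t_m[i] <- hb[i + m, i] && span_ok(i, i + m)
    turn[[as.character(m)]] <- t_m
  }
  flag <- list()
  for (cl in SS8_CLASSES) flag[[cl]] <- rep(FALSE, n)
  # helices: two consecutive n-turns starting at i-1 and i
  mark_helix <- function(t_m, m, cl) {
    if (n - m < 2L) return(invisible())
    for (i in 2:(n - m)) if (t_m[i - 1L] && t_m[i])
      flag[[cl]][i:(i + m - 1L)] <<- TRUE
  }
  mark_helix(turn[["4"]], 4L, "H")
  mark_helix(turn[["3"]], 3L, "G")
  mark_helix(turn[["5"]], 5L, "I")
  # bridges: Kabsch-Sander parallel/antiparallel patterns, |i-j| >= 3
  hbond <- function(i, j) {  # KS convention: CO(i) accepts from NH(j)
    if (i < 1L || j < 1L || i > n || j > n) return(FALSE)
    hb[j, i]
  }
  bridge <- matrix(0L, n, n)  # 1 parallel, 2 antiparallel
  for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      if (abs(i - j) < 3L) next
      par <- (hbond(i - 1L, j) && hbond(j, i + 1L)) ||
             (hbond(j - 1L, i) && hbond(i, j + 1L))
      anti <- (hbond(i, j) && hbond(j, i)) ||
              (hbond(i - 1L, j + 1L) && hbond(j - 1L, i + 1L))
      if (par) bridge[i, j] <- 1L else if (anti) bridge[i, j] <- 2L
    }
  }
  has_bridge <- rowSums(bridge > 0L) > 0L
  in_ladder <- rep(FALSE, n)
  for (i in seq_len(n)) {
    js <- which(bridge[i, ] > 0L)
    for (j in js) {
      ty <- bridge[i, j]
      nxt <- if (ty == 1L) c(j + 1L, j - 1L) else c(j - 1L, j + 1L)
      # ladder: bridge (i, j) extended by (i+1, j+-1) of the same type
      if (i < n && nxt[1] >= 1L && nxt[1] <= n && bridge[i + 1L, nxt[1]] == ty) {
        in_ladder[c(i, i + 1L, j, nxt[1])] <- TRUE
      }
    }
  }
  flag[["E"]] <- in_ladder
  flag[["B"]] <- has_bridge & !in_ladder
  # hydrogen-bonded turns: residues strictly inside an n-turn
  for (m in 3:5) {
    t_m <- turn[[as.character(m)]]
    for (i in which(t_m)) flag[["T"]][(i + 1L):(i + m - 1L)] <- TRUE
  }
  # bend: CA virtual-bond angle at i using i-2 and i+2
  for (i in seq_len(max(n - 4L, 0L)) + 2L) {
    u <- e$coords[i, 2, ] - e$coords[i - 2L, 2, ]
    v <- e$coords[i + 2L, 2, ] - e$coords[i, 2, ]
    ang <- acos(pmin(1, pmax(-1, sum(u * v) / (vnorm(u) * vnorm(v))))) * 180 / pi
    if (ang > 70) flag[["S"]][i] <- TRUE
  }
  priority <- c("H", "E", "B", "G", "I", "T", "S")
  lab <- rep(7L, n)  # C
  for (cl in rev(priority)) lab[flag[[cl]]] <- match(cl, SS8_CLASSES) - 1L
  ss8_labels(lab)
}

#' Construct SS8 labels
#' @param idx Integer vector of 0-based class indices (0..7).
#' @return An `ss8_labels` object.
#' @export
ss8_labels <- function(idx) {
  idx <- as.integer(idx)
  if (any(idx < 0L | idx > 7L)) stop("class indices must be in 0..7")
  structure(idx, letters = SS8_CLASSES[idx + 1L], class = "ss8_labels")
}

#' @export
print.ss8_labels <- function(x, ...) {
  cat("<ss8_labels>", paste(attr(x, "letters"), collapse = ""), "\n")
  invisible(x)
}

#' Letters of an SS8 label vector
#' @param labels An `ss8_labels` object.
#' @return Character vector of class letters.
#' @export
ss8_letters <- function(labels) SS8_CLASSES[as.integer(labels) + 1L]

#' Triplicate a residue-level SS8 matrix to atom rows
#'
#' Copies each residue row to its three backbone atoms (N, CA, C) in atom
#' storage order, so an `n_res x 8` matrix becomes `3*n_res x 8`.
#'
#' @param residue_matrix Numeric `n_res x 8` row-stochastic (or one-hot) matrix.
#' @return A `3*n_res x 8` matrix with columns named G,H,I,T,E,B,S,C.
#' @export
triplicate <- function(residue_matrix) {
  residue_matrix <- as.matrix(residue_matrix)
  if (ncol(residue_matrix) != 8L) stop("expected 8 columns")
  out <- residue_matrix[rep(seq_len(nrow(residue_matrix)), each = 3L), , drop = FALSE]
  dimnames(out) <- list(NULL, SS8_CLASSES)
  out
}

#' One-hot SS8 matrix (triplicated) from labels
#'
#' @param labels An `ss8_labels` object (or 0-based integer vector).
#' @return A `3*n_res x 8` one-hot matrix, one 1 per row at the class index.
#' @export
one_hot <- function(labels) {
  idx <- as.integer(labels)
  m <- matrix(0, length(idx), 8L)
  m[cbind(seq_along(idx), idx + 1L)] <- 1
  triplicate(m)
}
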