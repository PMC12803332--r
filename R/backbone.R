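# Backbone-only protein structures: PDB I/O and geometric utilities.
#
# Internal unit system: lengths in nm (PDB I/O converts Angstrom <-> nm),
# energies in kJ/mol, temperatures in K. Atom storage order within a residue
# is (N, CA, C), matching PDB record order; all per-atom matrices in the
# package (SS8 matrices, logits, forces) follow this order, so a structure
# with n residues maps to 3*n atom rows.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

aa_three_to_one <- function(x) AA1[match(toupper(x), AA3)]
aa_one_to_three <- function(x) AA3[match(toupper(x), AA1)]

# Ideal backbone internal coordinates (nm, degrees) used by the chain builder,
# the O/H reconstruction and the bonded surrogate potential.
IDEAL_GEOM <- list(
  b_N_CA  = 0.1458, b_CA_C  = 0.1523, b_C_N   = 0.1329,
  a_N_CA_C = 111.2, a_CA_C_N = 116.6, a_C_N_CA = 121.9,
  b_C_O = 0.123, b_N_H = 0.100, omega = 180
)

#' Construct a backbone structure
#'
#' A `backbone` holds the protein backbone at (N, CA, C) resolution: the
#' one-letter sequence and an `n_res x 3 x 3` Cartesian coordinate array in
#' nanometres, with the second dimension fixed in the order N, CA, C.
#'
#' @param sequence Character vector of one-letter amino-acid codes.
#' @param coords Numeric array of dimension `c(n_res, 3, 3)` in nm.
#' @param chain_id Single chain label.
#' @param validate If `TRUE`, warn when consecutive C(i)-N(i+1) peptide-bond
#'   distances fall outside the chemically plausible window (0.10, 0.20) nm.
#' @return An object of class `backbone`.
#' @export
backbone <- function(sequence, coords, chain_id = "A", validate = FALSE) {
  sequence <- as.character(sequence)
  n <- length(sequence)
  if (n < 1L) stop("a backbone needs at least 1 residue")
  if (n < 2L && validate) warning("single-residue chain: most geometry is undefined")
  if (!is.array(coords) || !identical(dim(coords), c(n, 3L, 3L)))
    stop("coords must be an array of dimension c(n_res, 3, 3)")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (anyNA(match(sequence, AA1))) stop("sequence contains non-standard codes")
  s <- structure(
    list(sequence = sequence, coords = coords, chain_id = as.character(chain_id)[1]),
    class = "backbone"
  )
  if (validate) {
    d <- peptide_bond_lengths(s)
    bad <- which(d < 0.10 | d > 0.20)
    if (length(bad))
      warning(sprintf("%d C(i)-N(i+1) distance(s) outside [0.10, 0.20] nm (first at residue %d)",
                      length(bad), bad[1]))
  }
  s
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %d residues, chain %s\n", n_res(x), x$chain_id))
  cat("  sequence:", paste(x$sequence, collapse = ""), "\n")
  invisible(x)
}

#' Number of residues in a backbone
#' @param s A `backbone`.
#' @return Integer residue count.
#' @export
n_res <- function(s) length(s$sequence)

# Distances C(i) -> N(i+1), length n-1
peptide_bond_lengths <- function(s) {
  n <- n_res(s)
  cc <- s$coords[-n, 3, , drop = FALSE]
  nn <- s$coords[-1, 1, , drop = FALSE]
  sqrt(rowSums((matrix(cc, n - 1L, 3L) - matrix(nn, n - 1L, 3L))^2))
}

#' Flatten backbone coordinates to an atom matrix
#'
#' Rows follow atom storage order: residue 1 N, CA, C, residue 2 N, CA, C, ...
#'
#' @param s A `backbone`.
#' @return A `(3 * n_res) x 3` numeric matrix in nm.
#' @export
atom_matrix <- function(s) {
  n <- n_res(s)
  m <- matrix(aperm(s$coords, c(2, 1, 3)), nrow = 3L * n, ncol = 3L)
  m
}

#' Rebuild a backbone from an atom matrix
#' @param s Template `backbone` (sequence and chain are kept).
#' @param m A `(3 * n_res) x 3` matrix in nm.
#' @return A `backbone` with replaced coordinates.
#' @export
set_atom_matrix <- function(s, m) {
  n <- n_res(s)
  stopifnot(nrow(m) == 3L * n, ncol(m) == 3L)
  s$coords <- aperm(array(m, dim = c(3L, n, 3L)), c(2, 1, 3))
  s
}

#' Read a backbone structure from PDB text
#'
#' Parses ATOM records (via bio3d), keeps the first model, optionally filters
#' to one chain, and retains only standard amino-acid residues possessing all
#' three of N, CA and C; incomplete residues are dropped with a warning.
#' Non-standard residues and capping groups (ACE, NME, ...) are excluded.
#' Coordinates are converted from Angstrom to nm.
#'
#' @param pdb_text PDB-format text (single string or character vector of lines).
#' @param chain Optional chain identifier to select.
#' @return A `backbone`.
#' @export
read_backbone <- function(pdb_text, chain = NULL) {
  pdb <- parse_pdb_text(pdb_text)
  build_backbone_from_atoms(pdb$atom, chain = chain)
}

parse_pdb_text <- function(pdb_text) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(paste(pdb_text, collapse = "\n"), tf)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tf, verbose = FALSE)),
    error = function(e) stop("malformed PDB input: ", conditionMessage(e))
  )
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L) stop("malformed PDB input: no ATOM records")
  pdb
}

build_backbone_from_atoms <- function(atoms, chain = NULL) {
  atoms <- atoms[atoms$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!is.null(chain)) {
    if (!chain %in% atoms$chain) stop(sprintf("chain '%s' not present", chain))
    atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  }
  std <- toupper(atoms$resid) %in% AA3
  atoms <- atoms[std, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no standard amino-acid residues found")
  key <- paste(atoms$chain, atoms$resno, atoms$insert %||% "")
  keys <- unique(key)
  seqs <- character(0)
  rows <- list()
  dropped <- 0L
  for (k in keys) {
    sub <- atoms[key == k, , drop = FALSE]
    idx <- match(c("N", "CA", "C"), sub$elety)
    if (anyNA(idx)) { dropped <- dropped + 1L; next }
    sub <- sub[idx, , drop = FALSE]
    seqs <- c(seqs, aa_three_to_one(sub$resid[1]))
    rows[[length(rows) + 1L]] <- cbind(sub$x, sub$y, sub$z)
  }
  if (dropped > 0L)
    warning(sprintf("dropped %d residue(s) missing one of N/CA/C", dropped))
  if (length(rows) == 0L) stop("no complete backbone residues after filtering")
  if (length(rows) < 2L) stop("fewer than 2 complete residues")
  n <- length(rows)
  coords <- array(0, dim = c(n, 3L, 3L))
  for (i in seq_len(n)) coords[i, , ] <- rows[[i]] / 10  # Angstrom -> nm
  ch <- if (!is.null(chain)) chain else atoms$chain[1]
  backbone(seqs, coords, chain_id = ch)
}

#' Write a backbone structure as PDB text
#'
#' @param s A `backbone`.
#' @param model_index Optional integer; if given, the ATOM block is wrapped in
#'   `MODEL`/`ENDMDL` records (multi-model trajectory framing).
#' @param include_O If `TRUE`, also write carbonyl O atoms (reconstructed via
#'   [reconstruct_O_H()]; the C-terminal O is placed in the N-CA-C plane).
#'   Useful for downstream tools whose DSSP needs O records.
#' @return A single string of PDB-format text (coordinates in Angstrom,
#'   `%8.3f`, so round-trips are exact to 1e-4 nm).
#' @export
write_backbone <- function(s, model_index = NULL, include_O = FALSE) {
  n <- n_res(s)
  O <- NULL
  if (include_O) {
    e <- if (inherits(s, "extended_backbone")) s else reconstruct_O_H(s)
    O <- e$O
    if (!e$o_defined[n]) {
      ca <- s$coords[n, 2, ]; cc <- s$coords[n, 3, ]; nn <- s$coords[n, 1, ]
      O[n, ] <- cc + IDEAL_GEOM$b_C_O * unit(unit(cc - ca) + unit(cc - nn))
    }
  }
  names3 <- c(" N  ", " CA ", " C  ", " O  ")
  elems <- c("N", "C", "C", "O")
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n)) {
    res3 <- aa_one_to_three(s$sequence[i])
    for (a in seq_len(if (include_O) 4L else 3L)) {
      serial <- serial + 1L
      xyz <- if (a == 4L) O[i, ] * 10 else s$coords[i, a, ] * 10  # nm -> Angstrom
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, names3[a], res3, substr(s$chain_id, 1, 1), i,
        xyz[1], xyz[2], xyz[3], 1, 0, elems[a]))
    }
  }
  body <- c(lines, "TER")
  if (!is.null(model_index))
    body <- c(sprintf("MODEL %8d", as.integer(model_index)), body, "ENDMDL")
  paste(c(body, "END", ""), collapse = "\n")
}

#' Read a multi-model PDB as a list of backbones
#' @param pdb_text Multi-model PDB text.
#' @param chain Optional chain filter.
#' @return A list of `backbone` objects, one per MODEL.
#' @export
read_backbone_models <- function(pdb_text, chain = NULL) {
  txt <- unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n"))
  starts <- grep("^MODEL", txt)
  if (length(starts) == 0L) return(list(read_backbone(txt, chain = chain)))
  ends <- grep("^ENDMDL", txt)
  if (length(ends) != length(starts)) stop("malformed multi-model PDB")
  lapply(seq_along(starts), function(k) {
    read_backbone(c(txt[(starts[k] + 1L):(ends[k] - 1L)], "END"), chain = chain)
  })
}

#' Reconstruct carbonyl O and amide H positions from the backbone
#'
#' Places O(i) in the peptide plane of CA(i), C(i), N(i+1), at 0.123 nm from
#' C(i) along the outward bisector of the C-CA and C-N(i+1) directions, and
#' H(i) on N(i) at 0.100 nm along the outward bisector of the N-CA and
#' N-C(i-1) directions (ideal trans-peptide geometry). The last residue's O,
#' the first residue's H, and proline H are flagged undefined.
#'
#' @param s A `backbone` with at least 2 residues.
#' @return An `extended_backbone`: the input plus `O`, `H` (`n_res x 3`
#'   matrices, NA rows where undefined) and logical flags `o_defined`,
#'   `h_defined`.
#' @export
reconstruct_O_H <- function(s) {
  n <- n_res(s)
  if (n < 2L) stop("need at least 2 residues to reconstruct O/H")
  O <- matrix(NA_real_, n, 3)
  H <- matrix(NA_real_, n, 3)
  o_def <- rep(FALSE, n)
  h_def <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) {
    ca <- s$coords[i, 2, ]; cc <- s$coords[i, 3, ]; nn <- s$coords[i + 1L, 1, ]
    dir <- unit(unit(cc - ca) + unit(cc - nn))
    O[i, ] <- cc + IDEAL_GEOM$b_C_O * dir
    o_def[i] <- TRUE
  }
  for (i in 2:n) {
    if (s$sequence[i] == "P") next
    nn <- s$coords[i, 1, ]; ca <- s$coords[i, 2, ]; cprev <- s$coords[i - 1L, 3, ]
    dir <- -(unit(ca - nn) + unit(cprev - nn))
    H[i, ] <- nn + IDEAL_GEOM$b_N_H * unit(dir)
    h_def[i] <- TRUE
  }
  structure(c(unclass(s), list(O = O, H = H, o_defined = o_def, h_defined = h_def)),
            class = c("extended_backbone", "backbone"))
}

#' Minimum RMSD under optimal rigid superposition (Kabsch)
#'
#' Superposes `b` onto `a` by the closed-form SVD solution (proper rotation,
#' reflections excluded) and returns the residual root-mean-square deviation.
#'
#' @param a,b `backbone` objects with equal residue counts.
#' @param atom_mask Optional logical mask, either per atom (length `3*n_res`)
#'   or per residue (length `n_res`, expanded to all three atoms): only masked
#'   atoms enter the fit and the RMSD.
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(a, b, atom_mask = NULL) {
  P <- if (inherits(a, "backbone")) atom_matrix(a) else a
  Q <- if (inherits(b, "backbone")) atom_matrix(b) else b
  if (!identical(dim(P), dim(Q))) stop("structures have different atom counts")
  if (!is.null(atom_mask)) {
    if (length(atom_mask) * 3L == nrow(P)) atom_mask <- rep(atom_mask, each = 3L)
    if (length(atom_mask) != nrow(P)) stop("atom_mask has wrong length")
    P <- P[atom_mask, , drop = FALSE]
    Q <- Q[atom_mask, , drop = FALSE]
  }
  if (nrow(P) < 3L) stop("need at least 3 atoms for superposition")
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  sv <- svd(crossprod(Q, P))  # 3x3
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diff <- P - Q %*% t(R)
  sqrt(mean(rowSums(diff^2)))
}

# Dihedral angle (degrees, in (-180, 180]) of points p1-p2-p3-p4
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3], b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3], b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3], n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / vnorm(b2)
  -atan2(y, x) * 180 / pi  # IUPAC sign: clockwise positive viewed from p2 to p3
}

#' Backbone dihedral angles
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#' phi of the first residue and psi of the last are undefined (NA).
#'
#' @param s A `backbone`.
#' @return A data.frame with columns `residue`, `phi`, `psi` (degrees).
#' @export
backbone_dihedrals <- function(s) {
  n <- n_res(s)
  if (n < 2L) stop("need at least 2 residues")
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L)
      phi[i] <- dihedral_angle(s$coords[i - 1L, 3, ], s$coords[i, 1, ],
                               s$coords[i, 2, ], s$coords[i, 3, ])
    if (i < n)
      psi[i] <- dihedral_angle(s$coords[i, 1, ], s$coords[i, 2, ],
                               s$coords[i, 3, ], s$coords[i + 1L, 1, ])
  }
  data.frame(residue = seq_len(n), phi = phi, psi = psi)
}
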