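# Idealized backbone generator: chains grown from internal coordinates with
# known secondary-structure content, plus controlled dihedral-noise
# perturbation paths. Stands in, at desk scale, for curated folded-structure
# datasets and unfolding trajectories.

# Place point D given chain A-B-C, bond |C-D| = r, angle B-C-D = theta (deg),
# torsion A-B-C-D = chi (deg). Standard NeRF internal-coordinate placement.
nerf_place <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  d_local <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  bc <- unit(C - B)
  ab <- B - A
  nvec <- c(ab[2] * bc[3] - ab[3] * bc[2],
            ab[3] * bc[1] - ab[1] * bc[3],
            ab[1] * bc[2] - ab[2] * bc[1])
  nvec <- unit(nvec)
  m2 <- c(nvec[2] * bc[3] - nvec[3] * bc[2],
          nvec[3] * bc[1] - nvec[1] * bc[3],
          nvec[1] * bc[2] - nvec[2] * bc[1])
  C + d_local[1] * bc + d_local[2] * m2 + d_local[3] * nvec
}

#' Build a backbone from per-residue dihedral angles
#'
#' Grows the chain by sequential internal-coordinate placement using ideal
#' bond lengths (N-CA 0.1458, CA-C 0.1523, C-N 0.1329 nm), ideal angles
#' (N-CA-C 111.2, CA-C-N 116.6, C-N-CA 121.9 degrees) and a fixed trans
#' peptide bond (omega = 180). `backbone_dihedrals()` round-trips the inputs.
#'
#' @param sequence One-letter amino-acid codes.
#' @param phi,psi Numeric vectors of dihedrals in degrees, same length as
#'   `sequence`. `phi[1]` and `psi[n]` are unused (may be NA).
#' @param chain_id Chain label.
#' @return A `backbone`.
#' @export
build_from_dihedrals <- function(sequence, phi, psi, chain_id = "A") {
  n <- length(sequence)
  if (length(phi) != n || length(psi) != n)
    stop("sequence, phi and psi must have equal length")
  g <- IDEAL_GEOM
  coords <- array(0, dim = c(n, 3L, 3L))
  a_ncac <- g$a_N_CA_C * pi / 180
  coords[1, 1, ] <- c(0, 0, 0)
  coords[1, 2, ] <- c(g$b_N_CA, 0, 0)
  coords[1, 3, ] <- coords[1, 2, ] +
    g$b_CA_C * c(-cos(a_ncac), sin(a_ncac), 0)
  if (n >= 2L) {
    for (i in 2:n) {
      coords[i, 1, ] <- nerf_place(coords[i - 1L, 1, ], coords[i - 1L, 2, ], coords[i - 1L, 3, ],
                                   g$b_C_N, g$a_CA_C_N, psi[i - 1L])
      coords[i, 2, ] <- nerf_place(coords[i - 1L, 2, ], coords[i - 1L, 3, ], coords[i, 1, ],
                                   g$b_N_CA, g$a_C_N_CA, g$omega)
      coords[i, 3, ] <- nerf_place(coords[i - 1L, 3, ], coords[i, 1, ], coords[i, 2, ],
                                   g$b_CA_C, g$a_N_CA_C, phi[i])
    }
  }
  backbone(sequence, coords, chain_id = chain_id)
}

# Canonical ideal dihedrals per motif
MOTIF_DIHEDRALS <- list(
  helix  = c(phi = -57, psi = -47),
  strand = c(phi = -139, psi = 135)
)

#' Specify a secondary-structure segment
#'
#' @param motif One of `"helix"`, `"strand"`, `"coil"`, `"hairpin"`.
#'   A hairpin is two antiparallel strands joined by a 4-residue turn.
#' @param length Residue count (hairpin: total including the turn; >= 10).
#' @param sequence Optional explicit codes (default poly-alanine).
#' @return A `segment_spec`.
#' @export
segment_spec <- function(motif = c("helix", "strand", "coil", "hairpin"),
                         length, sequence = NULL) {
  motif <- match.arg(motif)
  length <- as.integer(length)
  if (length < 1L) stop("segment length must be >= 1")
  if (motif == "hairpin" && length < 10L) stop("hairpin segments need length >= 10")
  if (!is.null(sequence) && base::length(sequence) != length)
    stop("sequence length must match segment length")
  structure(list(motif = motif, length = length, sequence = sequence),
            class = "segment_spec")
}

# Turn dihedrals that close an antiparallel beta hairpin (type I'-like)
HAIRPIN_TURN <- matrix(c(55, 40, 78, 6, -100, 130, -139, 135),
                       ncol = 2, byrow = TRUE, dimnames = list(NULL, c("phi", "psi")))

#' Generate an idealized protein from segment specifications
#'
#' Helix segments use (phi, psi) = (-57, -47); strand segments (-139, 135);
#' coil segments draw dihedrals uniformly from phi in [-180, -40], psi in
#' [-60, 180]; hairpin segments place two antiparallel strands around a
#' 4-residue turn so inter-strand hydrogen bonds form. Returns the intended
#' per-residue motif labels (H, E or C) for comparison with DSSP assignments.
#'
#' @param segments A list of [segment_spec()] objects (a single spec is
#'   accepted), total length >= 4.
#' @param seed Integer seed controlling coil dihedral draws.
#' @return A list with elements `structure` (a `backbone`) and `labels`
#'   (character vector of intended motifs, one of H/E/C per residue).
#' @export
make_protein <- function(segments, seed = 1L) {
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  total <- sum(vapply(segments, function(x) x$length, integer(1)))
  if (total < 4L) stop("total length must be >= 4")
  phi <- numeric(0); psi <- numeric(0); seqs <- character(0); labels <- character(0)
  draws <- with_seed(seed, {
    lapply(segments, function(sp) {
      if (sp$motif == "coil")
        cbind(phi = stats::runif(sp$length, -180, -40),
              psi = stats::runif(sp$length, -60, 180))
      else NULL
    })
  })
  for (k in seq_along(segments)) {
    sp <- segments[[k]]
    sq <- sp$sequence %||% rep("A", sp$length)
    seqs <- c(seqs, sq)
    if (sp$motif == "helix") {
      phi <- c(phi, rep(MOTIF_DIHEDRALS$helix["phi"], sp$length))
      psi <- c(psi, rep(MOTIF_DIHEDRALS$helix["psi"], sp$length))
      labels <- c(labels, rep("H", sp$length))
    } else if (sp$motif == "strand") {
      phi <- c(phi, rep(MOTIF_DIHEDRALS$strand["phi"], sp$length))
      psi <- c(psi, rep(MOTIF_DIHEDRALS$strand["psi"], sp$length))
      labels <- c(labels, rep("E", sp$length))
    } else if (sp$motif == "coil") {
      phi <- c(phi, draws[[k]][, "phi"])
      psi <- c(psi, draws[[k]][, "psi"])
      labels <- c(labels, rep("C", sp$length))
    } else {  # hairpin
      n_turn <- 4L
      n_s1 <- (sp$length - n_turn) %/% 2L
      n_s2 <- sp$length - n_turn - n_s1
      sphi <- MOTIF_DIHEDRALS$strand["phi"]; spsi <- MOTIF_DIHEDRALS$strand["psi"]
      phi <- c(phi, rep(sphi, n_s1), HAIRPIN_TURN[, "phi"], rep(sphi, n_s2))
      psi <- c(psi, rep(spsi, n_s1), HAIRPIN_TURN[, "psi"], rep(spsi, n_s2))
      labels <- c(labels, rep("E", n_s1), rep("C", n_turn), rep("E", n_s2))
    }
  }
  s <- build_from_dihedrals(seqs, phi, psi)
  list(structure = s, labels = labels)
}

#' Generate a reproducible mixed synthetic dataset
#'
#' Draws `n` proteins with randomized segment layouts (helices, hairpins,
#' strands, coils; 1-3 segments of 6-20 residues each, hairpins 12-20) and
#' random sequences, emulating a small diverse folded-structure corpus.
#'
#' @param n Number of proteins.
#' @param seed Integer seed.
#' @param random_sequence If `TRUE` (default) sample residue identities
#'   uniformly from the 20 standard amino acids; otherwise poly-alanine.
#' @return A list of `make_protein()` results.
#' @export
make_dataset <- function(n, seed = 1L, random_sequence = TRUE) {
  plans <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      n_seg <- sample(1:3, 1)
      segs <- lapply(seq_len(n_seg), function(j) {
        motif <- sample(c("helix", "strand", "coil", "hairpin"), 1,
                        prob = c(0.35, 0.15, 0.3, 0.2))
        len <- if (motif == "hairpin") sample(12:20, 1) else sample(6:20, 1)
        sq <- if (random_sequence) sample(setdiff(AA1, "P"), len, replace = TRUE)
              else rep("A", len)
        list(motif = motif, length = len, sequence = sq)
      })
      list(segs = segs, coil_seed = sample.int(2^30, 1))
    })
  })
  lapply(plans, function(pl) {
    segs <- lapply(pl$segs, function(x) segment_spec(x$motif, x$length, x$sequence))
    make_protein(segs, seed = pl$coil_seed)
  })
}

#' Generate a dihedral-noise unfolding path
#'
#' Frame k (k = 0, ..., n_frames-1) perturbs every defined (phi, psi) of the
#' input by independent Gaussian noise with standard deviation
#' `(k / (n_frames - 1)) * max_noise_deg`, then rebuilds the chain with ideal
#' internal coordinates. Frame 0 is the unperturbed structure. RMSD to frame 0
#' increases with k on average, giving a controlled unfolding coordinate.
#'
#' @param s A `backbone`.
#' @param n_frames Number of frames (>= 2).
#' @param max_noise_deg Noise standard deviation of the final frame (degrees).
#' @param seed Integer seed.
#' @return A `perturbation_path`: list with `frames` (list of `backbone`),
#'   `magnitudes` (per-frame noise sd, degrees) and `seed`.
#' @export
make_unfolding_path <- function(s, n_frames, max_noise_deg, seed = 1L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  dh <- backbone_dihedrals(s)
  n <- n_res(s)
  mags <- (seq_len(n_frames) - 1L) / (n_frames - 1L) * max_noise_deg
  noise <- with_seed(seed, {
    lapply(seq_len(n_frames), function(k) {
      matrix(stats::rnorm(2L * n, sd = mags[k]), ncol = 2)
    })
  })
  frames <- lapply(seq_len(n_frames), function(k) {
    phi <- dh$phi + noise[[k]][, 1]
    psi <- dh$psi + noise[[k]][, 2]
    phi[1] <- 0; psi[n] <- 0  # undefined termini: any value, unused by builder
    build_from_dihedrals(s$sequence, phi, psi, chain_id = s$chain_id)
  })
  structure(list(frames = frames, magnitudes = mags, seed = seed),
            class = "perturbation_path")
}
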