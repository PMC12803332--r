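---
title: "Secondary-structure likelihood potentials: model, energies, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secondary-structure likelihood potentials: model, energies, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`sspot` implements a complete desk-scale stack for turning local
secondary-structure preferences into a differentiable implicit-solvent-style
potential for protein backbones:

1. a **backbone representation** (N, C&alpha;, C atoms per residue, nm units)
   with PDB I/O and geometric utilities;
2. a **synthetic structure generator** building idealized chains from internal
   coordinates with known secondary-structure content;
3. a self-contained **Kabsch–Sander SS8 assigner** (the eight DSSP classes);
4. a backbone-only **multiscale graph neural network** predicting, for every
   backbone atom, a likelihood over the eight classes;
5. two **likelihood-derived energies** — one-state and multi-state — with
   exact analytic forces;
6. a minimal **Langevin dynamics engine** that propagates a chain under a
   harmonic bonded surrogate plus the learned energy.

The scientific idea is that per-atom SS8 likelihoods, distilled from a
strong teacher into a small geometric model, induce an energy
`E = -gamma * kB * T * sum(log q)` whose minimum lies at conformations the
model considers structurally plausible. Anchoring the sum to the *reference*
(folded) motifs gives a potential that selectively stabilizes the native
state; taking a (smooth) maximum over motifs instead gives a potential that
rewards any locally well-formed structure, suitable for disordered or
partially folded states.

# The backbone representation

A structure is `n_res` residues by 3 atoms (fixed order N, C&alpha;, C) by 3
coordinates, in nanometres. All per-atom matrices in the package — SS8 label
matrices, logits, likelihoods, forces — use the row order "residue 1 N,
C&alpha;, C, residue 2 N, ..." so a structure maps to `3*n_res` rows.
Residue-level quantities are *triplicated* to their three atoms.

PDB input keeps residues possessing all three backbone atoms; incomplete
residues are dropped with a warning rather than imputed, and non-standard
residues and capping groups are excluded. Coordinates convert Å to nm on
read and back on write (`%8.3f`, so round trips are exact to 1e-4 nm).

The DSSP step needs carbonyl O and amide H positions that backbone-only
inputs lack. `reconstruct_O_H()` places them from ideal trans-peptide
geometry: O at 0.123 nm from C along the outward bisector of C&rarr;C&alpha;
and C&rarr;N(i+1) (giving an O–C–N angle of ~122°), H at 0.100 nm from N
along the outward bisector of N&rarr;C&alpha; and N&rarr;C(i−1). The
C-terminal O, N-terminal H and proline H are flagged undefined. An
alternative DSSP convention places H along the preceding carbonyl direction;
on idealized chains the two conventions agree closely and the test suite
pins behaviour by agreement with an independent reference implementation
(mdtraj) rather than by bit-identity.

# The synthetic generator

`build_from_dihedrals()` grows chains by sequential internal-coordinate
(NeRF) placement with ideal bond lengths (N–C&alpha; 0.1458, C&alpha;–C
0.1523, C–N 0.1329 nm), ideal angles (111.2°, 116.6°, 121.9°) and a fixed
trans peptide (&omega; = 180°). Helix segments use (&phi;, &psi;) =
(−57°, −47°), strands (−139°, 135°), coils draw uniformly from
&phi; &isin; [−180°, −40°], &psi; &isin; [−60°, 180°]; a hairpin option joins
two antiparallel strands with a four-residue turn whose dihedrals were chosen
so the Kabsch–Sander assigner (and mdtraj) detect inter-strand hydrogen
bonds. `make_dataset()` composes 1–3 segments per protein with random
lengths (6–20 residues) and random sequences, emulating a small diverse
folded corpus.

What the generator does *not* emulate: side chains, packed tertiary
structure (no loop closure, so multi-segment chains need not form compact
bundles), chain breaks, experimental noise, or any sequence–structure
correlation (labels here derive purely from geometry). Tests passing on this
corpus therefore demonstrate that the pipeline learns geometry-to-label maps
and that the energies behave as designed — not that the desk model
generalizes to real proteins.

`make_unfolding_path()` perturbs every defined (&phi;, &psi;) by Gaussian
noise whose standard deviation ramps linearly from 0 to `max_noise_deg`
across frames, rebuilding the chain each time. Dihedral-space noise keeps
every frame a chemically valid chain; Cartesian noise would break bond
lengths and confound energy comparisons.

# SS8 assignment

`assign_ss8()` implements the Kabsch–Sander rules on the reconstructed
backbone: the electrostatic hydrogen-bond energy
`E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol (distances
in Å; a bond when `E < -0.5`); n-turns for n = 3, 4, 5 from i&rarr;i+n
bonds; two consecutive n-turns give helices (G/H/I); Kabsch–Sander parallel
and antiparallel bridge patterns give B, ladders of two or more consecutive
bridges E; remaining turn residues T; a bend S where the angle between
C&alpha;(i)−C&alpha;(i−2) and C&alpha;(i+2)−C&alpha;(i) exceeds 70°; all
else C. Overlaps resolve with priority H > E > B > G > I > T > S. &pi;-helix
detection uses the classic 5-turn rule, not the modern
&pi;-preference amendment. Chain breaks (C–N over 0.25 nm) sever turn and
helix patterns spanning the break. Residues with undefined H (N-terminus,
proline) can accept but not donate.

Class order is fixed package-wide as (G, H, I, T, E, B, S, C), 0-based
indices 0–7; every 8-column matrix uses this order.

On twenty idealized structures (helices, hairpins, coils, mixed folds) the
assigner agrees with mdtraj's DSSP at 100% of residues; the acceptance
criterion requires &ge; 90%, leaving room for dialect differences at segment
boundaries on less idealized inputs.

# The model

Each atom starts from the concatenation of a 16-dimensional amino-acid
embedding and a 16-dimensional atom-type embedding, linearly projected to
the hidden width. Two stacks of message passing follow. The short-range pass
runs over all backbone atoms within 1.0 nm: each edge expands its distance
in 32 Gaussian radial basis functions (centres uniform on [0, r_cut], width
= spacing), multiplied by a cosine cutoff envelope that takes messages and
their first derivatives smoothly to zero at the cutoff, a filter network
(two linear layers with shifted-softplus) mapping the expansion to a
feature-wise filter, and a scalar distance-based attention gate
(sigmoid of a linear form in the RBFs). The long-range pass is a
continuous-filter convolution over C&alpha; atoms only within 2.5 nm, whose
per-residue output is broadcast additively to that residue's N and C atoms —
the mechanism by which C&alpha;-level context reaches non-C&alpha; outputs.
A three-layer feedforward head maps final embeddings to 8 logits per atom;
the row-wise softmax gives likelihoods.

All features are functions of interatomic distances only, so the logits are
exactly invariant to rotations and translations and the forces exactly
equivariant; this also keeps reverse-mode differentiation through the
pipeline compact. Vector-valued (equivariant) features would add capacity
but are unnecessary for scalar class outputs.

Package defaults (hidden width 32, 32 RBFs, head 32+32) give 20,762
parameters. The desk-scale experiments in the tests and the acceptance
script use width 48 (41,674 parameters), at the scale the distillation
design targets; both are a `model_config()` away.

The forward/backward core is implemented twice: a pure-R reference and a
compiled (RcppArmadillo) kernel used by default
(`options(sspot.use_compiled = FALSE)` switches back). A test asserts the
two agree to 1e-12 on logits, coordinate gradients, and every parameter
gradient; finite-difference checks validate both against the energy itself.

# Energies and forces

With `q_i(j)` the likelihood of class j at atom i and
`y_i(j)` the one-hot reference labels:

* one-state: `E_os = -gamma * kB * T * sum_i log(q_i(ref_i) + eps)`
* multi-state: `E_ms = -gamma * kB * T * sum_i smooth_max_j log(q_i(j) + eps)`

with `kB = 0.008314` kJ/mol/K and `eps = 1e-8` inside the logarithm (so the
energies are finite at zero likelihood; the one-state floor is
`-3 n gamma kB T log(1 + eps)`, marginally below zero, documented rather
than clamped). `gamma` is dimensionless; 2.5 is the standalone-potential
scale, while an order-of-magnitude smaller value (0.175) is the appropriate
scale when the potential corrects a Generalized-Born electrostatics engine
(not implemented here; the checkpoint + energy/force contract is the
integration surface).

The multi-state maximum is smoothed by LogSumExp with sharpness `beta`
(default 16), which bounds the smoothing error per atom by
`log(8)/beta ≈ 0.13` — small against motif-energy scales while keeping
gradients smooth; it is applied to log-likelihoods, and
`max ≤ smooth_max ≤ max + log(8)/beta` holds exactly. The hard-max
multi-state energy never exceeds the one-state energy for any reference,
since the maximum likelihood bounds the reference likelihood.

Forces are exact reverse-mode gradients of the full pipeline (softmax,
head, both message-passing stacks, RBF expansion, envelope, attention), not
finite differences; central-difference checks agree to ~1e-8 relative, far
inside the 1e-3 contract. Net force and net torque vanish to machine
precision because the energy is rigid-motion invariant.

# Training

The loss is the sum of two averaged cross-entropies: teacher likelihoods vs
student, and DSSP one-hot labels vs student. Averaging is per atom within a
protein, then per protein within a batch (the alternative — pooling all
atoms — weights long proteins more; the convention is fixed here and
applied consistently). With the built-in DSSP teacher the two terms
coincide and the total is twice the anchor term, which is what makes a
desk-scale teacher faithful to the method: the loss already contains the
physical anchor. File-based soft teachers (8-column CSVs in G,H,I,T,E,B,S,C
order, probabilities or logits, per-residue rows triplicated) slot into the
same loss.

Optimization is Adam with the reference schedule: initial learning rate
decayed by 0.9 every three epochs (0-based epochs, so
`lr(e) = lr0 * 0.9^(e %/% 3)`), L2 weight decay 1e-6 added to the gradient,
whole-protein batches with a seeded shuffle, no early stopping, and a
seeded 80/20 train/validation split by protein. Everything is deterministic
given the seeds, and histories are bit-reproducible.

The desk-scale experiment trains on 80 synthetic proteins for 30 epochs
with the DSSP teacher. Two settings depart from the reference-scale values,
for reasons the reference scale itself explains: a batch of 50 proteins
makes sense against ~19,000 training proteins (hundreds of updates per
epoch) but collapses to ~2 updates per epoch at desk scale, so the desk
batch is 5; and the learning rate is 3e-3 rather than 1e-3 since with only
~360 total updates the schedule never reaches the small-step regime. The
decay shape (0.9 every 3 epochs) is kept and tested exactly. Width-48
models reach ~85% held-out atom-level correct-motif probability on 20
unseen proteins; the per-class confusion shows H near 0.97 with the
remaining mass concentrated in the geometrically ambiguous T/S/C boundary
classes. Optional dihedral-noise augmentation
(`training_config(augment_noise_deg = ...)`) is available but off by
default — at desk scale it trades clean-structure accuracy for robustness
and lowers held-out performance.

Two evaluation summaries are reported: `mean_correct_prob`, the mean
predicted likelihood of the true class over atoms (micro), and `diag_mean`,
the average of the confusion-matrix diagonal over classes with support
(macro). The micro mean is the primary desk-scale metric because tiny
synthetic corpora leave several classes (I, G, B) with little or no
support, making the macro average dominated by a handful of atoms.

# Dynamics

The bonded surrogate holds the chain together: harmonic bonds
(10^5 kJ/mol/nm²) at the generator's ideal lengths and harmonic angles
(500 kJ/mol/rad²) at the ideal values — deliberately no dihedral terms, so
the control potential carries no secondary-structure information
whatsoever. The integrator is BAOAB-splitting Langevin (half kick, half
drift, Ornstein–Uhlenbeck, half drift, half kick), timestep 0.002 ps,
friction 1/ps, all pseudo-atoms 12 amu, Maxwell-distributed initial
velocities, and a pre-drawn seeded noise stream so trajectories are
bit-reproducible on one thread. With friction and temperature zero it
reduces to velocity Verlet, under which total energy drift over 10⁴ steps
is below 1% of the potential-energy fluctuation scale at dt = 0.0005 ps. A
guard aborts on non-finite forces or per-step displacements over 10 nm,
optionally retrying with a halved timestep; `minimize_energy()` provides
the overdamped zero-temperature limit as backtracking gradient descent
whose accepted steps strictly decrease the energy.

The desk-scale stability analogue compares two 50,000-step runs at 300 K
from a 16-residue &beta;-hairpin native: the one-state potential
(&gamma; = 2.5) versus the bonded-only control. RMSD is computed over the
structured (non-C) residues, mirroring the practice of excluding flexible
regions from RMSD; the mask matters because coil-labelled tails are
unrestrained by construction — any disordered geometry keeps their C
likelihood high — so full-chain RMSD measures tail flapping rather than
fold integrity. A hairpin rather than a lone helix is the test system
because its inter-strand hydrogen bonds tie global shape to the SS8 labels;
a lone helix can bend without breaking a single label, leaving the
one-state energy almost flat along that mode. Under these conditions the
one-state run stays within 0.33 nm core RMSD while the control exceeds
0.5 nm.

The energy-versus-unfolding analysis (`analyze_trajectory()`) reports
per-frame RMSD, one-state and multi-state energies, and their Pearson and
Spearman correlations. Along seeded dihedral-noise unfolding paths of a
coil–helix–coil native (20 frames to 60° noise), the trained desk model
gives Spearman &rho;(RMSD, E_os) above 0.8 for every tested path seed;
the acceptance threshold is 0.7. At high noise on short mixed folds RMSD
itself stops being monotone in disorder (chains fold back), which bounds
what any energy can correlate with; path length and noise were chosen so
RMSD remains a valid unfolding coordinate.

# Numerical and design notes

* **Units**: nm, ps, kJ/mol, K, amu throughout; PDB I/O converts Å.
* **Seeding**: every stochastic operation takes an explicit seed and
  restores the caller's RNG state; nothing depends on global state.
* **Zero-likelihood guard**: `eps = 1e-8` enters inside the log, exactly as
  the motif-energy definition, not on the logits.
* **Cutoff smoothness**: the cosine envelope zeroes messages *and* their
  derivatives at the cutoff radius, so forces are continuous there; the
  energy is smooth everywhere else by construction (softplus activations).
* **Degenerate inputs**: single-residue chains are representable (the
  builder's contract) but dihedrals, O/H reconstruction and DSSP require 2,
  2 and 3 residues respectively; structures with no edges inside a cutoff
  fall back to bias-only messages.
* **Problem sizes**: the shipped experiments use 80 + 20 proteins of 6–60
  residues, 30 epochs, 20-frame unfolding paths, and 50,000-step dynamics —
  sizes chosen so the full stack (training included) reruns from scratch in
  minutes on one CPU while still exercising every claim.

# Known limitations

* The desk teacher is DSSP itself, so the distillation recovers a
  geometry-defined labelling; distilling a sequence-conditioned teacher's
  solvent-sensitive preferences requires supplying its likelihood files.
* The learned potential restrains what the labels see: motions that
  preserve every local motif (helix bending, rigid-segment rearrangement)
  are nearly flat directions. In the reference-scale method this is
  mitigated by training on diverse real folds and by pairing with an
  electrostatics term; at desk scale it shapes which stability experiments
  are meaningful (see the hairpin choice above).
* Saturated likelihoods (q &rarr; 1) make restoring forces vanish near the
  native basin; γ rescales the well depth but not this local flatness.
* No side chains, no solvent-accessibility, no Generalized-Born term, no
  umbrella sampling; the package stops at the energy/force contract.
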