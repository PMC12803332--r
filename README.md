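# sspot

Secondary-structure likelihood potentials from a backbone graph neural
network.

`sspot` is for computational structural biologists who want a
self-contained, inspectable implementation of the idea behind
distillation-based implicit solvent models: train a small geometric neural
network to predict, for every protein backbone atom, a probability
distribution over the eight DSSP secondary-structure classes (SS8), then
read those probabilities as an energy function that can drive molecular
dynamics.

## The model and the energies

Each backbone atom i (N, Cα, C per residue) receives an embedding built
from its amino-acid identity and atom type (16 dimensions each). Two stacks
of message passing follow: a short-range pass over all backbone atoms
within 1.0 nm (Gaussian radial-basis distance features, smooth cosine
cutoff, distance-based attention) and a long-range continuous-filter pass
over Cα atoms within 2.5 nm whose output is broadcast back to the
residue's N and C atoms. A three-layer head yields SS8 logits s_i(j);
likelihoods are the row-wise softmax

    q_i(j) = exp(s_i(j)) / Σ_j' exp(s_i(j'))

Training distills a teacher's per-residue SS8 likelihoods (soft labels,
supplied as CSV files) together with DSSP one-hot labels computed from
geometry, by the summed cross-entropy

    L = CE(P_teacher, Q) + CE(Y_DSSP, Q)

with Adam, learning rate decayed by 0.9 every three epochs, and L2 weight
decay 1e-6. Without teacher files the DSSP term doubles and serves as the
built-in teacher.

Likelihoods become energies (k_B = 0.008314 kJ/mol/K, ε = 1e-8):

    E_os(x) = -γ k_B T Σ_i log( q_i(ref_i)(x) + ε )        one-state
    E_ms(x) = -γ k_B T Σ_i smoothmax_j log( q_i(j)(x) + ε ) multi-state

The one-state energy reads, at every atom, the likelihood of the motif
present in a reference (folded) structure, so it selectively stabilizes
that state; the multi-state energy rewards any plausible local motif
(LogSumExp smooth maximum, sharpness β = 16). Both come with exact
analytic forces (reverse-mode differentiation through the whole network),
verified against central finite differences, and both are exactly
invariant under rigid motions.

The package also contains an idealized-backbone generator (helix / strand /
coil / β-hairpin segments grown from internal coordinates), a
self-contained Kabsch–Sander SS8 assigner validated against mdtraj's DSSP,
PDB backbone I/O, and a BAOAB Langevin engine with a harmonic bonded
surrogate.

## A worked example

```r
library(sspot)

# 1. a small synthetic corpus with DSSP labels, and a trained model
train_set <- make_dataset(80, seed = 101)
fit <- train(train_set,
             model_config(hidden_dim = 48, head_dims = c(48, 48), seed = 1),
             training_config(epochs = 30, batch_size = 5,
                             learning_rate = 3e-3, seed = 1))
evaluate_confusion(fit$model, make_dataset(20, seed = 202))
#> <eval_report>
#>   mean correct-motif probability (atoms): 0.852
#>   diagonal mean (classes with support):   0.658
#>   support: G=0 H=486 I=0 T=87 E=144 B=24 S=141 C=744

# 2. the learned energy rises as a fold is disrupted
native <- make_protein(list(segment_spec("coil", 3), segment_spec("helix", 12),
                            segment_spec("coil", 3)), seed = 4)$structure
path <- make_unfolding_path(native, n_frames = 20, max_noise_deg = 60, seed = 1)
an <- analyze_trajectory(path, native, assign_ss8(native), fit$model,
                         energy_params(gamma = 2.5))
round(attr(an, "spearman"), 3)
#> [1] 0.865

# 3. dynamics under the one-state potential keep the fold intact
hairpin <- make_protein(segment_spec("hairpin", 16), seed = 7)$structure
sc <- sim_config(n_steps = 5000, potential_mode = "os", gamma = 2.5, seed = 11)
traj <- run_md(hairpin, sc, model = fit$model)
tail(traj$records[, c("step", "E_gnn", "rmsd_nm", "temp_K")], 1)
#>    step     E_gnn   rmsd_nm   temp_K
#> 51 5000 0.9379868 0.4417487 233.3224
```

The evaluation report says the trained model assigns, on average, 85%
probability to the true DSSP class of a held-out atom (the per-class
confusion matrix is in `$confusion`). The Spearman coefficient is the rank
correlation between RMSD-from-native and the one-state energy along a
controlled unfolding path — values near 1 mean the energy tracks
unfoldedness. In the dynamics record, `E_gnn` staying within a fraction of
a kJ/mol of its native value means every secondary-structure label
survived the thermal motion; the full-chain RMSD of ~0.44 nm is dominated
by the unrestrained coil tails, and masking to the structured residues
(`kabsch_rmsd(hairpin, frame, atom_mask = ss8_letters(assign_ss8(hairpin)) != "C")`)
gives 0.26 nm for the hairpin core itself.

A thin command-line front end over the same functions is installed at
`inst/cli/sspot.R` (subcommands `generate`, `label`, `train`, `energy`,
`simulate`).

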