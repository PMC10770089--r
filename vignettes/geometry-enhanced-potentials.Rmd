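---
title: "Geometry-enhanced equivariant potentials: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-enhanced equivariant potentials: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rgcnet)
```

This vignette records the model, its assumptions, the tunable parameters,
the numerical choices, and the limits of what the test suite establishes.
It states no empirical number that the tests or `scripts/acceptance.R` do
not themselves compute.

## The model and its assumptions

`rgcnet` implements a machine-learned interatomic potential for isolated
(non-periodic) molecules.  Input is a configuration `(Z, X)` — atomic
numbers and Cartesian coordinates in Å; outputs are a scalar property
(energy in kcal/mol for the force-field head) and, for the energy head,
per-atom forces in kcal/mol/Å defined as the exact negative gradient of the
predicted energy.  Because forces come from one scalar by reverse-mode
differentiation, the force field is conservative by construction, and all
force equivariance follows from energy invariance.

The geometric core is *runtime geometry calculation*: each atom carries a
direction unit `v_i = sum_j u_ij` over its within-cutoff neighbors.  Three
invariant scalars derived from it reproduce, at cost linear in the number
of directed edges, sums that explicit enumeration computes at O(N²)–O(N³):
the angle sum `<v_i, v_i>`, the per-edge dihedral sum
`<Rej_{u_ij}(v_i), Rej_{u_ji}(v_j)>`, and the per-edge improper sum
`<Rej_{u_ij}(v_i), Rej_{u_ji}(v_i)>`.  The enumeration oracles in
`R/rgc.R` (`oracle_*_sum`) are implemented independently — per-neighbor
rejections summed pairwise, never through `v_i` — and the identity between
the two routes is the package's central correctness test.

Two readings of these "cosine sums" deserve care:

* the angle sum counts the diagonal terms `j = k` (each contributes
  `cos 0 = 1`), so an atom with two orthogonal neighbors scores 2, not 0;
* the dihedral and improper entries are inner products of *rejections*, so
  each torsion term carries a `sin`-magnitude weight along with its cosine.
  The oracles enumerate exactly those weighted terms.

The improper scalar is implemented with both rejections acting on the
vertex's own `v_i`.  Since rejection is insensitive to the sign of the
axis, it degenerates to `|Rej_{u_ij}(v_i)|²` — a squared norm.  We keep
this form deliberately (it is the form the architecture defines); a
variant using the neighbor's `v_j` in the second slot would be a different
feature, and we do not guess at it.

### Higher orders without tensor products

The angle pathway extends to spherical order `l` by replacing each `u_ij`
with its real spherical-harmonics vector and summing per-order inner
products.  The addition theorem
`sum_m Y_lm(a) Y_lm(b) = (2l+1)/(4π) P_l(a·b)` guarantees the result is
again a Legendre-weighted angle sum; no Clebsch–Gordan coupling is needed
and the parameter count does not grow.  We use orthonormal *real*
harmonics without the Condon–Shortley phase: the network is real-valued
throughout, conjugation is vacuous, and the addition theorem is
phase-convention-free as long as one convention is used consistently
(property-tested for `l ≤ 4`).  Only the angle pathway is expanded; the
dihedral/improper rejections always act on the order-1 (geometric)
components, because a higher-order analogue of the rejection is not
defined by the architecture.  In the network, `l_max = 2` therefore means:
vector channels carry 3 + 5 spatial components, messages and the angle
inner product use all of them, rejections use the first 3.

## The network

Blocks follow the vector–scalar interactive pattern: scalar node
embeddings `h` (per atom), scalar edge embeddings `f` (per directed edge),
and equivariant vector embeddings `v` (per atom, `(2l+1)×F` channels,
initialized to zero) update each other cyclically:

1. **Edge-fusion attention** scores each directed edge per head with
   `SiLU((W_Q h_i) ⊙ (W_K h_j ⊙ Dense_K(f_ij)))` — an activation-scored
   attention with *no softmax*: the printed operation contains no
   normalization, and the cosine-cutoff weight `φ(r) = ½(cos(πr/r_c)+1)`
   (which multiplies every message and vanishes smoothly at `r_c`) plays
   the moderating role.  Scores act per head: the channelwise product is
   summed within each head and the resulting per-head scalar gates all of
   that head's channels.
2. **Scalar2Vec** forms vector messages
   `Dense_u(m_ij) ⊙ u_ij + Dense_v(m_ij) ⊙ v_j`, aggregates them, and adds
   a gated residual `W_vm m_i ⊙ W_v v_i`.  Scalars broadcast over the
   spatial components of each channel — the only shape-consistent reading
   that preserves equivariance.  No vector pathway carries a bias.
3. **Vec2Scalar** updates nodes with
   `<W_t v_i, W_s v_i> ⊙ W_Angle m_i + W_res m_i` (runtime angle, now on
   learned vector channels) and edges with
   `<Rej(W_Rt v_i), Rej(W_Rs v_j)> ⊙ Dense_Dihedral(f_ij)` (runtime
   dihedral).  With `use_improper = TRUE` an analogous vertex-centred term
   is added to the edge update; it is off by default.

Gated equivariant output blocks (norm-gated, `F → F/2 → 1`) reduce to the
heads: total energy `E = Σ h_i` with `F = -∇E`; dipole magnitude
`|Σ v_i + h_i (r_i - r_c)|` about the center of mass; spatial extent
`Σ h_i |r_i - r_c|²`; or a plain scalar aggregate.

### Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `cutoff` | 5 Å | neighbor radius; the standard value for small organic molecules in this model family |
| `n_blocks` | 9 | message-passing depth for production-scale models; tests use 2 |
| `hidden_dim` | 256 | embedding width; tests use 16–64 |
| `n_heads` | 8 | attention heads; must divide `hidden_dim` |
| `n_rbf` | 32 | exponential-Gaussian radial basis size on `exp(-r)` abscissae |
| `l_max` | 1 | spherical order of vector channels (1 or 2) |
| `loss weights` | 0.05 / 0.95 | energy/force MSE weights for force-field training |
| `lr_decay_factor` | 0.8 | plateau decay factor |
| `plateau_patience` | 30 epochs | epochs without validation improvement before one decay |

The attention head count, RBF count and the embedding-block internals are
not pinned down by the architecture's public description; the defaults
above are declared as this package's choices, not inherited ones.  The
embedding block here fuses the species embedding with an RBF-filtered,
cutoff-weighted sum of neighbor species embeddings through one SiLU dense
layer; we deliberately omit layer normalization (sometimes used in this
position) — at desk scale it adds parameters and a second-derivative
pathway without changing any property the suite can observe.

## Differentiation strategy

No autodiff framework exists in the target R environment, so the package
ships a small tape engine (`R/autodiff.R`).  Design points:

* a closed primitive set (arithmetic, matmul, gather/scatter rows, column
  slice/concat, power, exp, trig, sigmoid, broadcasts) whose
  vector–Jacobian products are built *from the same primitives*, so
  gradients are tape nodes and the force-matching loss — which contains
  the force, itself a gradient — can be differentiated again exactly;
* per-parent lazy thunks: a backward pass materializes a gradient branch
  only if it can reach a requested target, so force evaluation never pays
  for parameter gradients and vice versa;
* deterministic reductions: edges are enumerated in a fixed order and
  `rowsum` aggregation is reproducible, so equal seeds give bitwise-equal
  runs on one machine.

Training-grade checks: first-order gradients and the double backward are
verified against central finite differences; analytic forces match finite
differences of the energy at 1e-4 Å steps to better than 1e-5 relative on
random configurations (an acceptance criterion).

## Training

Adam (the architecture's description names only learning rates and
schedules, not the optimizer; AdamW's decoupled decay is pointless without
weight decay, so plain Adam) with the combined loss
`w_E MSE(E) + w_F MSE(F)`, plateau-triggered learning-rate decay
("stopped decreasing" operationalized as: no improvement > 1e-7 absolute
for `plateau_patience_epochs` consecutive epochs), early stopping at 3×
the plateau patience, and best-validation checkpointing.  Labels are
standardized per fit — energies shifted by the training mean and both
labels scaled by the standard deviation of the training forces — and the
affine calibration is stored on the returned model and inside checkpoints;
this keeps the network's outputs O(1) regardless of the force scale of the
data and is standard practice in this model family.  NaN losses abort;
gradient clipping is off.

Everything runs in float64: R has no float32 arithmetic, so the
"float32 training / float64 evaluation" split common in GPU
implementations collapses to float64 everywhere.  Tolerances in the test
suite are float64-scale throughout.

## The synthetic world

The synthetic module is the package's source of labeled data and exact
oracles: classical bonded toy potentials (harmonic bonds `k(r-r0)²`,
harmonic angles `k_θ(θ-θ0)²`, cosine dihedrals `k_φ(1+cos(nφ-φ₀))`) with
hand-derived analytic gradients, verified against finite differences.
Datasets are Gaussian displacements around a reference geometry (not
Boltzmann samples — simplicity and exact label reproducibility), labeled
by the exact energy and forces.

The frozen learnability experiment (`reference_recovery()`): a 4-atom
carbon chain with bonds `k = 300 kcal/mol/Å², r0 = 1.5 Å` (a typical
single-bond stiffness), angles `k_θ = 60 kcal/mol/rad²` at the
tetrahedral angle, and one 3-fold dihedral with `k_φ = 3 kcal/mol`,
sampled at 0.05 Å displacement scale — 50 training and 10 validation
frames at seed 7 — trained on a 2-block, 64-channel model with the
0.05/0.95 loss.  Training settings chosen for the experiment (recorded
here once): Adam at `lr = 2e-3` (the conventional small-model range;
production learning rates of 1e-4 are tuned for datasets thousands of
times larger), batch size 25 (larger batches amortize per-step tape
overhead on one CPU), plateau patience 12 epochs, 500 epochs maximum.  The benchmark statistic is the validation force MAE divided by
the standard deviation of the training-label forces; the acceptance
criterion asks for < 5%.

What a green suite does and does not establish: it shows the
implementation is symmetric, energy-conserving, and able to regress a
smooth low-dimensional potential from few samples; it does not show
ab-initio accuracy, transferability across molecules, or stability of
long MD with a learned potential — those require real quantum-chemistry
datasets and production-scale training outside this package's scope.

## Molecular dynamics

Velocity Verlet in Å/fs/amu/kcal·mol⁻¹ units (conversion constant
`KCAL_PER_AKMA = 4.184e-4` amu Å²/fs² per kcal/mol, tested against the
hand computation), Maxwell–Boltzmann initialization with net-momentum
removal (hence `3N - 3` degrees of freedom in the temperature), optional
Berendsen weak-coupling rescale
`λ = sqrt(1 + (τ/τ_c)(T_target/T_inst - 1))` with a 100 fs default
coupling time (a conventional value; the thermostat settings of the
reference MD datasets are not published).  The default production
timestep is 0.5 fs.  `distance_distribution()` histograms all interatomic
pair distances per frame (0.05 Å bins by default, no kernel smoothing)
and averages over frames — the ensemble-averaged atomic density at radius
r used to compare trajectories.

## Numerical choices and degenerate inputs

* Cutoff membership is inclusive (`r ≤ r_c`); the cosine cutoff is zero
  exactly at the boundary, so membership there cannot change predictions
  (continuity is tested by scanning an atom across `r_c`).
* Coincident atoms are an error everywhere (the direction unit divides by
  `|r_ij|`), as are collinear angle arms and degenerate dihedrals in the
  toy potential.
* The channel norms in the gated output blocks use `sqrt(s + 1e-12)`: the
  gradient of a bare norm is undefined at zero, and vector channels are
  exactly zero for isolated atoms and at initialization.  The epsilon
  perturbs energies by at most ~1e-6 in a 1-channel block and is applied
  to an invariant, so no symmetry is affected.
* Enumeration oracles guard at `N ≤ 50` — they exist to be obviously
  correct, not fast.
* The `.npz` writer emits stored (uncompressed) zip members with a pure-R
  CRC-32 so archives round-trip without external tools; the reader also
  accepts compressed archives via R's internal unzip.
* The YAML reader/writer covers the subset the package's interfaces emit
  (flat maps, one nesting level, inline lists) — it is not a general YAML
  parser.

## Known limitations

* O(N²) neighbor search (no cell lists) and dense per-edge tapes: desk
  scale by design; hundreds of atoms are fine, tens of thousands are not.
* No periodic boundary conditions, no Lennard-Jones/nonbonded synthetic
  terms, no constraint algorithms, no replica exchange.
* `l_max ≤ 2` in the network and `l ≤ 4` in the harmonics module.
* Training is single-device, full-precision, without hyperparameter
  search; the goal is correctness and learnability, not benchmark parity.
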