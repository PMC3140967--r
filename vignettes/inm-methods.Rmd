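---
title: "Detecting open/closed conformational switching with instantaneous normal modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting open/closed conformational switching with instantaneous normal modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inmtools)
```

## The problem

Protein kinases such as AMPK/SNF1 switch between an inactive *open* and an
active *closed* interlobe conformation of the kinase domain. Root-mean-square
deviation (RMSD) to a reference structure is the conventional trajectory
observable for such switching, but RMSD is dominated by the largest
displacements and is insensitive to changes in the *pattern* of collective
motion. `inmtools` implements a complementary observable: a structural
similarity defined in the space of elastic-network normal modes, evaluated
instantaneously for every trajectory snapshot, together with the supporting
ensemble observables (quasi-harmonic configurational entropy by region,
solvent-accessible surface area profiles, and backbone dihedral statistics)
used to characterize what changes when the switch happens.

## The model

### Tirion elastic network

Each conformation is reduced to one node per residue (the C-alpha atom by
default) and modelled as a network of Hookean springs,

$$E \;=\; \frac{C}{2}\sum_{|r^0_{ij}| \le R_c}
\bigl(|r_{ij}| - |r^0_{ij}|\bigr)^2 ,$$

with a spring between every node pair within the cutoff \(R_c\) of the
*reference* (superscript 0) geometry. \(C\) is a single phenomenological
force constant: it scales all eigenvalues uniformly and cancels in the
similarity metric, so it defaults to 1. Masses are unit (Tirion's original
convention); frequencies \(\omega_k = \sqrt{\lambda_k}\) are therefore in
arbitrary units, which also cancel in the weighting below. The analytic
Hessian at the reference geometry is assembled per spring from the rank-one
block \(C\,\hat u \hat u^{\mathsf T}\) on the unit bond vector; a connected
network has exactly 6 zero modes (rigid translations and rotations), which
are discarded by the relative threshold
\(\lambda < 10^{-8}\lambda_{\max}\). The threshold is safe because the
machine-precision null space of an analytic Hessian sits many orders of
magnitude below the first internal mode of a compact protein; finding fewer
than 6 near-zero modes on a connected network is reported as an error, since
it can only mean an assembly bug.

### Instantaneous normal mode (INM) similarity

Every snapshot is treated as its own reference structure: its network is
rebuilt at the instantaneous geometry and diagonalized ("instantaneous"
normal modes). To compare a snapshot against a template (a crystal
reference), the snapshot's mapped nodes are first rigidly superposed onto
the template (Kabsch), because eigenvectors transform with the frame; the
package enforces this order of operations. Each of the \(n\) lowest
internal modes \(v_i\) of the snapshot (taken in fixed ascending frequency
order) is then matched to the template mode \(v_{m(i)}\), among a pool of
the template's 10 lowest, that maximizes the absolute overlap
\(|\langle v_i, v_m\rangle|\), and the similarity is the frequency-weighted
mean of the matched overlaps,

$$S \;=\; \frac{\sum_{i=1}^{n} \omega_{m(i)}\,
|\langle v_i, v_{m(i)}\rangle|}{\sum_{i=1}^{n} \omega_{m(i)}},$$

with the weights \(\omega_{m(i)}\) taken from the matched *template* modes.
Orthonormality of the eigenvectors forces \(S \in [0,1]\), and \(S = 1\)
exactly when the mode sets coincide. Eigenvector sign is arbitrary, so only
absolute overlaps are used, and within a degenerate eigenvalue block the
ordering is solver-dependent — the matching step, not the index order, is
what pairs modes. Note that \(S(a,b)\) and \(S(b,a)\) need not coincide
(matching is directional); the package computes the direction
snapshot-against-template and never averages the two.

Defaults follow the method's stated operating point: cutoff 13 Å,
\(n = 2\) modes, snapshots every 10 ps.

### State classification and transition counting

A trace holds, per snapshot, the similarity to an open template and to a
closed template. A frame is called *open* when
\(s_\text{open} \ge 0.95\) and \(s_\text{closed} \le 0.85\), *closed* in
the mirror case, and *intermediate* otherwise; the thresholds come from the
observed behaviour of stable trajectories (same-state similarity above
0.95, cross-state similarity in the 0.80–0.85 band) and are configurable.
A *dwell segment* is a run of at least `dwell` (default 5) same-state
frames; intermediate frames never terminate a segment — only an
opposing-state dwell does, which prevents threshold-grazing frames from
being counted as events. A transition is recorded at each change of state
between successive dwell segments, and per-start-state tables report the
percentage of trajectories with and without transitions, rounded to the
nearest integer (halves up).

### Schlitter configurational entropy

For an ensemble aligned to its mean structure (align to the first frame,
form the mean, re-align all frames to the mean — one re-iteration), with
positional covariance \(\sigma\) (1/n normalization) and diagonal mass
matrix \(M\),

$$S_\text{conf} \;=\; \frac{k_B}{2}\,
\ln\det\!\Bigl(\mathbf{1} + \frac{k_B T e^2}{\hbar^2} M^{1/2} \sigma
M^{1/2}\Bigr),$$

an upper bound on the true configurational entropy, computed in the
symmetrized form for numerical stability. Constants are SI (CODATA 2018)
and the result is molar (J/mol/K by default, kJ/mol/K selectable).
Per-region reports divide the region's total entropy by its backbone
(N, C-alpha, C) atom count, with an error bar from the standard deviation
over 3 contiguous frame blocks (block count configurable, minimum 2).
Published per-atom backbone values of magnitude ~20 are consistent with
J/mol/K; both unit labels are offered rather than silently reconciling the
discrepancy.

### SASA and dihedrals

SASA uses Shrake–Rupley with 960 deterministic golden-spiral sphere points,
probe 1.4 Å, and radii C 1.70 / N 1.55 / O 1.52 / S 1.80 / H 1.20 Å. At
this point density the quadrature error on an isolated sphere is well below
1%, numerically equivalent to lattice-based methods for per-residue
profiles. Per-residue trajectory profiles report the mean and the
*population* standard deviation over frames, so duplicating frames changes
neither. Backbone \(\varphi/\psi\) torsions follow the IUPAC sign
convention (right-hand rule looking down the central bond) with values in
\((-180^\circ, 180^\circ]\); 2-D densities are normalized per residue on a
periodic grid over the full torus, so wrap-around angles are binned, never
dropped.

## The synthetic world

The generators stand in for microsecond-scale solvated MD, which is not
reproducible at desk scale. They state a world and keep it fixed:

* **Hinge protein** (`make_hinge_protein`): two compact C-alpha solenoid
  domains (30 residues each by default) joined by a 2-residue hinge;
  consecutive C-alpha spacing is exactly 3.8 Å. The open (120°) and closed
  (60°) states differ *only* by a rigid rotation of domain 2 about the
  hinge axis, so domain 1 is bit-identical across states and the
  open/closed pair is a guaranteed discriminative fixture: \(S = 1\)
  against itself, \(\approx 0.64\) across states after superposition.
* **Trajectories** (`make_transition_trajectory`): frames jitter around one
  state with isotropic Gaussian coordinate noise of 0.3 Å (a thermal-looking
  amplitude, not a thermostat), optionally switching to the other state by
  linear interpolation over 10 frames. Seeded and bit-reproducible.
* **Gaussian ensembles** (`sample_gaussian_ensemble`): i.i.d. frames from a
  stated covariance, giving Schlitter's estimator an analytic truth. For
  entropy tests the covariance comes from the hinge network's internal
  modes (`enm_covariance`, the \(\lambda^{-1}\) pseudo-inverse), which has
  no rigid-body component, scaled so the mean square fluctuation is
  0.09 Å² per atom (RMSF 0.3 Å). The scale matters: quasi-harmonic
  analysis assumes small fluctuations, and at unphysically large amplitude
  (several Å) the mandatory rigid-body alignment itself distorts the
  apparent covariance, so no estimator could recover the generator value.

What a green test on this world does **not** establish: force-field
realism, solvent effects, barrier heights or kinetics, or the behaviour of
the metric on proteins whose conformational change is not hinge-like.

## Numerical choices

* Rigid-mode threshold \(10^{-8}\) relative; altloc policy highest
  occupancy with ties to "A"; inclusive residue intervals in author
  numbering throughout.
* The built-in global sequence aligner (match +1 / mismatch −1 / gap −2,
  deterministic traceback preferring diagonal) stands in for an external
  multiple-alignment tool when no explicit residue pairing or constant
  offset is given; explicit pairs always override.
* Superposition requires at least 3 non-collinear points and returns a
  proper rotation (det = +1) always.
* In `similarity_trace` the snapshot eigendecomposition is done once per
  frame and the eigenvectors are rotated per template (eigenvectors
  transform covariantly under the fitted rotation); this is exact, and is
  verified against direct per-template recomputation to ~1e-13.
* Trace/table/entropy/SASA artifacts are TSV with the resolved
  configuration echoed as `#` header comments; reruns with the same config
  and seed are byte-identical. Config files are JSON.

## Known limitations

* **Mode-shuffling non-monotonicity.** Along a noiseless open-to-closed
  path, \(S\) against the open template decays overall but is not strictly
  monotone: the max-overlap matching is discrete, and where the matched
  template set reshuffles, \(S\) can step upward (observed once near the
  closed end of a 21-point hinge-angle sweep, +0.058). Frequency weighting
  mitigates but cannot eliminate this; the property tests therefore assert
  monotonicity on every sub-path with stable matching and permit upward
  steps only at reshuffle points. Classification is unaffected in practice
  because reshuffles occur far below the 0.95 threshold band.
* The directional asymmetry \(S(a,b) \ne S(b,a)\) is inherent to
  max-overlap matching; both directions are computed in the tests and
  reported, never averaged.
* Two query modes may match the same template mode; the more elaborate
  optimal-mixing alternatives (e.g. RMSIP-based) are out of scope.
* The entropy block-error scheme (3 contiguous blocks) is a pragmatic
  default; it underestimates the error when the ensemble is correlated on
  the block timescale.
* No mmCIF, ligand chemistry, hydrogen inference, structure repair,
  free-energy or kinetics estimation.

## Worked example

```{r example, eval = FALSE}
open <- make_hinge_protein(state = "open")
closed <- make_hinge_protein(state = "closed")
traj <- make_transition_trajectory(open, closed, n_frames = 200,
                                   switch_frame = 50, noise_sigma = 0.3,
                                   seed = 1)
trace <- similarity_trace(traj, open, closed)   # cutoff 13, n = 2
call <- classify_trajectory(trace)              # 0.95 / 0.85, dwell 5
n_transitions(call)                             # 1
tabulate_transitions(list(call))
```
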