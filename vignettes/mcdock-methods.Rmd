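---
title: "Methods: parallel reduced-depth Monte-Carlo docking in mcdock"
author: "mcdock maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parallel reduced-depth Monte-Carlo docking in mcdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdock)
```

## The search model

`mcdock` docks a flexible ligand into a rigid receptor by running many
short, independent Monte-Carlo iterated local searches ("docking
threads") instead of one long serial chain.  The rationale is a subspace
argument: the conformational space S is covered by the random initial
conformations of n threads, each thread only needs to descend its own
neighbourhood, and the host-side aggregation (sort, RMSD de-duplication,
refinement of the top poses) restores a global answer.  Determinism is a
design contract: every thread owns an RNG substream keyed by
`(master_seed, thread_index)`, so the result set is bitwise identical
for any execution order or degree of parallelism.  This replaces
GPU-kernel scheduling with a portable reproducibility guarantee.

A conformation is parameterized as position (3), orientation as a unit
quaternion (4) and one torsion per rotatable bond, i.e. 7 + Nrot
coordinates.  We deliberately keep the redundant 4-component quaternion
block (rather than a 3-component tangent parameterization): the
optimizer state and gradient then have the stated 7 + Nrot dimension,
and the score is made invariant to quaternion norm by normalizing inside
the kinematics, so the post-step re-normalization is energy-neutral and
finite differences of the raw coordinates match the analytic gradient.

### Kinematics

The ligand's PDBQT torsion tree is flattened once into a node list in
depth-first order plus a boolean children map; the iterative traversal
of that list reproduces the recursive traversal exactly (tested against
an independent recursive implementation to 1e-12 Å).  Torsions are
applied in node order (parents before children), each rotating the
node's atoms and all descendants about the normalized parent-atom to
child-atom axis by the right-hand rule.  The rigid-body rotation is
applied about the centroid of the root-node reference atoms — any fixed
rotation center is a valid convention, and the centroid keeps position
and orientation mutations on comparable length scales.

### Scoring

The potential is the AutoDock Vina empirical form on surface distance
d = r − R_i − R_j: two attractive gaussians (widths 0.5 and 2 Å, the
second centred at 3 Å), quadratic repulsion for d < 0, and
piecewise-linear hydrophobic and hydrogen-bond terms, with the published
weights and an 8 Å cutoff; the weight table is exposed via
`scoring_terms()` rather than hard-coded.  Two implementation choices
matter:

* **Shifted truncation.**  The raw form has a ~3×10⁻³ kcal/mol step at
  the cutoff (the wide gaussian is not yet zero there).  Each pair term
  is therefore shifted by its own cutoff value so the potential is
  exactly continuous at r = 8 Å.  The shift is a constant per atom-type
  pair and cannot change pose ranking within the cutoff.
* **Typing without connectivity.**  PDBQT stores atom types but not
  bonds, so hydrophobic/donor/acceptor flags come from the type token
  alone (acceptors OA/NA/SA, donors N/O, hydrophobic C/A and halogens),
  and the ligand bond graph — needed to exclude 1-2/1-3/1-4
  intramolecular pairs — is inferred from the reference geometry
  (heavy-atom distance < 1.9 Å).  Intramolecular pairs additionally must
  span different rigid bodies.  Hydrogens (H, HD) are excluded from
  scoring, as is conventional.

The receptor field is precomputed on a per-atom-type lattice (default
spacing 0.375 Å, the AutoDock-family convention) spanning the docking
box plus one cell of margin, and queried by 8-corner trilinear
interpolation.  Points outside the lattice are clamped to its hull and
charged a quadratic penalty of 1 kcal/mol/Å², which keeps the optimizer
inside the box with finite, differentiable energies.  Final reported
scores (only) carry the conformational-entropy factor
1/(1 + 0.05846 Nrot); it is pose-independent, so applying it during the
search could not change anything.

### Gradient

The analytic gradient over the 7 + Nrot coordinates is assembled from
per-atom Cartesian contributions: lattice-interpolation derivatives plus
pair-term derivatives, pushed through the kinematic chain (position:
plain sum; quaternion: contraction with dR/dq chain-ruled through the
internal normalization; torsion k: the torque formula u_k · Σ (x_a −
x_axis) × g_a over the distal atoms).  The gradient is validated against
central finite differences (h = 1e-5) at random states.  Because the
trilinear interpolant is only C0 across cell faces and the
hydrophobic/h-bond terms are piecewise linear, finite differences are a
valid oracle only away from those loci; gradient tests reject probe
states whose FD stencil would straddle a face or kink (the analytic
gradient is still defined everywhere via the one-sided limit).

### Optimization

BFGS maintains a dense inverse Hessian, initialized to the identity at
every call, with the standard rank-two update.  Numerical guards the
update formula itself does not address: the update is skipped when the
curvature s·y ≤ 1e-12·|s||y| (it divides by (s·y)²), and a non-descent
direction resets to steepest descent with a fresh identity matrix.  The
exact line minimization is replaced by Armijo backtracking (c = 1e-4,
halving from α = 1, at most 10 trials); α = 0 terminates the call.
Termination: 30 iterations (configurable; refinement doubles it),
gradient norm < 1e-6, or a failed line search.  Accepted energies are
monotone by construction, so a BFGS call never returns a higher energy
than it was given.

### Monte-Carlo loop

Each thread iterates `search_depth` times: mutate exactly one uniformly
chosen POT block (position by ±2 Å per axis clamped to the box;
orientation by a uniform random-axis rotation; one torsion resampled
uniformly), BFGS-optimize and score, then accept by the Metropolis rule
P = 1 for improvements, exp(Δe/1.2) otherwise.  The first iteration of
every thread accepts unconditionally, guaranteeing each thread leaves
its random start; on acceptance the pose is optimized a second time, and
that second result replaces the current pose only if it does not
increase the energy (the pseudo-code this implements is ambiguous on the
point; this reading preserves descent).  Rejected candidates leave the
comparison energy at the current accepted pose.  The thread tracks the
best pose it ever scored.

### Host-side aggregation

All per-thread best poses are sorted by energy (ties broken by thread
index for stability) and greedily de-duplicated at 1 Å RMSD (the
AutoDock-family clustering convention; configurable).  The top 20 poses
are re-minimized *grid-free* — direct receptor pair sums with a doubled
iteration budget — which removes the interpolation error from the
reported minima; a refined pose replaces the original only if its
grid-free energy does not increase.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `thread` | 8000 | – | converged setting for medium/large complexes; desk-scale examples use 64 |
| `search_depth` | heuristic | iterations | `max(1, floor(0.24 Natom + 0.29 Nrot − 3.41))` |
| `metropolis_constant` | 1.2 | kcal/mol | acceptance temperature of the Vina-family rule |
| `position_amplitude` | 2 | Å | mutation step; common Vina-family practice |
| grid `spacing` | 0.375 | Å | AutoDock-family convention |
| `dedup_rmsd` | 1.0 | Å | clustering radius |
| `k_out` | 20 | poses | refined/reported pose count |
| BFGS `max_iters` | 30 (60 refine) | iterations | sufficient on the fixture complexes at desk scale |

`search_depth` resolution precedence in the CLI is explicit flag >
config file > heuristic.

## The synthetic fixtures

`make_planted_complex(natom, nrot, seed)` builds a chain-topology ligand
laid out on a compact helix (≈1.5 Å consecutive spacing, coordinates
quantized by the PDBQT writer so the planted pose is exactly
representable) and a receptor pocket constructed around the planted
coordinates: one contact-distance partner atom per ligand atom (carbon
partners at zero surface distance; donor/acceptor partners for the
ligand's polar anchors at d = −0.35 Å, inside the hydrogen-bond well),
plus a 48-atom outer carbon shell placed in the mid-range attractive
well.  The polar anchors at the chain ends and mid-chain break the
orientational symmetry of the pocket, and the outer shell widens the
energy funnel so that gradient-based local search from random starts
inside the box (planted extent + 4 Å) can reach the planted basin — the
generator's purpose is a *solvable-by-construction* problem whose
global minimum is known, and generation optionally verifies that the
planted pose scores at or below 10⁴ random conformations.

What the fixtures emulate: a funnel-shaped binding site with specific
polar contacts, realistic interaction magnitudes (pocket depth a few
kcal/mol), torsional flexibility, and exact PDBQT round-tripping.  What
they do not emulate: real protein geometry and chemistry (no backbone,
no charge distribution, no solvent), rugged multi-funnel landscapes,
ring flexibility, or symmetric ligands.  Passing the planted-recovery
tests therefore demonstrates that the search/score/optimize machinery is
correct and well-coupled, not that the scoring function ranks real
complexes accurately — that property belongs to the adopted potential,
not to this implementation.

`make_ranked_universe(n, overlap, seed)` builds two rankings of n
synthetic compound ids whose top-decile Jaccard index approximates
`overlap`, for exercising the screening-comparison utilities; at other
depths the overlap is not controlled.

## Problem sizes and numerical choices

The test suite and acceptance script run on the (12, 2) planted complex
(its heuristic depth is 1): pose recovery uses 64 threads over 20 master
seeds, and the thread/depth trade-off compares (10 threads × depth 22)
against (100 threads × depth 2) — the published depth pairs for a
22365-iteration budget scaled by one tenth, the package's desk-scale
budget choice.  Stochastic outcomes are asserted as rates over fixed
seed sets (recovery ≥ 90% of 20 seeds at < 2 Å RMSD; best-energy
agreement within 0.5 kcal/mol — the conventional score-comparability
margin — in ≥ 80% of 10 seeds), never as single-run values.

Degenerate inputs are defined behaviour: rigid ligands (Nrot = 0) skip
torsion mutation and have empty torsion vectors; a constant energy field
yields zero gradient and an immediately stationary BFGS; zero poses
write an empty file with a warning; duplicate config keys keep the last
value with a warning.  Quaternion construction normalizes and rejects
near-zero norms; mutation chains preserve unit norm to 1e-9.

## Known limitations

* Rigid receptor only; no flexible side chains, no solvation or charge
  terms beyond the adopted table.
* RMSD is computed in the given atom order without optimal superposition
  or symmetry correction, so symmetric ligands can over-report RMSD.
* Bond inference by distance can mis-join atoms in pathological
  geometries; real pipelines would carry connectivity.
* Threads are executed serially in R; the concurrency contract is
  reproducibility, not wall-clock parallel speed.  The `acceleration()`
  utility only reports runtime ratios measured externally.
* The dense inverse Hessian is fine at 7 + Nrot ≲ 30 but would not scale
  to very flexible ligands; an L-BFGS variant is out of scope.
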