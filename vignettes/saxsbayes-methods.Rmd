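---
title: "Bayesian SAXS restraints with automatic weighting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian SAXS restraints with automatic weighting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsbayes)
```

# The problem

Small-angle X-ray scattering (SAXS) measures a one-dimensional intensity
profile $I(q)$ of a macromolecule in solution, with per-point uncertainties
$s(q)$ estimated from merged exposures.  For a multidomain protein whose
domain structures are known but whose relative arrangement is not, SAXS can
restrain the arrangement — if the restraint is weighted correctly against
the other energy terms.  That weight is the crux: it depends on data
quality, on the forward model's systematic error, and on how far the
current structure is from fitting, none of which are known in advance.

`saxsbayes` treats the weight as a Bayesian nuisance parameter.  Given a
structure $X$ with model intensities $m_i = m(X, q_i, c_1, c_2)$, scale
factor $\gamma$ and error scale $\sigma$, the negative log likelihood of a
profile with $M$ points is

$$
-\log p \;=\; \frac{M}{2\sigma^2}\,\chi^2(\gamma) \;+\; M \log\sigma,
\qquad
\chi^2(\gamma) = \frac{1}{M}\sum_{i=1}^{M}
\Big(\frac{I_i - \gamma\, m_i}{s_i}\Big)^2 .
$$

Both nuisance parameters have closed-form optima: $\hat\gamma$ is the
error-weighted least-squares scale and $\hat\sigma^2 = \chi^2(\hat\gamma)$.
The factor $M/2\sigma^2$ multiplying $\chi^2$ is the *effective weight* of
the restraint.  Because $\sigma$ tracks the current misfit, the weight is
small while the structure is far from the data (letting other terms steer
sampling) and grows as the fit improves — an automatic annealing schedule.
Without the $M\log\sigma$ term the score would be trivially minimized by
$\sigma \to \infty$; with it, the optimum sits at $\sigma^2 = \chi^2$.

Marginalizing $\sigma$ under a Jeffreys prior $p(\sigma) \propto 1/\sigma$
(flat priors on $\gamma$, $c_1$, $c_2$ within bounds) gives the
parameter-free score $(M/2)\log\chi^2$, which ranks structures identically:
the package exposes both (`neg_log_likelihood()`, `marginal_score()`).
These prior choices are stated assumptions of this implementation; they
reproduce both the $\hat\sigma^2 = \chi^2$ stationarity and the
log-$\chi^2$ marginal form, and the test suite verifies the closed forms
against numeric minimization to $10^{-8}$.  $\chi^2$ is always computed on
the linear intensity scale with the experimental errors.

A practical consequence worth spelling out: at $\hat\sigma$ the weight is
$M/2\chi^2$, so halving $\chi^2$ doubles the weight.  During refinement the
weight trace is exactly reconstructible from the $\sigma$ trace, and the
package asserts that identity across stage boundaries of the composite
workflow.

# Forward model

Model intensities come from an exact Debye double sum over heavy atoms,

$$
m(X, q) = \sum_{i,j} f_i(q)\, f_j(q)\,
\frac{\sin(q d_{ij})}{q d_{ij}},
$$

with $\operatorname{sinc}(0) = 1$ handled explicitly.  The per-atom factor
combines three terms in the FoXS spirit:

* **Vacuum scattering** — 4-Gaussian-plus-constant Cromer–Mann
  coefficients for H, C, N, O, S, P.  Over the SAXS range
  ($q < 0.5\,\text{Å}^{-1}$) these agree with more elaborate
  parameterizations to well below the other model errors; the table's
  $f(0)$ reproduces each element's electron count within 1%.
* **Excluded volume** — a Gaussian dummy atom of the element's displaced
  solvent volume (Fraser convention, $\rho_0 = 0.334\,e/\text{Å}^3$),
  scaled by $c_1^3 \exp\!\big[-(4\pi/3)^{3/2} q^2 r_m^2 (c_1^2-1)/4\pi\big]$
  where $r_m$ is the molecule's mean dummy-atom radius.  $c_1 \in
  [0.95, 1.05]$ adjusts the total excluded volume through an effective
  atomic radius.
* **Hydration layer** — a water form factor placed on each atom weighted
  by its solvent-accessible surface fraction (Shrake–Rupley, probe 1.8 Å,
  64 sphere points — a deliberate speed/accuracy compromise; the tests
  compare against a 512-point evaluation) and by $c_2 \in [-2, 4]$, the
  density contrast of the hydration shell.

Hydrogens are excluded; their electrons and displaced volumes are folded
into the bonded heavy atoms through a name-based table for standard
protein atoms (bare-element fallback otherwise).  This is an
approximation: unusual atom names fall back to the bare element and lose
their implicit hydrogens.

Bead (coarse-grained) models carry a flat per-bead factor $f_0$, a
displaced volume and a radius, and run through the identical machinery;
outputs are flagged as coarse-grained.  The implementation is checked
against an independent double-loop oracle at $10^{-10}$ relative error and
against the two-scatterer closed form $2f^2(1 + \sin(qd)/qd)$.

$c_1$ and $c_2$ are optimized by the staged grid search used during
docking: an $11\times11$ grid over the full admissible ranges; a second
$11\times11$ grid centred on the best pair whose total span covers four
cells (a $2\times2$ block) of the first; a third round with half that
span.  Before every cell evaluation $\gamma$ and $\sigma$ are reset to
their maximum-posterior values.  Ties keep the first cell in row-major
(c1-major) order; refinement grids are clipped to the admissible ranges.
The search is a quantized estimator: recovery of generating values is
asserted to within its own final grid spacing, which is the information
it can deliver.

# Samplers

Structure determination is staged (docking → clustering → linker
construction → dihedral refinement), each stage driven by the same energy:
the SAXS restraint at current nuisance parameters plus a quadratic
excluded-volume penalty $\sum k (r_i + r_j - d_{ij})^2$ over clashing
pairs (pairs within one rigid body, and covalently adjacent residues, are
excluded; $k = 1$ score-unit/Å², standard van der Waals radii — the data
do not determine $k$, so it is a convention).

**Rigid-body docking** (`rigid_dock()`) alternates blocks of Metropolis
rotation/translation proposals of the mobile domain (Gaussian, 0.05 rad
and 0.05 Å by default — the magnitudes are deliberately read as applying
to both move types) with deterministic maximum-posterior updates of
$\gamma$ and $\sigma$ and, on a configurable cadence, the $c_1/c_2$ grid
search (`"step"`, `"start"`, or `"never"`; per-step optimization is the
docking default, refinement never re-optimizes them).  Temperature is
fixed at 1 — the scores are negative log probabilities, and the automatic
$\sigma$ adjustment already provides the annealing.  Starting poses are
uniformly random orientations on an enlarged enclosing sphere, rejected
until clash-free.  A window of 100 steps with zero acceptances logs a
stall warning but never aborts: stalling is diagnostic of a mis-weighted
restraint, which is exactly what the fixed-weight control runs
(`fixed_weight_run()`) are for.

**Dihedral refinement** (`dihedral_refine()`) proposes Gaussian
perturbations of one randomly chosen rotatable dihedral per move (0.05 rad
for termini, 0.005 rad for linker segments), rebuilding all downstream
atoms by rigid rotation about the bond axis, so covalent geometry is
invariant by construction (the tests assert bond-length drift below
$10^{-9}$ Å).  For Cα-only chains the virtual bonds play the role of the
backbone dihedrals.  Because downstream rotation carries the second
domain, refinement adjusts domains and linker jointly.

Nuisance parameters are *set* to their optima rather than sampled — the
samplers are maximum-posterior optimizers in the nuisance subspace, a
deliberate simplification matching the staged protocol.  All runs are
bit-reproducible given their seed.

# Pose clustering

Final docking poses are summarized by a 7-dimensional descriptor: the
mobile domain's centre of mass in a reference frame that superposes the
fixed domain onto its template, plus the unit quaternion rotating the
mobile template onto the mobile domain.  The map metric is

$$
d(n, m) = \lVert \mathbf{c}_n - \mathbf{c}_m \rVert
+ \frac{2 d_{\max}}{\pi} \arccos\left|\langle q_n, q_m\rangle\right|,
$$

with $d_{\max}$ the largest space diagonal of the bounding box of the
training descriptors' centres of mass, computed once and frozen.  The
absolute dot product folds the quaternion double cover ($q$ and $-q$ are
one rotation); dots within $10^{-12}$ of 1 are snapped to 1 so
self-distance is exactly zero.  No weighting beyond the $d_{\max}$ scaling
is applied.  A classic online SOM is trained under this metric: centres of
mass move by linear interpolation, quaternions by shortest-arc slerp with
renormalization.  The training schedule (10 epochs, learning rate 0.5 →
0.01 linearly, neighborhood radius max(shape)/2 → 1 exponentially) is a
package choice — the procedure itself does not prescribe one — and is
configurable.  Poses are reconstructible from neurons (templates placed by
quaternion and centre of mass, clash-flagged), and map "clusters" are
produced by connected-component labeling of non-empty neurons under a
user-supplied distance threshold, replacing a visual reading of the map
with something reproducible.

# Linker construction

Missing linkers are built in the Cα representation first: positions are
initialized on a circular arc between the anchor atoms whose arc length
matches the chain's natural length $(n+1)D$, $D = 3.86$ Å, bowed away
from the domains (a straight line when the chain is taut), pushed out of
obstacle exclusion spheres, then minimized — 1,000 steepest-descent steps
followed by 1,000 conjugate-gradient steps — under harmonic virtual-bond
restraints at target $D$ and one-sided excluded-volume restraints: linker
Cα contact $D$ among themselves, $1.5 D$ against obstacle atoms (whose
effective diameter $2D$ pushes the linker outside the protein during this
stage).  Obstacle atoms in an anchor's covalent neighbourhood keep only
the plain contact $D$, since the chain must attach there.  Harmonic force
constant 10 score-units/Å² and clash tolerance 0.01 are conventions.

All-atom placement initializes backbone atoms (and optionally Cβ —
side chains beyond Cβ are off by default, since the scattering model
tolerates coarse models and this stage's purpose is geometric
plausibility) uniformly in a sphere of diameter $D$ around each Cα, then
minimizes in two phases (250 SD + 1,000 CG each): bonded terms only, then
bonded terms plus clashes.  Bond angles are enforced as 1–3 distance
restraints (law of cosines at ideal peptide geometry with uniform force
constants) — geometrically equivalent for this purpose and much simpler
than torque-based angle gradients; the full bonded parameter set of a
simulation force field is deliberately not reproduced.  Models are
accepted only with every restrained bond within 5% of ideal and no
residual clash; rejected models are retried with a new seed.  Termini
grow one residue at a time with random φ/ψ at planar trans peptide
geometry, resampling any residue that clashes.

# The synthetic study system

Every stage is exercised on generated data (`make_two_domain_system()`,
`simulate_profile()`, `make_profile_pool()`), emulating a two-domain
protein at one bead per residue: two compact bead clusters of distinct
sizes (so the pose is identifiable), an optional flexible linker, and
profiles $I = \gamma\, m(X, q) + \varepsilon$ with
$s(q) = 0.01\,I(q) + 10^{-4} I(0)$ and $\varepsilon \sim N(0, s(q))$ —
noise chosen unit-consistent so $\chi^2 \approx 1$ at the truth and
$\hat\sigma \approx 1$ is the recovery target.  Bead defaults: 50
electrons, 100 Å³ displaced volume, radius $D/2 = 1.93$ Å (half the Cα
virtual bond, keeping the generator consistent with the linker model's
excluded-volume convention).  The generator builds its own linker with
the same Cα-path construction the pipeline uses, so generated systems
satisfy ideal linker geometry by construction.

Two deliberate choices keep the toy conditions in the regime the staged
method assumes:

* The *experimental* profile of a workflow test comes from the full
  (linker-bearing) system while docking models only the domains — as in
  a real application.  The linker is kept a modest fraction of the
  scattering mass (4 of 36 beads); a dominant flexible fraction makes the
  domains-only docking objective so biased that its poses are not useful
  starting points, which is a limitation of the staged protocol itself,
  not of the implementation.
* The ensemble-selection pool contains a family of interconverting decoys
  plus two structurally extreme planted states (compact and extended,
  mixed 70/30).  Smooth single-family pools are nearly collinear in
  profile space, and *no* selector can then pin member-level weights —
  the degeneracy the per-group weight reporting exists for.

What the generator does **not** emulate: beam smearing, buffer-subtraction
artifacts, inter-particle structure factors, detector noise correlations,
and atomic-level side-chain detail.  Passing tests therefore demonstrate
the estimators' and samplers' correctness and calibration on well-posed
inputs, not robustness to real-data systematics.

# Ensemble selection

From a pool of per-conformer profiles, `ensemble_chi2()` fits a mixture
$I_{\text{calc}} = \text{scale}\cdot\sum_k w_k I_k$ by error-weighted
nonnegative least squares (Lawson–Hanson) and reports
$\chi^2 = \frac1M \sum_i \big[(I_{\text{calc},i} - I_{\text{exp},i})/s_i\big]^2$.
The criterion as written carries no scale factor, but the weights are
explicitly fitted quantities, so a global scale is profiled out by
default; `fit_scale = FALSE` gives the literal unscaled form.  The genetic
algorithm (`run_ga()`) evolves member sets with tournament selection (size
2), member-id crossover at rate 0.8, an expected one member replacement
per offspring ("mutation frequency of one" is read per offspring, with a
per-gene mode available), and elitism of one — the selection operator is
otherwise unspecified, and tournament-with-elitism is the standard
reproducible choice.  Fitness values are memoized over member sets.
`size_scan()` repeats the GA per ensemble size and reports mean, sd and
minimum $\chi^2$; identical members in a degenerate fit fall back to a
uniform split with a warning.

# Numerical choices and degenerate inputs

* $\sigma$ floor $10^{-6}$ on exact fits (logged); $\chi^2 = 0$ in the
  marginal score uses the same floor.
* A non-positive $\hat\gamma$ (model anti-correlated with data) warns
  rather than errors: it signals broken data, not a broken call.
* Grid-search cells with non-finite scores are skipped with a warning;
  an all-non-finite grid is an error.
* Near-unit quaternion dots are clamped (and snapped within $10^{-12}$)
  before `acos`.
* Steepest descent uses backtracking step control (halve on increase,
  grow 1.2× on success) so the descent property holds exactly;
  conjugate-gradient phases delegate to `stats::optim(method = "CG")`.
* Profile resampling exists for fixture construction only; model-data
  comparisons always evaluate the forward model on the experimental grid.

# Problem sizes used by the test suite

The suite runs the full staged protocol at desk scale, chosen so every
stochastic property is measured rather than assumed: docking convergence
over 20 seeds at 25 steps × 10 moves; a 200-step fixed-weight stall run; a
7-point fixed-weight ladder at 60 steps; SOM separation on 300 descriptors
and a 15×15 map; linker geometry over 10 seeds; GA recovery on a
50-conformer pool at population/generations 200; and an end-to-end
workflow with 2 docking replicas, an 8×8 map and 250 refinement steps.
Full-protocol defaults (64 replicas × 500 steps, 50×50 map, 2,000
refinement steps) remain the package defaults and scale down with one
`scale` argument.

# Known limitations

* Single-dataset restraints only: simultaneous profiles would each need
  their own $\sigma$.
* The forward model is formula-faithful to the published corrections but
  not bit-compatible with FoXS or CRYSOL; no multipole expansion, no
  explicit hydration shell.
* Nuisance parameters are optimized, not sampled; posterior uncertainty
  on $\gamma$, $\sigma$, $c_1$, $c_2$ is not propagated.
* The excluded-volume term is a soft-sphere penalty, not a force field;
  linker conformations are geometrically plausible, not energetically
  ranked.
* Ensemble-size selection is by inspection of the $\chi^2$-vs-$k$ curve;
  no evidence-based model selection is provided.
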