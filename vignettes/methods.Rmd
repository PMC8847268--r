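---
title: "Methods: EDL-based inverse electrocardiography with a His-Purkinje multi-wave initial estimate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EDL-based inverse electrocardiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Body-surface potential maps (BSPM) are linear in the cardiac sources but
the map from *activation times* to potentials is not: each ventricular
node contributes a transmembrane-potential upstroke delayed by its local
activation time (LAT) $\delta$. Estimating $\delta$ from a multi-lead
surface recording — inverse electrocardiography — is therefore a
non-convex, severely ill-posed problem: many activation sequences produce
nearly identical BSPMs, especially during normal sinus rhythm, where the
His-Purkinje conduction system launches several near-simultaneous
endocardial wavefronts whose far-field contributions partially cancel.

`edlwave` implements the two-step strategy this package is organized
around: (1) a physiology-constrained **initial estimate**, and (2) a
local **Levenberg-Marquardt refinement** of nodal LATs. Two initial
estimators are provided: the novel **multi-wave** search over nine
His-Purkinje-associated endocardial regions, and the older **multi-focal**
additive search used as a baseline.

## Source and volume-conductor model

The cardiac source is an equivalent double layer (EDL) on the closed
ventricular surface (epicardium + endocardium + base). Node $n$ carries a
dipole-layer strength proportional to a logistic upstroke
$s(t-\delta_n)$, $s(u) = A/(1+e^{-u/\tau})$ with amplitude
$A = 100$ mV and $\tau = 1$ ms. Only the upstroke matters inside the QRS
window, so repolarization is omitted. A closed layer of uniform strength
is externally silent; all observable signal comes from the *spread* of
$\delta$ — this cancellation property is asserted to $10^{-6}$ in the
tests and is the mechanism behind the partial cancellation of
simultaneous wavefronts.

Potentials are propagated through a piecewise-homogeneous torso
(thorax 0.2 S/m, lungs 0.04 S/m, blood pools 0.6 S/m) with the boundary
element method: vertex collocation, linear (1/3-lumped) analytic
solid-angle weights (van Oosterom–Strackee), principal-value diagonals
fixed by the closed-surface identity, and rank-one deflation of the
singular insulated-boundary operator. The myocardial surface carries the
sources but is not a conductivity interface (0.2 S/m on both sides).
Under this EDL normalization the transfer matrix depends only on
conductivity *ratios*; a global conductivity scaling leaves it unchanged.
The BEM is validated against the closed-form Legendre series for a
current dipole inside a homogeneous sphere (relative RMS error ≈ 0.2% at
the resolution used in the tests; the acceptance bound is 2%).

## Activation model

Activation times are computed with the fastest-route algorithm (FRA):
multi-source earliest arrival on the surface graph, augmented with
"second-ring" shortcuts (for each interior edge, the edge connecting the
two opposite triangle vertices) to reduce metrication error. Edge speed
follows the elliptical group-velocity law
$v(\theta) = v_\ell v_t / \sqrt{v_t^2\cos^2\theta + v_\ell^2\sin^2\theta}$
with $\theta$ the angle between the edge and the local fiber direction
and $v_t = v_\ell / 2$ (anisotropy ratio 2). Defaults: $v_\ell$ =
0.85 mm/ms, raised to 1.7 mm/ms within 15 mm (graph distance, not chord
distance, to avoid cross-cavity leakage) of any active focus, emulating
the fast sub-endocardial layer near Purkinje-myocardial junctions. The
FRA is checked for exact agreement against an independent Dijkstra
implementation (`igraph::distances`) on the same weighted graph.

## Multi-wave initial estimation

Nine candidate-origin regions are anatomically defined: the insertions of
the two LV papillary muscles and the RV moderator band (vertex *sets*, all
nodes of the insertion activated together), four LV septal regions
(inferior third; superior antero-septal third; two evenly spaced between
— the anatomical placement rule for the two intermediate positions is
qualitative, so they are spaced evenly along the base–apex axis) and two RV septal
regions (near the apex, mid-wall), the septal ones as 10 mm-radius vertex
sets. Step 1 sweeps each region's candidate foci against an
initial-timing grid (0–35 ms for structures, 0–25 ms for septal regions,
5 ms steps — the ranges are stated, the step is our choice) and keeps the
(focus, $t_0$) maximizing the Pearson correlation between computed and
recorded BSPM. Step 2 enumerates all $2^9 - 1 = 511$ non-empty subsets
of the nine chosen candidates; each subset is *re-simulated* jointly so
the velocity boost covers the union of active foci (not a pointwise
minimum of cached sequences), gated to a total activation duration within
85–115% of the measured QRS duration (boundaries inclusive: the exclusion
rule is strict), and ranked by correlation. Ties prefer fewer foci, then
lexicographic group order, so runs are deterministic. If every subset is
gated out the best ungated candidate is returned with a warning rather
than failing.

## Multi-focal baseline

The fundamental search tests every candidate vertex as a single origin,
tuning a uniform conduction velocity so the total activation duration
matches the QRS duration (travel times scale as $1/v$, so one unit-speed
FRA run per candidate suffices), capped at 2.5 mm/ms. Up to six foci are
then added greedily (timing grid 0–QRS, improvement threshold $10^{-4}$
on correlation), keeping the fundamental's velocity — only the
fundamental is duration-matched. Candidate sets default to every vertex
on meshes up to 2000 nodes and farthest-point subsamples beyond that;
the tests use sparser deterministic subsamples to stay within budget.

## Refinement

The refinement iteratively minimizes
$\lVert V - \phi(\delta)\rVert_F^2 + \mu^2 \lVert L\delta \rVert_F^2$
by Levenberg-Marquardt with an analytic Jacobian (column $n$ is the outer
product of column $n$ of the average-referenced transfer matrix with the
upstroke derivative at $t - \delta_n$; the Gauss-Newton Gram matrix
therefore factorizes into an elementwise product of two small Gram
matrices). $L$ is the dimensionless umbrella surface Laplacian
(row-stochastic adjacency minus identity). The conventional value
$\mu^2 = 5\cdot10^{-6}$ is quoted in units (mV² ms² m⁻²) that presuppose a
particular, unstated Laplacian discretization; the default keeps the
numerical value against the dimensionless operator, at which scaling the penalty is indeed "very small" relative to
the data term. Two robustness guards matter in practice and are
documented choices of this package: damping is floored at $10^{-3}$ of
the largest curvature, and any step moving a node by more than 25 ms is
rejected with increased damping — without them, descent steps along
near-null directions (nodes barely visible at the electrodes) move those
nodes by hundreds of milliseconds while still marginally decreasing the
objective. Accepted steps are monotone non-increasing in the objective;
iteration stops at a relative decrease below $10^{-4}$ or at the
25-iteration cap. With $\mu^2 = 0$ the truth is an exact fixed point; with
$\mu^2 > 0$ electrode-invisible nodes drift a few ms toward the smooth
consensus, which the tests bound rather than deny. The refined $\delta$
is deliberately *not* re-projected onto FRA-realizable sequences, so the
refinement can perturb local velocities.

## Evaluation machinery

* BSPM match: Pearson correlation over concatenated entries and relative
  difference $\lVert V-\phi\rVert_F / \lVert V\rVert_F$.
* Inter-map comparison: Pearson correlation and mean absolute LAT
  difference over the vertices with reference data, after shifting the
  estimate so the earliest masked LATs coincide (no common clinical time
  reference exists for phantoms).
* Triangulation conduction velocity: per-triangle in-plane LAT gradient
  from the two edge equations under a locally-planar wavefront; speed is
  the inverse gradient magnitude. Exact on affine LAT fields (tested).
  Speeds above 5 mm/ms are excluded (the breakthrough-correction variant
  at 3 mm/ms is exposed as a parameter).
* Breakthroughs: the field never had a formal definition, so this package
  operationalizes one — clusters of vertices that are minimal within a
  10 mm graph-distance ball, retained when at least 5 ms deeper than the
  surrounding LAT just outside the ball. A constant map has zero
  breakthroughs; a single-focus map has one.
* EAM handling: landmark-initialized rigid ICP (Kabsch, $\det R = +1$
  enforced, no scaling), projection of points to the nearest triangle with
  a 10 mm exclusion, then assignment of each point to the nearest vertex
  of its snapped triangle and per-vertex averaging. The nearest-vertex
  (rather than whole-triangle) assignment is what makes projection of
  self-generated data exactly recoverable.

## The phantom: what it emulates, and what a green test establishes

The synthetic world is a torso ellipsoid (electrodes by farthest-point
sampling, 67 by default, mirroring a 67-lead BSPM montage), two lungs,
and a watertight biventricular source surface: an epicardial
half-ellipsoid plus two cavity half-ellipsoids joined by a
zipper-triangulated base annulus, with shrunken capped cavities as blood
pools. Fibers are rule-based circumferential (long axis × normal).
Papillary/moderator-band insertions are *marked vertex sets*, not
protruding geometry. A seeded parametric jitter breaks the exact
ellipsoidal symmetry so that no test accidentally relies on it; the
phantom is bit-reproducible for a fixed spec.

The phantom produces realistic *structure* (nested closed surfaces,
mV-scale potentials, physiological conduction parameters) but not
realistic *data*: no torso inhomogeneity beyond lungs/blood, no noise
unless requested, fibers far simpler than myocardial truth, and — because
the source surface is a closed sheet — no transmural septal conduction,
which stretches activation durations beyond clinical QRS widths for
sparse foci. A green recovery test therefore establishes algorithmic
self-consistency (the estimator finds the truth its own forward model
generated), not clinical accuracy.

### Identifiability of subset recovery

Noiseless subset recovery asks step 1 to identify each true
(focus, $t_0$) from a multi-wave mixture. Experiments with the phantom
show a clear gradient: simultaneous-onset truths over the three
*structure* groups (whose insertion vertex sets leave no within-group
ambiguity) are recovered exactly with winning correlation 1.0; truths
containing a septal region are still recovered as subsets, but the chosen
septal focus may be a within-region neighbour of the true vertex
(correlation ≈ 0.998); arbitrary staggered timings or four overlapping
waves can lose a shadowed wave for under $10^{-3}$ of correlation, and
the duration gate cannot separate candidates when all 511 durations are
dominated by the same slow far wall. This is
the ill-posedness the method is designed around, not an implementation
defect; the acceptance experiment uses the simultaneous-onset truth, and
near-simultaneous onset is also the physiological regime of the
His-Purkinje system.

## Numerical choices

* Solid-angle sign convention: outward normals; a closed surface subtends
  $-4\pi$ from inside, 0 from outside. Asserted to $10^{-9}$.
* Mains removal: spectral notch (zero the bins within ±2 Hz of the mains
  frequency). An IIR notch of equivalent bandwidth rings for hundreds of
  samples on windowed beats; the FFT notch is transient-free and any
  spectrally equivalent filter is acceptable here. Baseline drift:
  natural cubic spline through the lowest-RMS-decile (isoelectric)
  samples; resampling by natural cubic interpolation.
* Correlation scoring may decimate the recorded sample grid
  (`sample_stride`) — ranking is insensitive to 2–4 ms sampling and the
  tests use strides 2–4 to stay inside their budget.
* Duration-gate boundaries are inclusive with a $10^{-9}$ relative guard
  so exact 85%/115% candidates survive floating-point rounding.
* Electrode snapping: the phantom references electrodes by thorax vertex
  id, so no snapping tolerance applies; `volume_conductor` validates ids.

## Known limitations

Surface-only propagation (no transmural shortcuts); QRS-only scope (no
repolarization); the multi-focal additive search is quadratic in
candidates × timing grid and is the slow path, as expected; breakthrough
counting and the EAM projection rule are package operationalizations of
procedures the field leaves informal; clinical benchmark figures (inter-map correlations against invasive
maps, absolute LAT differences) require patient recordings that have no
public deposit and are out of scope for the test suite.
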