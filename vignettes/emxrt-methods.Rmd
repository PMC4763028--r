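---
title: "Energy-modulated photon planning: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-modulated photon planning: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emxrt)
```

This vignette is the package's own account of its models: what is assumed,
which knobs matter, which conventions were genuinely open and how they were
fixed, and what the passing test suite does and does not demonstrate.

## Beam model

Megavoltage photon depth doses are represented by their printed anchors —
depth-at-percent pairs on the falling branch and percent-at-depth values
including the surface dose — rather than by a physics parameterization.
`fit_pdd()` interpolates the buildup and falloff branches separately with
Fritsch–Carlson monotone cubics joined at *d*max (a single spline through
all anchors overshoots 100 at the peak, where the secant slopes change
sign), and continues beyond the deepest anchor with an exponential fitted
to the last two anchors. This guarantees anchor fidelity (every anchor is
reproduced exactly, hence well within the 1-percentage-point and 0.2 cm
test tolerances), monotonicity on both branches, and a defined value at any
depth the selector's exit-point convention may request.

Two surface-dose sets exist in the benchmark data: Monte Carlo values (for
example 36.1% at 6 MV) and substantially higher chamber-measured values
(63.7%). The selector operates on the simulated curves, so the Monte Carlo
values are the anchors; measured values are retained as metadata only and a
user can fit curves from them by building a `pdd_anchors` object directly.

Lateral profiles are a flat core with an error-function penumbra of width
`sigma` (0.3 cm up to 6 MV, 0.4 cm at 10 MV — typical megavoltage penumbra
widths at depth). Horn-shaped in-field unevenness is deliberately not
modeled: the inverse planner's beamlet weights absorb any in-field fluence
structure, so a flatness model would add parameters without changing the
optimized plans.

## Phantoms and geometry

Phantoms are voxel grids of relative electron density with named logical
masks; density is assigned by region label (water 1.0, lung 0.25, bone 1.4,
air 0.001), not by CT-number calibration. The calibration geometry of the
energy selector — a water slab with a spherical target of diameter TS
centered at depth EP — is generated by `make_selector_phantom()` and is
exact by construction. Three patient-like archetypes (`lung_like`,
`deep_pelvic`, `brain_like`) provide heterogeneity, deep targets and
OAR-abutting targets respectively; their structure positions are jittered
by a few millimetres from an integer seed so that generation is
reproducible without being degenerate. The archetypes emulate the *scale*
and *composition* of real anatomy, not its shapes: passing tests on them
shows the pipeline handles heterogeneity and deep geometry correctly, not
that clinical plan quality on real CT data is achieved.

Defaults: 2.5 mm isotropic spacing for planning-quality grids, 1 mm for
geometry unit tests (the voxelized sphere volume converges to the analytic
volume as spacing shrinks; tests check the error halves from 2 mm to
1 mm). Gantry angle 0 enters anteriorly, angles increase clockwise viewed
from the feet, SAD is 100 cm.

Ray tracing uses an exact parametric voxel walk; water-equivalent lengths
are line integrals of density over the traversed segments. The four
characteristic points are the first/last body and target crossings. When a
ray crosses the target twice, point 2 is the first entry, point 3 the last
exit, and TS integrates density only over the in-target subsegments. EP
always terminates at the isocenter, even when the isocenter is not the
target center. Depths are reported from the body entrance, so point 1 is at
depth 0 by definition.

## The energy selector's open conventions

The four-point correlation score leaves three genuine choices open, fixed
here as follows and exposed as arguments:

* **Score form.** The score is typeset without an explicit square root in
  its denominator, but its name, its scale invariance and its unit maximum
  all argue for the cosine form
  `sum(w * D * d) / sqrt(sum(D^2) * sum(d^2))`, which is the default. The
  literal unrooted form (`form = "literal"`) and a centered Pearson-style
  form (`form = "centered"`) are available.
* **Exit-point depth.** The thickness of the calibration water phantom
  behind the target is not specified anywhere; the default places the body
  exit at `2 * EP`, i.e. an isocentric, symmetric phantom. Any function of
  (EP, TS) can be supplied instead.
* **Weight placement.** The point weights appear in the numerator only, as
  typeset.

The deep-target override is applied at EP ≥ 18 cm: the printed look-up
table shows 10 MV throughout its EP = 18 column, so the threshold is
inclusive even though the accompanying text says "> 18 cm". Table cells
require EP strictly greater than TS/2 (a target touching the skin is not a
valid scenario), ties in the score break toward the lower energy, and table
look-ups for traced beams snap to the nearest grid node with ties toward
the smaller value.

Under these defaults the regenerated table reproduces the printed
reference's structure — the 10 MV override block exactly, no 2 MV cell
anywhere, energies nondecreasing with depth for almost all rows — but
agrees cell-by-cell in only about half of the 243 populated cells
(`compare_energy_table()` reports the per-cell score margins; most
disagreements are one energy step with margins below 0.03). The exact
printed table evidently depends on the full shape of the underlying depth
doses between the printed anchors and on the unstated exit convention; none
of the score-form × exit-depth combinations examined during development
reproduces more than ~70% of cells, and the combinations that score higher
than the default also select 2 MV in populated cells, which the reference
explicitly excludes. Cell-level reproduction of the printed table is
therefore *not* claimed; the structural properties above are the tested
contract.

## Dose engine

Dose deposition coefficients use a deterministic divergent pencil-beam
kernel in place of Monte Carlo beamlet scoring: for voxel *i* and beamlet
*j*,

a(i, j) = PDD(wed) / 100 × OAR(u − cᵤ) × OAR(v − cᵥ) × (SAD / t)²,

where `wed` is the water-equivalent depth of the voxel's projection onto
the beamlet axis (density integral from the skin, no lateral heterogeneity
correction — the standard first-order pencil beam), (u, v) are the voxel's
beam's-eye-view coordinates at the isocenter plane, and the lateral profile
is applied separably in u and v. Separability matters: square beamlets with
a radial profile do not tile, and the open-field composite would ripple by
roughly ±9%; with the separable erf profile the composite open field
reproduces the input PDD to better than 1% beyond *d*max (tests allow 3%).
Each beam is normalized so its open-field composite equals 1 at
water-equivalent *d*max on the central axis, evaluated analytically so the
normalization does not depend on the voxel grid. Entries below 1e-4 of
their column maximum are dropped and recorded as such in the matrix
metadata; dose stays in these relative units until plan normalization.

## Inverse planner

The objective is the quadratic prescription misfit over target voxels plus
`r`-weighted dose-volume penalties with violation flags. Flags follow the
standard DVH-gating construction: for an upper constraint (p, v%) the
voxels between p and the current dose at volume v% are flagged — the
allowed hottest v% is left alone — and symmetrically for lower constraints.
The target's two default constraints are a lower bound at 0.98 p₀ and an
upper bound at 1.08 p₀, each with a 5% volume allowance; the source
formulation fixes *two* target constraints but never prints their bounds,
so these are conventions, not reproductions, and are fully configurable.

Optimization is projected steepest descent: the search direction is always
the negative gradient (flags frozen per iteration, a subgradient
convention), the trial step is the spectral Barzilai–Borwein length (the
exact Cauchy step of the flag-frozen quadratic at restarts), and a
monotone Armijo backtracking line search plus projection onto x ≥ 0
safeguards every step, so the recorded objective history is nonincreasing
at fixed r by construction. Plain halving backtracking satisfies the same
contract but needs roughly an order of magnitude more iterations on the
planning instances. The penalty factor starts at 1 and doubles every 20
iterations by default ("increasingly severe" is the only guidance given);
convergence is declared after the relative objective change stays below
1e-5 for 5 consecutive iterations at the current r, with a 500-iteration
default cap and an optional wall-clock limit. The 0/1 aperture
initialization (beamlets whose axis crosses the target) is rescaled once so
the mean target dose matches the prescription — the weights are in
arbitrary relative units, and without the rescale the first hundred
iterations just recover the dose scale.

One caveat documented from the validation work: with a margin ring of
beamlets around the aperture, the target-only least-squares problem is
nearly consistent (optimal objectives of order 0.01 Gy² for a 50 Gy
prescription, i.e. sub-0.01 Gy RMS residuals), and on that near-degenerate
tail first-order methods stall at a small multiple of the optimum even
though the resulting *plans* are indistinguishable (coverage tests pass
with the full beamlet set). The oracle-agreement tests therefore compare
objectives on well-determined instances — aperture-only beamlet sets and
random overdetermined problems — where the match with an independent
bound-constrained quadratic solver is within 1%.

## Plan evaluation

DVHs are stored as exact sorted voxel doses; binning (0.05 Gy) exists only
for export. D\_q% is the inverse empirical CDF with linear interpolation
between order statistics (`quantile(type = 7)`) — the interpolation
convention is never stated in the source material, and this choice makes
re-normalization exactly idempotent: after `normalize_plan()`, PTV D95%
equals the prescription to machine precision. The integral dose is reported
both as the mean normal-tissue dose in Gy and as the Gy·L volume integral,
because published comparison tables are ambiguous between the two
conventions; reports label both and assert neither as canonical. Report
rounding follows the published style: doses to 1 decimal, HI to 2,
relative differences to 1.

Of the 82 printed index pairs used to validate `relative_difference()`, 72
reproduce the printed percent change exactly at one decimal, 7 differ by
exactly one unit in the last digit (consistent with the authors rounding
higher-precision inputs before printing), and 3 are internally inconsistent
by more than that; the tests assert the 79 and exclude the 3.

## Problem sizes

Unit tests run at 2–5 mm spacing on phantoms of 10⁴–10⁵ voxels. The
planning acceptance case is a five-beam water slab of about 43,000 voxels
with 180 beamlets (80 in the aperture-only variant), chosen so the full
chain — tracing, dose matrices, optimization, evaluation — completes in
about a minute on a single core while keeping the target sampled by
hundreds of voxels.

## Known limitations

* No Monte Carlo transport: interface build-down/build-up, lateral scatter
  disequilibrium in lung, and collimator leakage are absent; the pencil
  beam applies water-equivalent depth along the beamlet axis only.
* The energy look-up table reproduces the printed reference structurally,
  not cell-by-cell (see above).
* Archetype phantoms approximate patient scale, not patient anatomy; no
  DICOM import.
* The optimizer is first-order by design; on nearly-consistent
  least-squares instances it returns plans, not certified minimizers (the
  objective may sit a small multiple above the true optimum while the dose
  distribution differs by less than 0.01 Gy RMS).
* A single energy per gantry angle; the 15 MV extension is possible through
  user-supplied anchors but is not part of the default pool.
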