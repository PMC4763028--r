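# emxrt

Desk-scale toolkit for **energy-modulated photon radiotherapy (EMXRT)
planning**: instead of planning every beam of an intensity-modulated
treatment at one fixed energy, EMXRT selects a (possibly different) nominal
energy from a 2–10 MV pool for each gantry angle before the beamlet weights
are optimized. The package implements the whole chain on synthetic voxel
phantoms: beam modelling from benchmark water-phantom data, ray tracing,
per-angle energy selection, pencil-beam dose calculation,
dose-volume-constrained inverse planning, and plan evaluation.

## The methods in brief

**Beam model.** Each energy's central-axis percent depth dose (PDD) is a
monotone shape-preserving interpolant through published Monte Carlo
water-phantom anchors (10 × 10 cm² field, SSD 100 cm), normalized to 100 at
the depth of maximum dose *d*max, with a fitted exponential tail beyond the
last anchor. Beam quality is summarized by
TPR₂₀,₁₀ = %D(20)/%D(10), which increases from 0.446 (2 MV) to 0.627
(10 MV) across the pool.

**Energy selector.** For a beam with water-equivalent effective path length
EP (skin → isocenter) and tumor size TS (target entrance → exit), four
characteristic points are read off the PDD: skin (depth 0), target entrance
(EP − TS/2), target exit (EP + TS/2) and the body exit. The candidate
energy's four doses d = (d₁…d₄) are scored against the ideal template
D = (10, 100, 100, 10) % with point weights ω = (0.5, 1, 1, 1) by the
correlation-coefficient score

CC = Σᵢ ωᵢ Dᵢ dᵢ / √(Σᵢ Dᵢ² · Σᵢ dᵢ²),

and the energy with the maximal CC wins; deep targets (EP ≥ 18 cm) always
receive 10 MV, and EP < TS/2 is geometrically invalid. Tabulating the
selection over EP = 2…21 cm × TS = 2…16 cm yields the energy look-up table
used to assign energies per gantry angle from ray-traced (EP, TS).

**Inverse planning.** Dose is linear in the beamlet weights x through the
dose deposition matrix A (1 × 1 cm beamlets, divergent pencil-beam kernel):
dᵢ = Σⱼ aᵢⱼ xⱼ. Weights minimize the quadratic objective

F(x, r) = Σᵢ∈T (dᵢ − p₀)² + r Σₖ ωₖ Σᵢ∈T δᵢ (dᵢ − pₖ)²
        + r Σₙ ωₙ Σₖ ωₙₖ Σᵢ∈OARₙ δᵢ (dᵢ − pₙₖ)²

by projected steepest descent (x ≥ 0) from the beam's-eye-view aperture
initialization, with the dose-volume violation flags δᵢ recomputed each
iteration and the penalty factor r escalated on a fixed schedule. Plans are
normalized so the prescription isodose covers 95% of the target, then
evaluated through DVHs: Dmean, D2%, D50%, D95%, D98%,
HI = (D2% − D98%)/D50%, VxGy and the normal-tissue integral dose.

## Worked example

```r
library(emxrt)

beams <- default_beams()               # fit the 2-10 MV pool from packaged data
beams$curves[["6"]]
#> <pdd_curve> 6 MV: dmax 1.5 cm, surface 36.1%, TPR20,10 0.579

# a 4 cm tumor centered 6 cm deep in a water slab
ph <- make_selector_phantom(EP = 6, TS = 4, thickness = 12)
trace_four_points(ph, beam_ray(0, ph$isocenter))
#> <four_point_trace> skin 0.0, target 4.00-8.00, exit 12.00 cm; EP 6.00, TS 4.00 cm

sel <- select_energy(6, 4, beams = beams)
round(attr(sel, "scores"), 4)
#>      2      3      4      5      6     10
#> 0.8035 0.8423 0.8644 0.8825 0.8909 0.9002
```

The trace confirms the phantom geometry (the ray enters the skin at depth
0, crosses the target between 4 and 8 cm, EP = 6 and TS = 4 cm), and the
selector's per-energy scores show how the CC ranks the pool for that
scenario. A full plan — energy assignment, dose matrix, optimization,
normalization and a metric panel — runs through one call:

```r
cfg <- run_config(phantom = list(archetype = "lung_like", seed = 7, spacing = 0.5),
                  gantry_angles = c(0, 40, 320), energy_mode = "auto",
                  prescription = 50)
res <- run_pipeline(cfg)
res$assignment              # per-angle EP, TS and selected MV
subset(res$metrics, structure == "PTV")   # D95% = 50 by construction
```

`compare_plans()` joins two such metric panels (for example an
energy-modulated run against a fixed 6 MV run) and reports the relative
difference 100 × (A − B)/B per structure and index.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/emxrt.R select --ep 9.9 --ts 5.4
Rscript inst/cli/emxrt.R table --out energy_table.csv
```

## Scope

Synthetic phantoms only: densities are assigned by region label, and no
DICOM/CT import is provided. The dose engine is a deterministic divergent
pencil-beam kernel — not a Monte Carlo transport code — so build-down at
interfaces, scatter tails and leaf transmission are out of scope. See the
methods vignette (`vignettes/emxrt-methods.Rmd`) for the model assumptions,
parameter defaults and known limitations.
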