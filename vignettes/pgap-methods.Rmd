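---
title: "Pareto-navigation calibrated automated planning: models and methods"
author: "pgap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pareto-navigation calibrated automated planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Overview

`pgap` implements a protocol-based automatic iterative optimisation (PBAIO)
planning engine together with a multi-dimensional Pareto-navigation
calibration layer, and exercises both end-to-end on procedurally generated
prostate phantoms.  The package covers the full chain:

1. **phantom** — labelled voxel anatomy (targets, organs at risk, planning
   target volumes) on a regular grid;
2. **dose engine** — a beamlet influence matrix for an arc of coplanar
   beams and the linear dose model `d = D x`;
3. **protocol** — the priority-structured planning-goal data model with
   quadratic penalty functions and dose falloff thresholds;
4. **pbaio** — the planning loop: inner projected-gradient fluence
   optimisation plus dynamic positioning and dynamic weighting of the
   trade-off objectives;
5. **pareto** — exhaustive sampling of a navigation grid, multilinear
   interpolation of the navigated dose, calibration commit and averaging;
6. **metrics** — the DVH metric panel (Dx%, Vd Gy, mean/max, homogeneity
   index, Paddick conformity index) with the PTV subtraction convention;
7. **study** — paired cohort comparison with an exact Wilcoxon signed-rank
   test, a calibration-propagation experiment, and a synthetic end-to-end
   evaluative study.

Everything is deterministic given its seeds; no clinical data is read or
required.

# Coordinate conventions

One convention is used everywhere: axis 1 is left-right (x), axis 2 is
anterior-posterior (y) with **+y posterior**, axis 3 is inferior-superior
(z) with +z superior.  Voxel centres sit symmetrically about the grid
centre; all lengths are millimetres and all doses Gy.

# The phantom

The anatomy emulates a prostate-only cohort treated with a 60 Gy in 20
fraction simultaneous-integrated-boost schedule: prostate and up to 2 cm of
proximal seminal vesicles as targets; rectum, bladder and (institution-B
profile) femoral heads and bowel as organs at risk.  The default grid is
64 x 64 x 48 voxels at 4 mm — deliberately coarser than a clinical CT so a
complete plan optimises in seconds on one CPU; spacing and grid are
configurable and several studies in this package use 48^3 at 4 mm, which we
found the best speed/fidelity compromise for cohort-scale experiments.

The body is an elliptic cylinder (semi-axes 90% of the grid half-extent, so
anatomy scales with the grid).  The prostate is an ellipsoid whose
semi-axes are jittered per patient by uniform draws (+-2 mm) from the
patient seed; the rectum is a posterior tube whose anterior wall is tangent
to — face-adjacent to, never overlapping — the prostate surface, because
the clinical margin recipe (0 mm posterior expansion for the boost volume)
only makes sense for abutting anatomy.  The bladder sits
superior-anterior.  The seminal-vesicle lobe extends 20 mm (configurable)
superiorly from the prostate; the clinical definition gives only an upper
bound ("up to 2 cm proximal"), so the default length is a documented choice
rather than a claim of fidelity.

PTVs follow the margin recipe exactly: PTV60 = prostate + 5 mm (0 mm
posterior); PTV57.5 = prostate + 10 mm (5 mm posterior); PTV48 =
(prostate + vesicles) + 10 mm; all clipped to the body.  Margin expansion
uses voxel-centre distance with ellipsoidal interpolation between the six
axis margins — the common treatment-planning-system behaviour, and directly
verifiable against a brute-force distance oracle (the test suite does
exactly that).  Because each directional margin of PTV60 is no larger than
the corresponding PTV57.5 margin, the nesting PTV60 within PTV57.5 within
PTV48 holds by construction and is asserted on every generated patient.

What the phantom does **not** emulate: CT intensities, tissue
heterogeneity, deformable anatomy, hip prostheses, inter-fraction motion.
Passing tests therefore demonstrate the correctness of the planning
machinery on plausible geometry, not clinical dosimetry.

# The dose engine

The clinical study this package mirrors used a commercial treatment
planning system as its dose/optimisation substrate.  Here the substrate is
the simplest physically plausible linear model that makes the
target-coverage versus organ-sparing trade-off real: an influence matrix
for `n_beams` static beams equispaced over 360 degrees (default 36,
approximating a single full VMAT arc).  Beamlets tile the target's
beam's-eye-view bounding box (8 mm pitch, 10 mm margin), and a beamlet
deposits

```
output_scale * exp(-mu_atten * depth) * exp(-lateral^2 / (2 sigma_lateral^2))
```

at a voxel, with `depth` the distance from the body surface along the beam
(per beamlet-aligned ray bin) and `lateral` the in-plane plus axial offset
from the beamlet axis.  The constants `mu_atten = 0.005/mm` and
`sigma_lateral = 4 mm` are **non-clinical**: they produce a ~1.4 Gy/mm
achievable penumbra and depth-dependent attenuation, which is all the
optimisation layer needs.  Entries below `1e-4 * output_scale` are dropped,
keeping the matrix ~2% dense.  Rows outside the body are identically zero.

Plans are normalised post-optimisation by a single scale factor so the
PTV60 median dose (D50%) equals the 60 Gy prescription, for both
institution profiles (the source protocol states this rule for one
institution only; applying it uniformly makes cross-profile metrics
comparable and is flagged here).

# The protocol model and penalties

Goals carry a priority (P1 critical / P2 target / P3 trade-off), a type, a
target with units (`Gy`, `%Presc,PTV` = percent of the ROI's own PTV
prescription, `%Presc` = percent of the 60 Gy overall prescription, `%Vol`),
and — for P3 — a stored weighting factor (WF), the quantity that Pareto
navigation calibrates.  The two shipped protocol fixtures encode the final
calibrated goal sets of the two institution profiles, including their
differences (removed low-weight rectum/bladder goals, added bowel goals,
the 54.6 vs 54.0 Gy intra-PTV falloff high level).

Penalty functional forms are not specified by the source description, so the
package uses the standard differentiable one-sided quadratics,
volume-normalised over the goal region `N`:

* `min_dose`: `sum(max(0, T - d_v)^2) / N`;
* `max_dose`, conformality and falloff ceilings: the mirrored form, with a
  per-voxel threshold `max(low, high - g * dist)` for falloff goals
  (distance from the source region in cm, gradient `g` in Gy/cm resolved
  from `%Presc`/cm);
* `mean_dose`: `max(0, mean - T)^2`;
* `dv_max` (a `V_dGy <= V%` ceiling): of the voxels above the dose level,
  the hottest `floor(V% * N)` are allowed; the remaining *lowest-dose
  violating tail* is penalised toward the level.  This tail rule is the
  standard DVH-objective construction; contributions vanish continuously as
  a voxel's dose crosses the level, and tied voxels contribute identically,
  so the penalty is continuous in dose.
* `median_max` ("D50% ceiling") is implemented as a `dv_max` at 50% volume
  with the dose level at the resolved target — a median ceiling.

Gradients are the exact analytic partials of these forms and are verified
against central finite differences in the test suite.

Three region choices deserve emphasis:

* **Falloff source regions.**  The external normal-tissue falloff measures
  distance from the union of the PTVs and applies on body-minus-PTVs; an
  intra-PTV falloff measures distance from the next-higher-prescription PTV
  and applies on the goal's PTV minus all higher PTVs.  The degenerate
  PTV57.5 falloff with `high = low = 54 Gy` becomes a uniform 54 Gy ceiling
  on PTV57.5 minus PTV60 — implemented exactly so.
* **P2 goals on nested PTVs act on subtraction regions** (the PTV minus all
  higher-prescription PTVs): a 104.9%-of-48-Gy ceiling on the whole of
  PTV48 would contradict the 60 Gy boost it contains.  This mirrors the
  reporting convention used for D98%/D2%/HI.
* **Max-dose goals** are optimised with the one-sided quadratic over the
  whole region (continuous and differentiable, satisfying the gradient
  contract) rather than on a near-max sub-region whose membership would
  change discontinuously with dose; reporting provides both the true voxel
  maximum and the D1% near-max.

# The planning loop

`autoplan()` runs `outer_loops` rounds (default 8) of: inner fluence
optimisation, dynamic positioning, dynamic weighting; then a final inner
pass and normalisation.  The inner optimiser is projected gradient descent
on the nonnegative orthant with a Barzilai-Borwein initial step and a
monotone backtracking line search — accepted steps never increase the
objective, and the whole loop is bit-reproducible.

**Dynamic positioning (the delta rule).**  After each pass, every P3 goal
with a dose-volume, mean or max parameter has its objective target moved to
`max(0, achieved - delta)`: 2 percentage points for volume parameters, 1 Gy
for dose parameters (both configurable; the source description fixes only
that the offset is constant, so the defaults are package choices applied
globally per unit kind, with per-goal override possible through the config).
This ratchet is what keeps driving organ-at-risk doses down even when every
nominal target is already met.

**Dynamic weighting.**  Each P3 optimiser weight is scaled per loop by
`clip(((WF * penalty) / tau)^alpha, 1/rho, rho)` with `alpha = 0.5`,
`rho = 4`.  The fixed point is `WF * penalty = tau`: a goal with a large
stored WF is allowed only a small residual penalty, which is exactly what
makes WF the cross-patient balancing knob.  Two numerical choices matter
here and were set by analysing the loop's equilibrium:

* `tau = 1` (the `penalty_target`).  The delta rule re-positions targets
  just below the achieved values each loop, so steady-state penalties are
  of order `delta^2 ~ 1` in these units.  A much smaller `tau` puts every
  goal permanently above its fixed point, the clip saturates, and all P3
  weights grow geometrically (`rho^L`), drowning the *fixed* P2 weight of
  250 and destroying target coverage; a much larger `tau` collapses all P3
  weights to nothing, making the stored WFs — the quantity navigation
  calibrates — inert.
* `weight_span = 2`: the adapted weight is additionally kept within
  `[WF/span, WF * span]`.  This trust region preserves the P1 (1000) >
  P2 (250) > P3 hierarchy, keeps every navigated trade-off responsive to
  its WF over the full navigation range, and still satisfies the bound
  `weight in [w0 * rho^-L, w0 * rho^L]`.

**Equilibrium and the PTV57.5 corridor.**  The shipped protocol
intentionally contains a contradiction: the PTV57.5 ring carries a P2
minimum-dose floor of 56.75 Gy *and* a P3 uniform falloff ceiling of
54.0 Gy on the same voxels.  The loop settles in the corridor between the
two (ring median above 54 Gy, RMS deficit below the floor of 1.5-2%), which
is also where the clinical results this package mirrors sit.  Goal
satisfaction is therefore asserted as root-mean-square violation over the
goal's optimisation region — the natural measure for volume-normalised
quadratic objectives — at 1.5% of the resolved target for every P2 goal
except that one, which gets the corridor check.

# Pareto navigation

A navigation dimension is any goal parameter — a WF or a target — with 2-7
strictly increasing sampled values.  `generate_dataset()` runs `autoplan`
for the full cartesian product of sampled values (first dimension fastest),
sharing the influence matrix and configuration so plans differ only through
the navigated parameters.  Exhaustive sampling grows as the product of the
sample counts, so more than four dimensions triggers a warning.

`interpolate()` reconstructs the navigated dose by multilinear
interpolation over the enclosing grid cell (no extrapolation).  Because
interpolation is linear and voxel-wise, it commutes with every linear
functional of dose — mean doses, fixed-voxel values — and corner weights
sum to one; both identities are tested.  WF dimensions interpolate in the
raw parameter value; since calibrated WFs span orders of magnitude,
log-spaced *sample values* are the sensible choice for wide ranges and can
be supplied directly.  Navigated doses are interpolated between
*normalised* plans (each corner plan has its PTV60 median already fixed at
60 Gy), so navigation previews live on the same scale as final plans.

`navigate_metrics()` evaluates the DVH metric panel on the interpolated
dose without re-running any optimisation (the "real-time" contract;
evaluating a hundred positions takes well under two seconds on the test
fixtures), `commit_calibration()` writes the navigated values back into the
protocol, and `merge_calibrations()` averages WFs across patients
(arithmetic by default, geometric optionally).  Sequential navigation
rounds — generate, navigate, commit, repeat on the committed protocol — are
supported directly by composing these functions.

# Metrics

`Dx%` uses descending order statistics at midpoint cumulative-volume
positions `(k - 0.5)/N` with linear interpolation, clamped at the extremes
(equivalently `quantile(type = 5)`); so D50% of doses {10, 20, 30, 40} is
25 Gy and D100% is the minimum.  `Vd` counts voxels at or above the level.
The homogeneity index is `(D2% - D98%) / D50%` — the source description
never defines HI, so this standard definition is fixed here and documented
prominently because all comparisons depend on it.  The Paddick conformity
index is `TV_PIV^2 / (TV * PIV)` with the prescription isodose volume
counted inside the body; the default reference isodose is 95% of the PTV's
nominal prescription, matching the coverage rule of the clinical goal
table.  D98%, D2% and HI on nested PTVs are reported on subtraction masks
(higher-prescription PTVs removed).  Every metric is property-tested
against a brute-force sorting oracle on random small fields.

# The study machinery

`wilcoxon_signed_rank()` follows the analysis rules of the evaluative
study: zero differences are omitted; fewer than ten remaining pairs means
"not tested"; otherwise the two-sided p value comes from exact enumeration
of all `2^n` sign assignments (average ranks for tied magnitudes) up to
n = 15 and from the tie- and continuity-corrected normal approximation
above (the crossover at 15 keeps exact enumeration under 2^15 evaluations).
Zero-difference *omission* (not midrank retention) is deliberate — it is
the stated practice of the analysis this package mirrors.

`run_utility_experiment()` reproduces the calibration-propagation design as
a synthetic analogue: a four-dimension navigation (PTV60 min-dose target,
PTV60 max-dose target, rectum mean-dose WF, external falloff WF; two
samples per dimension spanning a ten-fold WF range) on patient 1 of a
ten-patient cohort; a rectum-sparing calibration Cal1 (relaxed PTV60
targets, maximum rectum WF, minimum falloff WF) and a balanced calibration
Cal2 (the nominal protocol values) are committed and propagated to every
patient.  On the packaged phantoms this yields a strictly lower rectum mean
dose under Cal1 for every patient, with the cohort-mean homogeneity index
rising and the conformity index falling — the same trade-off signature, and
the same sign structure, as the clinical demonstration.  The experiment
runs at 48^3 / 4 mm with 24 beams and a shortened loop (30 inner
iterations, 5 outer loops), sizes chosen so a cohort completes in a few
minutes on one CPU; signs and orderings are stable under these settings.

`run_study()` is the end-to-end synthetic analogue of the evaluative
study: calibration and validation cohorts (defaults 10/20), a scripted
two-dimension navigation committed on the first calibration patient, and a
paired comparison of the calibrated protocol against a deliberately
mis-prioritised comparator (rectum WFs divided by 10).  **There is no
clinical comparator at desk scale**: the comparator arm exists to exercise
the comparison machinery — the clinical tables this package mirrors are
explicitly not reproduction targets.  Outputs are CSV tables, 1-1 scatter
plots (PNG, with PDF fallback on devices without bitmap support) and a JSON
manifest of every seed and configuration from which the run is exactly
reproducible.

# Degenerate inputs and numerical edges

Empty masks raise errors naming the structure; a zero-median plan cannot be
normalised; an empty prescription isodose volume defines CI = 0 with a
warning; positions outside the sampled navigation range refuse to
extrapolate; `dv_max` ties are handled by the documented tail rule; the
Euclidean distance transform is an exact separable lower-envelope pass per
axis (verified against brute force).  Serialisation of geometries uses
run-length-encoded masks in JSON and round-trips exactly; protocols are
strict-schema JSON in which unknown fields are errors, not warnings.

# Known limitations

The dose model has no scatter, heterogeneity or deliverability concepts,
and monitor units are out of scope; absolute organ-at-risk doses are
therefore not clinically meaningful even though their orderings and
trade-off responses are.  The phantom's anatomy is convex-ish and rigid.
Exhaustive Pareto sampling limits practical navigations to about four
dimensions; adaptive sampling is future work.  The weight-adaptation law is
a reasoned reconstruction (fixed-point multiplicative update within a trust
region) of a mechanism whose published description is qualitative; its
parameters are configurable and logged per loop precisely so that users can
study alternatives.
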