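# pgap

Automated radiotherapy treatment planning with Pareto-navigation
calibration, self-contained on synthetic prostate phantoms.

## The problem

Automated planning engines must be *calibrated*: someone has to decide how
strongly each trade-off — rectum sparing versus dose conformality versus
target homogeneity — is weighted before the engine can plan novel patients
consistently.  The usual options are trial-and-error (slow, and blind to
how metrics co-vary) or machine learning on historical plans (needs large
datasets of uncertain quality).  Pareto navigation offers a third route:
generate a small grid of plans that sample the trade-off surface, explore
it interactively by interpolating between neighbouring plans, and store the
parameter values of the preferred point as the calibration.

`pgap` implements this whole pipeline in R for medical-physics researchers
and methodologists: a protocol-based automatic iterative optimisation
(PBAIO) planning engine, a programmatic multi-dimensional Pareto-navigation
layer on top of it, the DVH metric panel and paired statistics used to
evaluate such systems — and a procedural prostate phantom generator so that
every stage runs, and is tested, without any clinical data.

## The model in brief

* **Dose**: a linear beamlet model `d = D x` with `D` a sparse influence
  matrix for an arc of coplanar beams (exponential depth attenuation,
  Gaussian lateral penumbra; deliberately simple, non-clinical constants)
  and `x >= 0` the beamlet weights.  Plans are normalised so the PTV60
  median dose D50% equals the 60 Gy prescription.
* **Objectives**: planning goals at three priorities — P1 critical
  (optimiser weight 1000), P2 target coverage/homogeneity (weight 250), P3
  trade-offs carrying a stored weighting factor `WF`.  Penalties are
  one-sided volume-normalised quadratics; dose-volume ceilings
  `V_d Gy <= V%` penalise the lowest-dose violating tail; dose falloff
  goals use per-voxel thresholds `max(low, high − g·dist)`.
* **PBAIO loop**: between optimisation passes every P3 objective is
  *re-positioned* to `max(0, achieved − δ)` (δ = 2 %Vol / 1 Gy) — a ratchet
  that keeps driving organ doses down — and *re-weighted* multiplicatively
  toward the fixed point `WF · penalty = τ`, which makes the stored WF the
  knob that balances trade-offs consistently across patients.
* **Pareto navigation**: a navigation dimension is any goal parameter (WF
  or target) with 2–7 sampled values; plans are generated for the full
  cartesian product, the navigated dose is the multilinear interpolation of
  the enclosing corner plans, and `commit_calibration()` writes the chosen
  position back into the protocol.
* **Evaluation**: Dx% / Vd Gy metrics from sorted order statistics,
  homogeneity index `(D2% − D98%)/D50%`, Paddick conformity index
  `TV_PIV² / (TV · PIV)`, PTV subtraction convention for nested targets,
  and a two-sided Wilcoxon signed-rank test with tie omission and an
  `n < 10 → not tested` rule (exact enumeration up to n = 15).

See `vignettes/pgap-methods.Rmd` for assumptions, parameter defaults and
the design decisions behind them.

## Worked example

```r
library(pgap)

# a synthetic patient: targets, OARs, PTVs on a 48^3 grid at 4 mm
geom <- build_ptvs(generate_patient(seed = 1,
          anatomy_config = list(grid_shape = c(48L, 48L, 48L),
                                spacing = c(4, 4, 4))))

# automated plan under the institution-A protocol
plan <- autoplan(geom, chhip_protocol("instA"),
                 beam_config(n_beams = 24),
                 pbaio_config(inner_iterations = 30, outer_loops = 5))
print(plan)
#> pgap_plan: 2856 beamlets, final objective 968.9, norm factor 1.0022
```

Key plan-quality metrics for that run:

```
         metric    value
1    PTV60 D98% 58.60648
2      PTV60 HI  0.05205
3      PTV48 CI  0.81750
4  Rectum Dmean 13.72805
5 Bladder Dmean 16.34753
clinical goals passed: 14 of 17
```

Read: the boost volume keeps D98% at 58.6 Gy (97.7% of prescription) with
good homogeneity (HI 0.052); the 48 Gy target is conformal (Paddick CI
0.82); the mean rectal dose is pushed to 13.7 Gy by the dynamic
positioning ratchet.  The three failed clinical-goal rows are the
PTV57.5/PTV48 median-coverage rules, which this protocol deliberately
trades against its intra-PTV falloff ceilings (see the vignette).

Calibration by navigation, in four lines:

```r
dims <- list(
  navigation_dimension("Rectum|mean_dose|", "weighting_factor",
                       c(5.84, 18.5, 58.4), label = "rectum_wf"),
  navigation_dimension("External|dose_falloff_external|",
                       "weighting_factor", c(51, 102, 204), label = "falloff_wf"))
ds   <- generate_dataset(geom, chhip_protocol("instA"), dims)
navigate_metrics(ds, c(rectum_wf = 30, falloff_wf = 150),
                 list(list(kind = "Dmean", roi = "Rectum"),
                      list(kind = "CI", roi = "PTV48", param = 45.6)))
calibrated <- commit_calibration(ds, c(rectum_wf = 30, falloff_wf = 150))
```

A thin command-line interface over the same functions lives at
`inst/cli/pgap.R` (`phantom`, `autoplan`, `evaluate`, `study` subcommands).

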