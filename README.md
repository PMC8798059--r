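# mtkinetics

Microtubule dynamic instability: simulation, synthetic TIRF imaging, and
the statistical estimators used to characterize microtubule assembly
factors.

## The problem

In vitro reconstitution assays image single microtubules growing from
GMPCPP-stabilized seeds by TIRF microscopy and quantify how a
microtubule-associated protein (MAP) changes polymer dynamics. Every
headline number in such a study is the output of a regression on
hand-measured image features:

* **Growth kinetics.** Tip velocity is linear in free tubulin,
  `v = k_a·c − k_d` (dimers/s), fitted across a tubulin series to give the
  apparent on-rate constant `k_a` (dimers µM⁻¹ s⁻¹), off-rate `k_d`
  (dimers s⁻¹) and critical concentration `C_c = k_d / k_a` (µM), the
  concentration at which net elongation stalls.
* **Templated nucleation.** The probability that a seed nucleates a
  microtubule within one minute follows an endpoint-constrained Hill law,
  `p(c) = c^s / (C^s + c^s)`, with half-max concentration `C` and
  steepness `s`.
* **Spontaneous nucleation.** Per-field microtubule counts are zero below
  a critical tubulin concentration and linear above it; the fitted
  x-intercept is the spontaneous critical concentration.
* **Catastrophe frequency.** Growth→shrinkage switches per unit of total
  growth time, with a bootstrap confidence interval over filaments.
* **Seed depolymerization.** GMPCPP seeds shrink at a constant speed
  (µm/min) measurable over hours of slow imaging.

`mtkinetics` is for people who make or check such measurements. It
implements the full chain — a stochastic dynamic-instability simulator, a
synthetic TIRF kymograph/field renderer (107 nm pixels, Gaussian PSF,
Poisson shot noise), automated tip tracking with penalized change-point
phase segmentation, and all of the estimators above — so that the analysis
can be validated end to end as *parameter recovery*: simulate under known
parameters, analyze blind, and require the fits to return the generating
values. A bundled condition table carries fitted parameters for a
tubulin-alone control and several concentrations of CKAP2, a spindle MAP
that raises `k_a` ~54-fold and lowers both critical concentrations
~100-fold.

## Worked example

The closed-form layer is exact: under the control law
(`k_a = 2.6`, `C_c = 2.89`), the net velocity at 8 µM tubulin is

```r
library(mtkinetics)
p <- condition_params("control")
growth_velocity(8, p)
#> [1] 0.49056        # um/min  (13.286 dimers/s at 1625 dimers/um)
```

and a noiseless concentration series returns the law to machine precision:

```r
fit <- fit_growth_kinetics(data.frame(
  tubulin_uM = c(5, 8, 11, 14),
  growth_rate_um_min = growth_velocity(c(5, 8, 11, 14), p)))
fit
#> Growth kinetics (linear regression of mean growth rate vs tubulin)
#>   k_a = 2.6 +/- 7.5e-16 dimers uM^-1 s^-1
#>   k_d = 7.514 +/- 7.6e-15 dimers s^-1
#>   C_c = 2.89 +/- 2.1e-15 uM
```

A full stochastic run — simulate trajectories, render kymographs, track
tips, segment phases, fit everything — is one call. Here the control
condition only, 40 filaments per tubulin concentration (about 20 s):

```r
res <- run_pipeline(run_config(seed = 1,
  growth = list(conditions = "control",
                tubulin_uM = list(control = c(5, 8, 11, 14)),
                n_filaments = 40, duration_s = 600),
  templated = list(conditions = "control",
                   tubulin_uM = list(control = c(2, 4, 6, 8, 10, 12, 16, 20)),
                   n_seeds = 150, t_max_s = 120),
  spontaneous = list(conditions = "control",
                     tubulin_uM = list(control = c(26, 30, 35, 40, 45, 50)),
                     n_fields = list(control = 20)),
  depolymerization = list(conditions = "control", duration_min = 600,
                          frame_interval_min = 1, initial_length_um = 10)))
report(res)
#> == Pipeline results ==
#> -- growth --
#>   control      k_a            = 2.585 +/- 0.00511 dimers/uM/s
#>   control      k_d            = 7.501 +/- 0.0514 dimers/s
#>   control      C_c            = 2.902 +/- 0.0146 uM
#>   control      f_cat @ 5 uM   = 0.07173 +/- 0.014 1/min
#>   ...
#> -- templated_nucleation --
#>   control      hill_C         = 7.164 +/- 0.0701 uM
#>   control      hill_s         = 3.437 +/- 0.108
#> -- spontaneous_nucleation --
#>   control      slope          = 1.976 +/- 0.0466 MT/field/uM
#>   control      critical_conc  = 25.62 +/- 0.345 uM
#> -- depolymerization --
#>   control      v_depoly       = 0.01301 um/min
#> seed 1, config 3a198cc499820fabb01ff75e6311a21b
```

The generating parameters were `k_a = 2.6`, `C_c = 2.89`, Hill
`C = 6.85`, `s = 3.37`, spontaneous critical concentration `25.4`,
depolymerization `0.013` — each recovered within a few percent through the
full imaging loop (`C_c` within 0.4%, the depolymerization rate within
0.1%). The catastrophe-frequency rows illustrate a documented resolution
limit: dips briefer than the frame interval allows go uncounted, so
detected frequencies at low tubulin undershoot the generating 0.3 min⁻¹
(see the methods vignette).

Individual stages are exported and composable: `sample_trajectory()`,
`render_kymograph()`, `track_tip()`, `segment_phases()`,
`summarize_dynamics()`, `nucleation_ecdf()`, `fit_nucleation_hill()`,
`catastrophe_frequency()`, `count_field_microtubules()`,
`curvature_intensity()`, and friends. Fits are classed objects with
`print`, `coef`, `summary`, `predict`, `plot` and `residuals` methods.
Event tables and condition tables round-trip as tab-separated text; images
round-trip as multi-page TIFF with a YAML calibration sidecar.

See `vignettes/microtubule-dynamics.Rmd` for the model, the estimators,
the tracking/segmentation design choices, and what the synthetic data do
and do not establish about real data.

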