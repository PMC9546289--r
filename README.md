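# afmforce

Analysis of atomic force microscopy (AFM) force–distance curves for
single-cell and single-molecule biomechanics, written for studies that ask
how a molecular perturbation — here, the edited (Q→R) versus unedited form
of the actin crosslinker Filamin A — changes cell stiffness, cell–matrix
adhesion and the mechanical stability of a single protein domain.

The package covers three measurement modes behind one curve container:

* **Cell indentation.** Approach curves are baseline/tilt-corrected,
  contact-point fitted and converted to an indentation axis
  δ = (z₀ − z) − F/k; the Young's modulus comes from Hertz theory with the
  Sneddon extension for four-sided pyramidal indenters,

  F = E/(1 − ν²) · (tan α / √2) · δ²,

  fitted over a fixed 500 nm depth with ν = 0.5; the indentation at 1 nN
  is read from the data alongside.
* **Adhesion.** Retract curves are integrated between the zero-force point
  and the detachment point, W_Adh = ∫ F(z) dz, reported in femtojoules,
  with detachment found by the mirrored contact-point algorithm and
  discrete ruptures counted.
* **Polyprotein unfolding.** Sawtooth traces of a 3×I27–FLNA22–4×I27
  construct are decomposed into peaks; each rising edge is fitted with the
  worm-like chain law F(x) = (k_BT/p)[¼(1−x/Lc)⁻² − ¼ + x/Lc] at fixed
  persistence length p = 0.4 nm; events are classified by contour-length
  increment (FLNA ≈ 30.4 nm vs I27 ≈ 27.3 nm), traces pass explicit
  acceptance rules, and speed dependence follows Bell–Evans kinetics
  k(F) = k₀·exp(FΔx/k_BT).

Because no instrument data ship with the package, a synthetic-curve
generator with known ground truth stands in for the microscope: every
stage is validated by parameter recovery, and population statistics
(lognormal fits with the analytic mode exp(µ−σ²) as the "most probable
value", percentile summaries, kernel densities, exact Mann–Whitney tests)
reproduce the reporting style of cell-mechanics studies.

## Worked example

```r
library(afmforce)
set.seed(1)
cfg <- indentation_sim_config(modulus_mode = 1.88, noise_sd = 5)
cur <- simulate_indentation_curve(E = 2, cfg)   # ground truth: E = 2 kPa
fit <- fit_hertz(preprocess_curve(cur), cfg$geometry)
print(fit)
#> <hertz_fit> E = 2.001 kPa (alpha = 18 deg, nu = 0.5, depth 500 nm, n = 411)
#>   indentation at 1000 pN: 1276.1 nm
```

The fitted modulus recovers the simulated 2 kPa to 0.05% at 5 pN noise;
1276 nm is the depth at which this soft cell reaches the 1 nN setpoint
(stiffer cells indent less). A full two-group study — simulate two cell
populations, preprocess, fit, compare — is one call:

```r
st <- run_stiffness_study(seed = 42)  # modes 1.88 vs 2.72 kPa, 500 curves each
print(st)
#> <stiffness_study> seed 42, 1000 curves (1000 passing QC)
#> <group_comparison> youngs_modulus_kPa: FLNAQ vs FLNAR
#>   FLNAQ      n= 500  mean 2.766  median 2.298  mode 1.712
#>   FLNAR      n= 500  mean 4.07  median 3.358  mode 2.424
#>   delta (% of FLNAQ): mean +47.2%, median +46.1%, mode +41.6%
#> Mann-Whitney (normal_approximation): U = 78044, n = 500/500, p = 8.469e-25 ***
write_study_results(st, "results/stiffness")   # CSV tables + JSON report
```

The recovered modes track the realized 50-cell populations to ~0.1%; their
scatter around the configured 1.88/2.72 kPa reflects drawing 50 cells per
group. `run_adhesion_study()` and `run_unfolding_study()` do the same for
the other two modes.

Curves round-trip through a documented plain-text container (FDC-TSV) via
`write_curve()`/`read_curve()`, and study file sets are described by a CSV
manifest (`read_manifest()`, `load_manifest_curves()`).

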