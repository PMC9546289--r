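---
title: "Models and methods: AFM force spectroscopy with afmforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: AFM force spectroscopy with afmforce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmforce)
```

afmforce analyses atomic force microscopy (AFM) force-distance curves in
three measurement modes -- live-cell indentation, single-cell adhesion and
single-molecule polyprotein unfolding -- and ships a synthetic curve
generator with known ground truth so that every stage of the pipeline is
verifiable by parameter recovery. This vignette explains the models, the
parameters that matter, the numerical choices, and what the simulations do
and do not establish about real data.

Units are fixed package-wide: nm, pN, s, K; Young's moduli in kPa; work of
adhesion in fJ (1 pN nm = 1e-6 fJ). Piezo height decreases during approach
and increases during retract, so `z0 - z` is travel past contact on the
approach.

## Cell elasticity: Hertz theory with the Sneddon pyramidal extension

Post-contact force on the approach follows

$$F = \frac{E}{1-\nu^2}\,\frac{\tan\alpha}{\sqrt 2}\,\delta^2,$$

with Young's modulus $E$, Poisson ratio $\nu = 0.5$ (the cell treated as
incompressible), pyramid face angle $\alpha$ and indentation
$\delta = (z_0 - z) - F/k$, i.e. piezo travel past the contact point minus
the cantilever deflection at spring constant $k$. The model assumes small
indentations (below roughly 10% of cell height), isotropy and an
infinitely hard indenter; cells are viscoelastic bodies, so $E$ is an
effective elastic stiffness at the chosen loading rate, not a material
constant.

The pipeline is deliberately two-step, mirroring standard practice:

1. **Baseline**: an iteratively reweighted linear fit (3-MAD trimming) over
   the first half of the approach removes offset and tilt and estimates the
   force noise SD. The non-contact fraction is configurable
   (`baseline_fraction`); the default 0.5 assumes the operator started the
   ramp well above the cell, which the generator's default pre-contact span
   (4--6 um of a 7.5 um curve) guarantees.
2. **Contact point**: a two-stage detector. The candidate is the start of
   the last run of samples that stays above `threshold * noise_sd`
   (default 3 sigma, absolute floor 0.5 pN, minimum run of 10 samples so
   isolated noise spikes cannot fake a contact). Refinement minimises the
   residual sum of squares of a piecewise model -- zero force before $z_0$,
   the quadratic law in *deflection-corrected* indentation after -- over a
   candidate window reaching 500 nm behind and 150 nm ahead of the
   candidate (on soft samples the noise threshold is crossed long after
   true contact), followed by parabolic sub-sample interpolation. The
   window is evaluated on a fixed sample set so RSS values are comparable
   across candidates.
3. **Fit**: $E$ is the only free parameter, so the least-squares fit over
   $\delta \in [0, 500\,\mathrm{nm}]$ is the closed-form regression of $F$
   on $\delta^2$ through the origin; $z_0$ is held fixed from step 2 (no
   joint refit). Curves that do not reach the fit depth raise a
   `shallow_curve` condition. The indentation at 1 nN is read from the
   data by linear interpolation at the first crossing, not from the fit.

Default face angle is 18 degrees, a typical value for the soft
silicon-nitride probes used for cells; it is configurable because probe
batches differ and the analysis scales only through the prefactor
$\tan\alpha/\sqrt2$.

The automated QC (noise, contact, monotonicity, saturation, drift flags
with explicit thresholds) replaces manual outlier screening; every
threshold is reported per curve so batch runs leave an audit trail.

## Adhesion: detachment point and work of adhesion

For retract curves of a cell-adhesion experiment the package computes

$$W_\mathrm{Adh} = \int_{z_\mathrm{zero}}^{z_\mathrm{DP}} F(z)\,dz$$

by trapezoidal integration between the retract zero-force point and the
detachment point. The baseline comes from the farthest 20% of the retract
-- after detachment, the only region guaranteed force-free. The detachment
point is the last position where the force is still below
`-threshold * noise_sd`, interpolated to its return to the baseline band
(the contact-point idea, mirrored). By default only the adhesive
(negative-force) part contributes; positive excursions between ruptures
count as zero rather than negative work, with a `signed = TRUE` option
because the integral's sign handling is a genuine modelling choice.
Discrete ruptures are counted as upward force steps exceeding
`max(20 pN, 5 * noise_sd)` inside the adhesive region. The constant-height
pause segment is excluded from integration.

## Protein unfolding: worm-like chain sawtooths and Bell-Evans kinetics

Sawtooth retract traces of a 3xI27--FLNA22--4xI27 polyprotein are analysed
with the worm-like chain (WLC) interpolation force law

$$F(x) = \frac{k_BT}{p}\left[\frac14\left(1-\frac{x}{L_c}\right)^{-2}
  - \frac14 + \frac{x}{L_c}\right],$$

at fixed persistence length $p = 0.4$ nm (the effective value for a
stretched polypeptide backbone; never fitted in the standard pipeline, a
free-$p$ mode exists for diagnostics only). The extension axis is
tip-sample separation, $x = z - F/k$: deflection-corrected, which is the
physically correct coordinate for the WLC regardless of what coordinate a
given instrument exports.

Peaks are local maxima of a lightly smoothed trace above
`max(30 pN, 5 * noise_sd)`, pruned by a required inter-peak force drop
(25% of the lower peak); each peak's rising edge (preceding valley to
peak) is fitted for $L_c$ alone by bracketed 1-D minimisation over
$(\max x, 10 \max x)$. Peak force is the maximum measured force on the
rising edge, not the WLC model value.

**Contour-length increments and attribution.** The length released by the
domain unfolding at peak $i$ appears in the edge of peak $i+1$, so the
forward difference $L_{c,i+1} - L_{c,i}$ is attributed to event $i$. The
final detachment peak closes the series: it supplies the last edge and is
excluded from domain counting. Events are classified by increment windows,
30.4 +- 1.5 nm for FLNA repeat 22 and 27.3 +- 1.5 nm for titin I27
(non-overlap enforced); two true events closer than the resolvable spacing
merge into one detected event whose increment is a clean multiple of
27.3 nm and stays unclassified rather than guessing.

**Acceptance rules.** A trace is accepted if it shows at least 4
I27-classified events, at most one FLNA event, and -- where an FLNA event
is present -- the weak-before-strong ordering: no stronger I27 peak
precedes it. Each rule is individually switchable; rejection is a result,
not an error. Summaries are always produced for accepted traces and for
all traces, because which population enters published force statistics is
an analysis choice worth keeping visible.

**Bell-Evans kinetics.** Domains unfold with force-dependent rate
$k(F) = k_0 \exp(F\Delta x / k_BT)$, giving a most probable unfolding
force $F^* = (k_BT/\Delta x)\ln(r\Delta x/(k_0 k_BT))$ at loading rate
$r$; `bell_evans_force()` is the analytic oracle against which the
simulator is validated, with the local loading rate computed from the
series stiffness of cantilever and chain
(`unfolding_loading_rate()`).

## The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
and is the source of every parameter-recovery test.

* **Indentation**: populations of 50 cells measured 10 times each, moduli
  lognormal with configurable mode and shape (location
  $\mu = \ln(\text{mode}) + \sigma^2$, because the headline statistic of
  cell-mechanics work is the most probable value, not the mean). Default
  modes 1.88 and 2.72 kPa with $\sigma = 0.5$; 7.5 um curves at 5 um/s and
  4096 Hz, 1 nN setpoint, 120 pN/nm lever, 310 K. The forward model solves
  the quadratic force balance including cantilever deflection, then adds a
  drawn baseline tilt (+-0.02 pN/nm) and white Gaussian force noise
  (5 pN).
* **Adhesion**: retract profiles piecewise linear on the sampling grid, so
  the noise-free trapezoidal work equals the target exactly; triangular or
  multi-rupture shapes with sharp sign-restoring steps. Per-curve work is
  lognormal with configured median; group medians 2 and 5 fJ encode a true
  2.5x ratio. Detachment positions 5--15 um: the real experiment retracts
  far enough (100 um) that storing the full flat tail adds nothing, so the
  generator keeps a 1.5x tail beyond detachment, still leaving the
  farthest 20% force-free for the baseline.
* **Unfolding**: constant-velocity pulling with the instantaneous force
  solving the serial WLC + cantilever balance (vectorised bisection, 64
  iterations) on an internal 0.1 nm grid -- at these stiffnesses about
  1--4 pN per step, keeping the kinetic Monte Carlo hazard integration
  (trapezoidal, inversion sampling) accurate. $k_0$ and $\Delta x$ are
  *calibration defaults*, not measured constants: no kinetic parameters
  are available for these exact constructs, so values were chosen once so
  that simulated most-probable forces land near published ranges (I27
  roughly 215/250 pN at 400/1600 nm/s; FLNA repeat 22 tens of pN):
  I27 $k_0 = 3.5\times10^{-4}\,s^{-1}$, $\Delta x = 0.25$ nm; FLNA$^Q$
  $k_0 = 8\,s^{-1}$, $\Delta x = 0.22$ nm; FLNA$^R$ $k_0 = 2.5\,s^{-1}$,
  $\Delta x = 0.15$ nm. Temperature defaults: 310 K for cell work, 298 K
  for protein work.

What the generator does *not* emulate -- and hence what passing tests do
not establish about real data: viscoelastic creep and rate-dependent
moduli, hydrodynamic drag on the lever, 1/f and drift noise, cantilever
resonance ringing after ruptures, refolding kinetics, tethers and membrane
jumps in adhesion curves, and surface-coupling artefacts near contact.
Recovery results bound algorithmic error only; systematic instrument
effects need real calibration data.

## Statistics

Populations are described by moments, type-7 percentiles (10/25/50/75/90,
matching percentile boxplots whose whiskers span the 10th--90th
percentiles), a lognormal fit by closed-form maximum likelihood on logs
with the analytic mode $\exp(\mu - \sigma^2)$ as the "most probable
value" (the kernel-density peak, Gaussian kernel with Silverman bandwidth,
is reported alongside as a cross-check), and the $R^2$ of the fitted
density against a Freedman-Diaconis histogram. A Shapiro-Wilk screen at
$\alpha = 0.05$ routes the recommended headline description (normal vs
lognormal); the routing is reported, never silent.

Two-group comparison uses a Mann-Whitney test implemented in the package:
exact enumeration of all $\binom{n_1+n_2}{n_1}$ labelings for combined
$n \le 20$ (ties handled through midranks; tie-free null distributions are
memoised per sample-size pair), and a tie-corrected normal approximation
with continuity correction otherwise. The statistic is $\min(U_1, U_2)$;
significance stars use strict thresholds (`***` < 0.001, `**` < 0.01,
`*` < 0.05, `ns` otherwise -- exactly 0.05 is `ns`). Group deltas are
reported as $(g_2-g_1)/g_1$ for mean, median and mode.

Repeated measurements per cell are pseudoreplicates; the default
comparison is per-curve, matching common practice in the field, and a
per-cell aggregation is a one-liner on the per-curve table. Mixed-effects
modelling of the cell level is out of scope and acknowledged as a
limitation.

## Numerical choices and degenerate inputs

* Closed-form linear algebra wherever the model allows (Hertz fit, WLC
  fits are 1-D bracketed minimisations with golden-section/parabolic
  steps, tolerance 1e-8 of the bracket).
* WLC force balance by bisection (64 iterations), robust against the
  divergence at $x \to L_c$.
* Noise-free curves get an absolute contact threshold floor (0.5 pN) so
  `threshold * noise_sd = 0` cannot fire on the first sample.
* Constant samples: `sd = 0`, lognormal $\sigma = 0$, mode equals the
  value, no KDE.
* A flat retract yields work 0 with the detachment point collapsing onto
  the zero-force point -- a result, not an error; likewise trace rejection
  in unfolding.
* Files store doubles with `%.17g`, making write-then-read bit-exact.

## Problem sizes

The shipped studies run at desk scale, chosen once: 50 cells x 10 curves
per group for stiffness (1000 curves), 90 curves per group for adhesion,
60--100 traces per speed for unfolding, 2000 events for the kinetic
Monte Carlo calibration check and 2000 null datasets for the test-level
check. At these sizes the full test suite and the acceptance script each
complete in a few minutes on one CPU.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
cfg <- indentation_sim_config(modulus_mode = 1.88, noise_sd = 5)
cur <- simulate_indentation_curve(E = 2, cfg)
pr <- preprocess_curve(cur)
fit <- fit_hertz(pr, cfg$geometry)
print(fit)
#> <hertz_fit> E = 1.995 kPa (alpha = 18 deg, nu = 0.5, depth 500 nm, n = 427)
#>   indentation at 1000 pN: 1279.7 nm

st <- run_stiffness_study(seed = 1, n_cells = 10L, curves_per_cell = 5L)
print(st$comparison_E)
```
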