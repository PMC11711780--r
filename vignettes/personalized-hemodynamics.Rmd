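---
title: "Personalizing a lumped-parameter model of the left heart and assessing its repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalizing a lumped-parameter model of the left heart and assessing its repeatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemofit)
```

## The problem

Lumped (zero-dimensional) models of the circulation compress the left heart
and the systemic vasculature into a handful of compartments with pressures,
volumes and flows. Once such a model is personalized — its subject-specific
parameters tuned so the simulated hemodynamics reproduce an individual's
measured flow waveforms and cuff pressures — the fitted parameters
(ventricular elastance properties, aortic compliance) become candidate
non-invasive biomarkers. Their usefulness hinges on repeatability: if two
analysts, or two acquisition settings, produce slightly different input
measurements, how much do the fitted parameters move?

`hemofit` implements the full chain needed to study that question at desk
scale: the forward model, the input derivations, the parameter estimation,
a synthetic-measurement generator that emulates observer and sequence
variability at calibrated levels, the repeatability statistics, and a
one-at-a-time input sensitivity analysis.

## The forward model

The closed loop is: pulmonary-venous reservoir → left atrium → mitral valve →
left ventricle → aortic valve → ascending aorta → aortic segment →
peripheral Windkessel → venous return to the reservoir. Units are fixed
package-wide: mL, s, mmHg, cm², g/mL.

Both chambers follow a time-varying elastance
$P(t) = E(t)\,(V(t) - V_0)$ with the normalized double-Hill activation

$$
g(t) = \frac{h(t)}{h(t_{max})},\qquad
h(t) = \frac{(t/(\alpha_S T))^{R_C}}{1+(t/(\alpha_S T))^{R_C}}
       \cdot \frac{1}{1+(t/(\alpha_D T))^{R_R}},
$$

and $E(t) = E_{min} + (E_{max}-E_{min})\,g(t)$. This functional form is the
standard one carrying exactly this parameter set — contraction and
relaxation rates $R_C, R_R$, systolic and diastolic time constants
$\alpha_S, \alpha_D$ (fractions of the cycle length $T$), and the time of
end-systole $t_{max}$. The atrium runs the same form on a clock shifted by
`la_onset`, placing the atrial kick in late diastole. Note that $t_{max}$
enters through the normalization: the activation equals 1 at $t_{max}$ by
construction, so parameter sets are kept self-consistent by setting
$t_{max}$ to the shape's actual argmax (`activation_peak_time()`); the
synthetic-subject generator does this automatically.

The aortic valve uses the energy-loss pressure-gradient formulation: the
convective gradient is
$\Delta P = \rho/(2\,\mathrm{ELCo}^2)\; Q|Q| \cdot (0.06/133.322)$ with
$\mathrm{ELCo} = EOA \cdot A_{LVOT} / (A_{LVOT} - EOA)$, plus an inertial
term $B\,dQ/dt$ (switchable off with `b_av = 0`, in which case the flow
relaxes onto the algebraic energy-loss solution). The unit factor is
implemented verbatim as printed in the source formulation; its physical
derivation is not restated here. Both valves are diodes smoothed by a
sigmoidal gate over a `dp_width = 0.1` mmHg pressure window: a valve is open
while its driving gradient is positive *or* forward flow persists (inertial
deceleration), and a closed valve leaks at most
$|\Delta P| / r_{closed} \approx 0.01$ mL/s.

### Parameters

The model has 40 scalar parameters, 23 flagged subject-specific and 17
fixed (`default_parameters()` lists all of them with bounds). Of the free
set, `eoa`, `a_lvot` and `lv_emax` are derived directly from measurements
and may move only ±10% during optimization; the other 20 are tuned by the
optimizer from the defaults. The cycle length `t_cycle` is assigned from
the measurement and never optimized. The 17 fixed values are
literature-typical healthy choices made once for this package (the original
model's fixed values live in prior work and are not printed in the source);
they are all overridable, and each is documented in the parameter table.

Two fixed values deserve comment. The closed-valve resistance and the
sigmoid width are numerical devices for stiff-integrator stability, kept in
the parameter table so they are visible and versioned. The pulmonary venous
"source" is a large-compliance reservoir (15 mL/mmHg) rather than a fixed
pressure: this keeps total blood volume exactly conserved, which the test
suite checks to integrator tolerance.

### Numerics

The right-hand side exists twice: a readable pure-R reference (`ode_rhs()`)
and a compiled C mirror used by default; the tests assert their equality at
random states to 1e-12. Integration is adaptive stiff LSODA with relative
tolerance 1e-6 and absolute tolerance 1e-8, run cycle by cycle until the
state at a cycle start changes by less than `periodicity_tol` (default
1e-3, with 30 cycles maximum; the default subject converges in 5). The
estimation routines tighten this to 1e-4 so that finite-difference
derivatives are not swamped by truncation noise — the optimizer's
forward-difference step (`epsfcn = 1e-4` in normalized coordinates) is
chosen for the same reason.

One visible numerical artifact: shortly after aortic-valve closure the LV
can transiently rebuild enough pressure to re-open the valve for one or two
samples (elastance still rising toward $t_{max}$ on a nearly empty
ventricle). This small secondary ejection wavelet is deterministic model
physics, identical in simulation and synthetic data, so it does not bias
estimation; it does make `derive_eoa()` on model-generated waveforms read a
few percent high, since the wavelet contributes stroke volume outside the
contiguous systolic support.

## Input derivation

`derive_eoa()` implements $EOA = SV/VTI$ with trapezoidal quadrature: the
stroke volume is the closed-cycle integral of the aortic-valve flow, and
the velocity-time integral runs over the contiguous systolic support where
the flow exceeds 1% of its peak (widened by one bracketing sample so the
rising and falling edges survive coarse 30–40 ms acquisition grids). The 1%
threshold keeps diastolic velocity noise out of the VTI.

`derive_emax_lv()` is the single-beat estimate
$E_{max} = 0.9\,(SBP + \Delta P_{max}) / (ESV - V_{0})$ with the convective
valve gradient evaluated at peak aortic-valve flow. $V_0$ defaults to
10 mL and is configurable. The package defaults were chosen so the model is
*consistent* with this estimator: on the default subject the single-beat
value lands within a few percent of the generating `lv_emax`, which is what
makes the ±10% optimization window meaningful.

## Estimation

`estimate()` minimizes a weighted least-squares cost over the 23 free
parameters in bound-normalized coordinates with Levenberg–Marquardt.
Residuals: each measured flow waveform (simulation resampled onto the
*measurement* grid by periodic linear interpolation, so the cost is
invariant to solver step control), normalized per site by its peak flow and
sample count; plus systolic and diastolic cuff-pressure residuals scaled so
1 mmHg ≈ a 1% whole-waveform peak-flow error. Without the pressure terms,
compliances and resistances are identifiable only up to a pressure gauge.
The weighting is this package's declared choice.

Multi-start: the first start is the measurement-derived assembly; further
starts are Latin-hypercube points within bounds, attempted only while the
best cost exceeds `restart_threshold` (default 1e-3) up to `n_starts`.
Everything is deterministic under `seed`, and parameters that finish within
0.1% of a bound are reported rather than silently clipped — hitting a ±10%
window is diagnostic information.

On noise-free synthetic bundles the seven headline parameters ($E_{min}$,
$E_{max}$, $R_C$, $R_R$, $\alpha_S$, $\alpha_D$, $C_{aa}$) are recovered
with a median relative error near 1% across ten ground-truth draws (the
acceptance suite recomputes this). Individual draws can stall in local
minima where atrial-timing mismatch traps the mitral residual; restarts
recover some but not all of these, and the worst single-parameter errors
then sit in $R_R$ and $\alpha_S$ — the parameters the source study also
flags as heart-rate sensitive.

## The synthetic cohort

`build_cohort()` emulates the study design: per subject a ground-truth
parameter draw (uniform within modest healthy windows around the defaults;
`subject_ranges()`), then five analysis occasions — two by observer 1, one
by observer 2, and one per acquisition sequence (40 ms and 30 ms sampling).
`observe()` produces what an analyst would have extracted: scalars
multiplied by $(1 + \mathrm{CoV}\,z)$ with truncated (±3 SD) standard-normal
$z$; waveforms scaled by a per-site net-flow factor plus smooth zero-mean
shape noise (moving-average-filtered white noise, 60 ms correlation time,
cycle-mean removed so net flows calibrate exactly); then resampling to the
occasion's acquisition interval.

Noise levels are calibrated so each *paired* comparison lands on the
study's input CoVs (intra-observer: A_LVOT 2.8%, ESV 3.0%, EOA 1.5%, net
flows 4.1/1.2/1.8%; inter-observer: 12/3.8/8.6% and 9.1/2.7/3.4%;
inter-sequence: A_LVOT 12%, EOA 8.6%, cycle length 3.7%, net flows
13/9.1/4.2%). Since the paired CoV statistic equals
$\sqrt{(\sigma_A^2+\sigma_B^2)/2}$ for independent per-occasion noise,
observer 2 receives $\sigma = \sqrt{2\,\mathrm{CoV}_{inter}^2 -
\mathrm{CoV}_{intra}^2}$ so both the intra and inter pairs calibrate
simultaneously. Inter-sequence occasions perturb the cycle length and
re-simulate the physiology at the new $T$ (a physiological change between
scans, not an analysis error), and share a single ESV analysis, mirroring
the study's treatment of the morphological images. Cuff pressures are
shared across occasions. The Gaussian multiplicative error model is this
package's stated assumption; the source study reports no distributional
model of observer error. The waveform shape-noise amplitudes (3/5/8% of
peak for intra/inter/sequence) are the free knob tuned only for a plausible
RMSE ordering, not to any printed value.

What the generator does **not** emulate: MRI physics (velocity encoding,
phase wraps, navigator efficiency), spatially correlated segmentation
error, observer bias that persists across a subject's occasions, or
beat-to-beat variability within an acquisition. Passing tests on this
cohort therefore demonstrate the *pipeline's* behavior under calibrated
input variability, not agreement with the original subjects' data — the
study's per-parameter CoV tables are not reproducible without the original
MRI measurements, and the package makes no claim to reproduce them
numerically.

## Statistics

For each paired comparison, `run_variability_study()` applies to every
input measure and (when estimates are supplied) every headline parameter:

* Bland–Altman bias $\bar d$ and limits of agreement $\bar d \pm 1.96\,SD$
  (sample SD);
* a repeatability CoV: root-mean-square within-subject SD over the grand
  mean, with the within-subject variance of a duplicate pair taken as
  $d_i^2/2$. The cited CoV method's exact form is not printed in the
  source, so this definition is declared; a pairwise alternative
  (`method = "sd_diff"`) is available for sensitivity and coincides for
  balanced pairs;
* a two-sided Wilcoxon rank-sum test, exactly enumerated for combined
  $n \le 20$ (ties via average ranks) and normal-approximated with tie and
  continuity correction above, reported against a 0.05 threshold. The
  source names the (unpaired) rank-sum test for these paired occasions and
  it is implemented as named; the paired signed-rank alternative was
  considered out of scope since the statistic reported is the one stated;
* per-site waveform RMSE after normalizing time to cycle fraction
  (occasions can differ in cycle length) and resampling both waveforms onto
  a common uniform grid.

All of these are checked against independent brute-force oracles — explicit
enumeration for the rank test, direct-formula implementations for the rest
— on randomized small inputs in the test suite.

## Sensitivity analysis

`sweep_input()` perturbs one of EOA, A_LVOT or $E_{max}$ over a ±10% grid
in 2.5% steps (mirroring the optimization window; the original
supplementary grid is not printed) with everything else fixed, recomputing
ELCo where needed, and reports both waveform RMSE against baseline and
relative changes of scalar summaries. On the default subject the maximal
elastance dominates the two valve-geometry inputs by over an order of
magnitude on aortic pressure and both valve flows, reproducing the expected
ordering; the acceptance suite asserts the ordering, not any particular
magnitude.

## Problem sizes and limitations

The shipped analyses use 10 subjects × 5 occasions, 10 recovery draws,
1000 calibration pairs per observer comparison (500 for the re-simulating
inter-sequence comparison) and 20 cohort replicates for the qualitative
ordering check — sizes chosen so the whole workflow reruns in minutes on a
single core while keeping Monte-Carlo error well below the assertion
margins (a paired CoV over 1000 pairs has ~2% relative sampling error).

Known limitations: no right heart or pulmonary detail beyond the source
reservoir, no baroreflex, one aortic RLC segment (the original model's
segmentation of the arch is not recoverable from the source), the
valve-reopening wavelet noted above, and local-minimum stalls for a
minority of recovery draws. Parameter *uncertainty* (profile likelihood or
Bayesian) is deliberately out of scope; the package quantifies
reproducibility under input variability, which is a different question.
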