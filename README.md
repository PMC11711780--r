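# hemofit

Personalization of a lumped-parameter (0-D) model of the left heart and
systemic circulation from non-invasive measurements, and analysis of how
repeatable the personalized parameters are when the input measurements vary
— between repeated analyses by one observer, between observers, and between
MRI acquisition sequences.

**Who this is for:** researchers working with model-based cardiovascular
biomarkers (time-varying elastance parameters, aortic compliance) who need a
desk-scale testbed for the whole estimation chain: forward model → input
derivation → bound-constrained fitting → repeatability statistics.

## The model and method

The closed loop couples a pulmonary-venous reservoir, a time-varying
elastance left atrium and ventricle, a mitral valve (resistance +
inertance, diode), an energy-loss aortic valve, a compliant ascending aorta
(`C_aa`), an aortic RL segment, and a peripheral Windkessel. Chamber
pressure is `P = E(t) (V − V0)` with the normalized double-Hill activation

    E(t) = E_min + (E_max − E_min) · h(t)/h(t_max),
    h(t) = [(t/(α_S T))^R_C / (1 + (t/(α_S T))^R_C)] · 1/(1 + (t/(α_D T))^R_R)

and the aortic valve obeys ΔP = ρ/(2·ELCo²)·Q|Q|·(0.06/133.322) + B·dQ/dt
with ELCo = EOA·A_LVOT/(A_LVOT − EOA).

Personalization: of the model's 40 parameters, 23 are subject-specific.
`EOA` (= SV/VTI), `A_LVOT` and the maximal LV elastance
(`E_max = 0.9·(SBP + ΔP_max)/(ESV − V0)`) come straight from the
measurements and may move ±10 % during optimization; the cycle length is
fixed to the measured value; the rest are fitted by multi-start
Levenberg–Marquardt against the three measured flow waveforms (mitral
valve, aortic valve, ascending aorta) and the cuff pressures.

A synthetic-measurement generator stands in for the MRI data: ground-truth
subjects are drawn from healthy ranges and "observed" with multiplicative
scalar noise, smooth waveform shape noise and acquisition-grid resampling,
calibrated so the paired comparisons land on the study-grade input
variabilities (e.g. EOA CoV 1.5 % intra-observer, 8.6 % inter-observer;
heart-rate CoV 3.7 % between sequences). Repeatability is then quantified
with Bland–Altman bias and limits of agreement, repeatability CoVs,
Wilcoxon rank-sum tests and per-site waveform RMSE.

## Worked example

```r
library(hemofit)

sim <- simulate_model(default_parameters())
print(sim)
#> <simulation_result> converged after 5 cycles (drift 2.48e-04, tol 1e-03)
#>   aortic pressure 116.2/72.6 mmHg, LV volume 53.7-130.9 mL, SV 77.2 mL
```

A converged healthy baseline: 116/73 mmHg aortic pressure, stroke volume
77 mL, ejection fraction ≈ 59 %. Now a self-consistency experiment — draw a
ground-truth subject, observe it noise-free, and refit:

```r
truth <- draw_subject(seed = 42)
bundle <- observe(truth, noise_model(), seed = 7)    # noise-free, 40 ms grid
fit <- estimate(bundle, seed = 1, n_starts = 1, maxiter = 100,
                periodicity_tol = 1e-4)
print(fit)
#> <estimation_result> converged, 25 iterations, 1 start(s), cost 3.233e-05
#>   at bound: a_lvot, lv_emax
```

The seven headline parameters (passive and maximal LV elastance,
contraction/relaxation rates, systolic/diastolic time constants, ascending
aorta compliance) come back with a median relative error of a few percent;
`at bound` flags parameters pinned against their ±10 % measurement windows.
The full study pipeline lives in `analysis/01…05` (baseline simulation,
cohort generation, per-occasion personalization, variability tables,
sensitivity sweep), writing its tables under `results/`. For example, the
sensitivity stage prints:

```
rmse_aortic_pressure  lv_emax 1.364 | eoa 0.0619 | a_lvot 0.0306 -> elastance dominates
```

i.e. a ±10 % change in maximal elastance perturbs the aortic pressure trace
over 20× more than the same relative change in valve geometry.

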