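# dermakin

Analysis toolkit for transdermal drug-delivery pharmacokinetics, built for
studies that combine **skin–blood microdialysis sampling**, **Franz
diffusion-cell permeation experiments** and **Fickian diffusion modeling**
of drug transport from a delivery matrix through the skin to the capillary
bed. Intended users are PK/formulation scientists who have dialysate and
receptor-cell concentration series and want calibrated tissue
concentrations, flux and diffusivity estimates, a mechanistic forward
model, and standard non-compartmental summaries — all scriptable and fully
reproducible.

## What it computes

**Microdialysis recovery.** A probe samples only a fraction of the true
tissue concentration. Recovery is estimated ex vivo/in vivo by the gain
method, `R = 100·C_out/C_in`, and the loss (retrodialysis) method,
`R = 100·(C_in − C_out)/C_in`, both special cases of the relative recovery
`RR = (C_d − C_p)/(C_m − C_p)`. Retrodialysis correction is only valid
when recovery equals delivery, so a per-concentration Welch t-test
(`gain_loss_equivalence()`) makes that check explicit. Tissue
concentrations are then `C = C_dialysate / R` (`correct_series()`).

**Franz-cell permeation.** Cumulative permeated amount with
replacement-volume correction, `Qn = (Cn·Vn + Σ_{i<n} Ci·Vi)/A`;
steady-state flux `Js = dQn/dt` by OLS over a lag-excluding window; and the
apparent diffusivity from Fick's first law with the steady-state linear
profile, `D = Js·L/c0`.

**Two-layer diffusion model.** The delivery matrix (−Lm ≤ x ≤ 0) and the
skin (0 ≤ x ≤ Ls) each obey `∂C/∂t = D ∂²C/∂x²`, coupled by flux
continuity and a partition jump `Cs(0,t) = km·Cm(0,t)` at the interface,
with zero flux at the donor surface and a capillary clearance sink
`−Ds ∂Cs/∂x = kcl·Cs` at the skin base. Defaults: Lm = Ls = 0.04 cm,
km = 0.5, kcl = 25 cm/h, Cm0 = 0.2 g/cm³, dt = 0.001 h. The solver is
Crank–Nicolson on a conservative finite-volume grid
(`simulate_diffusion()`), with `probe_series()` extracting the
concentration time course at a probe depth (default 0.0336 cm),
`mass_balance()` auditing conservation, and `fit_skin_diffusivity()`
estimating Ds (optionally Dm) from observed series by bounded
least squares.

**NCA.** `pk_summary()` reports Cmax, Tmax, terminal half-life
(log-linear fit, `t½ = ln2/λz`), AUC0–t (linear trapezoid) and AUC0–∞
(`+ C_last/λz`).

**Membrane trajectory metrics.** Time-average-reference RMSD (no
superposition), phosphate-plane bilayer thickness, the ±2 Å padded
bounding-box solvent-carving rule, and upper-leaflet insertion-centre
coordinates, over PDB/XYZ/tabular coordinate frames.

**Synthetic data.** Every experimental design above has a seeded generator
(`make_dialysate_dataset()`, `make_permeation_dataset()`,
`make_calibration_dataset()`, `make_trajectory()`) returning known ground
truth alongside noisy observations.

## Worked example

The bundled demo generates a full synthetic study and analyses it:

```r
library(dermakin)
res <- run_demo(seed = 42, out_dir = "demo_out")
#> [demo] pooled loss-method recovery: 69.2% (equivalence PASS)
#> [demo] fitted Ds = 0.000294 cm^2/h (true 0.0003)
#> [demo] Cmax = 0.0097 at Tmax = 120 min, t1/2 = 399 min
#> [demo] flux 2384 (true 2500), D 9.54e-05 (true 1e-4)
```

Reading: probe calibration replicates generated at a true recovery of
69.7% pool to 69.2%, and the gain/loss methods test as equivalent, so the
retrodialysis correction is justified. The dialysate series corrected by
that recovery, fed to the PDE fit, recovers the generating skin
diffusivity within 2%. The corrected series peaks at 120 min
(concentration in model units), with a 399 min terminal half-life. The
Franz-cell branch recovers the closed-form steady-state flux within ~5%
under 5% measurement noise. The same pipeline runs from the shell via
`exec/dermakin` (`dermakin demo --seed 42 --out demo_out`), which also
writes a `manifest.json` per run.

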