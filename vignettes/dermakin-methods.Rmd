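---
title: "Methods: models, numerics and design choices in dermakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, numerics and design choices in dermakin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermakin)
```

dermakin analyses transdermal drug-delivery experiments in which a drug
leaves a delivery matrix (ointment, nanoemulsion, gel), crosses the skin,
and is cleared by the capillary bed, while microdialysis probes sample the
skin and blood compartments and Franz cells measure ex vivo permeation.
This vignette is the package's own account of the models it implements,
the numerical choices behind them, and what the bundled synthetic data do
and do not establish about real data.

## Microdialysis recovery

A microdialysis probe's dialysate underestimates the surrounding tissue
concentration by its *recovery* fraction. Two empirical calibrations are
implemented:

* **gain method** — the probe window sits in a spiked medium
  (concentration $C_{in}$) and captures $C_{out}$: recovery
  $= 100\,C_{out}/C_{in}$;
* **loss (retrodialysis) method** — the perfusate is spiked and drug is
  lost to drug-free surroundings: recovery $= 100\,(C_{in} -
  C_{out})/C_{in}$.

Both are limits of the relative recovery $(C_d - C_p)/(C_m - C_p)$ with
drug-free perfusate or drug-free medium respectively, and `relative_recovery()`
is tested against those algebraic identities. In vivo correction divides
every dialysate concentration by the in vivo recovery; this is only valid
when recovery equals delivery, so `gain_loss_equivalence()` runs a
two-sided Welch two-sample t-test per concentration level (α = 0.05 by
default) and demands that every level pass. A named test was chosen
deliberately: "the two methods are basically consistent" is not an
assertable claim, a per-level Welch decision is. Degenerate replicate sets
with zero variance in both groups are decided by exact mean comparison
(p = 1 or p = 0) rather than erroring out, because the case arises in
pathological fixtures.

Pooling across concentration levels uses the *unweighted mean of level
means*. Calibration tables commonly carry unequal level sets per probe, and
the unweighted rule matches the arithmetic behind the standard pooled
summaries for concentric probes (e.g. level means of 46.4, 54.1, 54.4 %
pool to 51.6 %). Recoveries are percentages at the I/O boundary and
fractions internally; loss-method measurements with $C_{out} > C_{in}$
(possible under noise) are clipped to 0 % recovery with a warning rather
than rejected.

## Franz-cell permeation

`cumulative_amount()` implements the replacement-volume bookkeeping
$Q_n = (C_n V_n + \sum_{i<n} C_i V_i)/A$ with default geometry $V_n = 5$
mL, $V_i = 1$ mL, $A = 0.785$ cm² (a standard vertical Franz cell sampled
1 mL per time point). `steady_state_flux()` fits $Q_n$ on $t$ by OLS; the
`"auto"` window picks, among trailing windows of ≥ 4 points, the one with
maximal r² (ties to the longest window) — a conventional heuristic for
excluding lag-phase curvature when no window is prescribed.
`diffusivity_from_flux()` evaluates Fick's first law $D = -J_s/(dC/dx)$
with the steady-state linear profile $dC/dx \approx -c_0/L$, the standard
sink-condition treatment; an explicit gradient can be supplied instead.
Because published flux tables rarely state their fitting window or
gradient evaluation, tabulated diffusivities are treated as *inputs* to
the diffusion model, never as fitting oracles.

## The two-layer diffusion model

The forward model couples two diffusion equations on adjacent slabs:

$$\frac{\partial C_m}{\partial t} = D_m \frac{\partial^2 C_m}{\partial x^2},
\quad -L_m \le x \le 0, \qquad
\frac{\partial C_s}{\partial t} = D_s \frac{\partial^2 C_s}{\partial x^2},
\quad 0 \le x \le L_s,$$

with zero flux at the donor surface $x=-L_m$; flux continuity
$-D_m \partial_x C_m = -D_s \partial_x C_s$ **and** the partition
(isolation) jump $C_s(0,t) = k_m C_m(0,t)$ at the interface; the Robin
clearance condition $-D_s \partial_x C_s = k_{cl} C_s$ at the skin base;
and uniform initial concentrations per layer.

Default parameters, with units and provenance of the choice:

| parameter | default | unit | role |
|---|---|---|---|
| $L_m, L_s$ | 0.04 | cm | matrix and skin thickness |
| $D_m, D_s$ | 7.42e-6, 10.60e-6 | cm²/h | nanoemulsion-based-gel diffusivities |
| $k_m$ | 0.5 | — | interface partition coefficient |
| $k_{cl}$ | 25 | cm/h | capillary clearance coefficient |
| $C_{m0}, C_{s0}$ | 0.2, 0 | g/cm³ | initial loading |
| $dt$ | 0.001 | h | time step |
| nx_m, nx_s | 200 | — | grid intervals per layer |

The equations are linear, so the concentration unit is arbitrary; units
are carried as metadata and never converted silently. Several points of
the model statement required a decision:

* **Dimensionality.** The physical patch is a rectangle, but the equations
  and boundary conditions have no transverse dependence; the model is
  solved in 1-D and the patch width (0.04 cm) kept as metadata only. The
  solution is identical and far easier to verify.
* **Clearance boundary.** The gradient at the skin base is of $C_s$, so
  the Robin condition uses $D_s$ (a skin-side statement of capillary
  uptake).
* **Skin initial condition** is a configurable constant $C_{s0}$,
  default 0 (drug-free skin at application time).
* **Three-part system, two diffusing layers.** The receptor side
  (dermis-linked capillaries) enters as the clearance boundary, not as a
  third diffusing slab; an explicit third layer would be a
  straightforward extension but is not built.

### Numerical scheme

Space is discretised in flux (finite-volume) form on uniform per-layer
grids. The interface is a *dual-valued node*: the unknown is the
matrix-side value $u_I$, the skin-side value is $k_m u_I$ (the partition
condition is imposed exactly), and the control volume spanning
$[-\Delta x_m/2, \Delta x_s/2]$ carries mass
$(\Delta x_m + k_m \Delta x_s)/2 \cdot u_I$ with one-sided fluxes on each
face — discrete flux continuity. Because the operator is in flux form,
row sums vanish except for the clearance term, and discrete mass is
conserved exactly (the conservation test measures ~1e-8 relative error,
dominated by the time-quadrature of the cleared flux at the output
cadence).

Time stepping is Crank–Nicolson with two backward-Euler startup steps
(Rannacher smoothing): the initial profile is discontinuous at the
interface, and undamped Crank–Nicolson would carry oscillatory transients
into the early-time solution. The very first step's right-hand side is
built from the *exact piecewise initial cell masses* rather than the
projected nodal values, so the interface cell straddling the
discontinuity starts with the correct mass; without this, a closed system
equilibrates to a value offset by $O(\Delta x)$ (≈ 0.1 % at the default
grid), which the analytic-equilibrium check would resolve. The stored
$t=0$ slice reports the exact piecewise initial condition, with both
interface sides present ($x=0$ appears once per layer).

Verification, all in the test suite and acceptance script: (i) closed
symmetric systems relax to the mean; (ii) closed partitioned systems reach
$C_m \to C_{m0} L_m/(L_m + k_m L_s)$ to < 0.1 %; (iii) the early-time
homogeneous limit matches the infinite-medium step solution
$C = (C_{m0}/2)\,\mathrm{erfc}(x/2\sqrt{Dt})$ to < 2 % while
$\sqrt{Dt} < L_m/4$; (iv) halving $\Delta x$ and $\Delta t$ changes the
probe series by < 0.5 % sup-norm; (v) an independently coded explicit-Euler
solver with a *different* interface treatment (zero-capacity interface
node solved from flux matching each step) agrees to < 1 % on a coarse
grid. Limit checks (ii)–(v) use diffusivities around 1e-3 cm²/h so the
dynamics complete within a short horizon; the default transdermal values
(1e-5 scale) are exercised by the conservation and fitting checks. The
solver refuses runs that go non-finite or more negative than 1e-6 of the
initial concentration, naming dt and the grid in the error.

### Diffusivity fitting

`fit_skin_diffusivity()` minimises the SSR between the simulated probe
series (linearly interpolated to the observed minutes) and the observed
values. The search is on $\log_{10} D$ with ±3-decade bounds,
multi-started from 0.1×, 1× and 10× the template value. The 1-D search is
golden-section (`optimize`) per start bracket: at small $D_s$ the probe
depth lies many diffusion lengths from the source, the objective is flat
to machine precision, and finite-difference gradients vanish — golden
section is immune to that failure mode, where a quasi-Newton line search
stalls at its start. The flat-objective case (no drug anywhere) is
detected by comparing the objective across the decade-spaced starts and
flagged `degenerate` rather than reported as an estimate. The
two-parameter $\{D_s, D_m\}$ case uses L-BFGS-B with widened
finite-difference steps.

Problem sizes for the Monte-Carlo recovery check (package's choice,
stated for reproducibility): truth is simulated on the default fine grid
(200 intervals per layer, dt = 0.001 h); the 20 replicate fits use a
60-interval, dt = 0.01 h template. Crank–Nicolson drift between those
grids is below 0.5 %, negligible against the 10 % acceptance band and the
~0.5 % median error actually measured.

## Non-compartmental analysis

Times are minutes throughout (the sampling-grid unit), so $\lambda_z$ is
1/min and AUCs ng·min/mL. Decisions: terminal fit on the **last 3
samples** by default (configurable) — the window must start after
$T_{max}$ and contain positive concentrations, and a slope
indistinguishable from flat (decay < 1e-10 over the window) is an
estimation error, not a huge half-life; **linear** trapezoid throughout
(the most common default; log-linear down-steps are not implemented);
ties in $C_{max}$ resolve to the earliest time. AUC extrapolation adds
$C_{last}/\lambda_z$ and requires a valid terminal fit.

## Membrane trajectory metrics

The RMSD here is the *time-average-reference* form: the reference is each
atom's mean position over all frames, and no rotational/translational
superposition is applied before comparison. This differs from
conventional Kabsch-aligned RMSD and measures absolute wandering about
the time mean — appropriate for a membrane patch that is not expected to
drift, and it makes the rigid-translation invariance of the *series*
(translating every frame equally) exact. Bilayer thickness assigns
leaflets by each frame's phosphate z-median (robust to drift) and takes
the difference of leaflet mean z. Solvent carving deletes waters whose
representative coordinate (the oxygen position) falls inside the ligand
bounding box padded by 2 Å per side on **all three axes simultaneously**.
The insertion-centre rule — A and B as midpoints of the extreme phosphate
x and y, C as the midpoint of the top phosphate z and the top water z —
is one defensible reading of an ambiguous published recipe; it is
isolated in `insertion_center()` so it can be swapped without touching
anything else. Literature-scale plateau values (RMSD ≈ 20, thickness ≈
50 Å) are qualitative context only and are never asserted.

## Synthetic data: what it emulates, what it does not

The generators reproduce the *designs*: 30-min dialysate sampling over
12 h at skin and blood sites, hourly Franz-cell sampling, calibration
replicates (n = 5) at 52.5/210/1050 ng/mL, phosphates on two jittered
z-planes. Noise is multiplicative lognormal with unit mean for
concentrations (CV 5 % by default, in the range of typical LC–MS
replicate RSDs; positivity is preserved) and additive normal for recovery
percentages (SD 2.5 points, matching typical calibration tables). Every
generator is a pure function of (parameters, seed) — the global RNG state
is saved and restored — and Franz-cell data come from the homogeneous
membrane closed form $Q(t) = \frac{Dc_0}{L}(t - \frac{L^2}{6D}) -
\frac{2c_0L}{\pi^2}\sum \frac{(-1)^n}{n^2} e^{-Dn^2\pi^2t/L^2}$ truncated
at relative 1e-8, so slope and lag have known truth.

What passing these tests does **not** show: real skin is stratified
(stratum corneum / epidermis / dermis) with depth-dependent diffusivity,
while the model's layers are homogeneous; dialysate noise is not purely
multiplicative; probe recovery can drift over a 12 h experiment; and the
generator's truth comes from the same model family being fitted, so the
fitting checks establish *self-consistency and noise robustness*, not
model adequacy for real tissue. The blood-site series is taken as the
capillary-boundary concentration attenuated by the concentric-probe
recovery — a deliberate simplification, as the model has no systemic
compartment.

## Known limitations

* Two homogeneous diffusing layers plus a boundary sink; no stratified
  skin, no systemic PK compartment.
* The auto flux window and the 3-point terminal fit are heuristics;
  both are overridable and reported with their diagnostics (r², window).
* `insertion_center()`'s C coordinate follows one reading of an ambiguous
  rule (documented above).
* No periodic-boundary unwrapping or superposition in trajectory
  analysis; inputs are assumed already whole.
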