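---
title: "Methods: from optode frames to oxygen-consumption rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from optode frames to oxygen-consumption rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roptode)
```

This vignette documents the models, defaults and numerical choices behind
the package, in the spirit of a statistical-methods appendix: what is
assumed, what is tunable, and what the validation on synthetic data does
and does not demonstrate.

## 1. The sensing model and its assumptions

A platinum-porphyrin optode disk emits red light that is dynamically
quenched by dissolved oxygen and green reference light that is not. The
working observable is the luminance ratio $R = (\mathrm{red} -
\mathrm{green})/\mathrm{green}$ (or the simple ratio
$\mathrm{red}/\mathrm{green}$ when a camera's internal IR-blocking filter
is left installed; the two differ by exactly one, so either carries the
same information). The response follows a modified Stern–Volmer relation

$$\frac{R}{R_0} = \alpha + \frac{1-\alpha}{1 + K_{SV}\,C},$$

with $C$ in % air saturation, $R_0$ the zero-oxygen ratio (dimensionless,
typically 1.7–2.0 for these coatings), $K_{SV}$ the quenching constant
(per % saturation, typically around 0.01), and $\alpha \in [0,1)$ the
nonquenchable signal fraction. The model assumes a single quenchable
population plus a constant background; it makes the response strictly
decreasing in $C$, which is what licenses the closed-form inversion

$$C = \frac{1}{K_{SV}}\left[\frac{1-\alpha}{R/R_0 - \alpha} - 1\right],$$

valid on the open band $(\alpha R_0,\, R_0]$. Ratios above $R_0$ are
physically "more-than-zero-oxygen" indications (drift, super-saturation);
the package clamps them to $C = 0$ with a warning rather than failing,
because isolated over-range frames are common at experiment start.
Ratios at or below the floor $\alpha R_0$ carry no information and raise
an error.

Calibration is per disk. Because disks carry engraved IDs, every
measurement is tied to its own coefficients through a JSON registry.
Fitting uses Levenberg–Marquardt least squares with deterministic
initialisation ($R_0$ from the lowest-concentration ratio, $K_{SV}$ from
a two-point estimate, $\alpha$ from 0) and no random restarts, so a given
input always yields the same curve. By default $\alpha$ is fixed at zero:
published coefficient tables for this coating report only $(R_0, K_{SV})$
pairs, two-parameter fits are markedly more stable on six-level response
curves, and a free $\alpha$ is available (`fix_alpha = FALSE`) when the
low-oxygen end visibly flattens. The concentration unit inside the model
is % air saturation throughout — $K_{SV}$ magnitudes near 0.01 are only
dimensionally sensible per percent — and all mg/L bookkeeping lives in
the gas-exchange module.

### Calibration comparison

When two calibrations look similar (different lighting, different camera,
before/after sterilisation), the package compares them with a two-sample
Kolmogorov–Smirnov test at $\alpha = 0.05$. The source procedure does not
state which samples are compared; `compare_calibration_curves` evaluates
both curves' back-calculated concentrations on a shared grid of ratio
values spanning the band both can invert, which directly measures the
disagreement in the quantity users consume. The wrapper also accepts any
numeric samples, so raw ratios or residuals can be compared instead. The
exact KS test is discrete and therefore mildly conservative at the sample
sizes involved; the package's null simulations put its attained level a
little below the nominal 5 %.

### Detection limits

Detection and quantification limits follow the 3.3σ/m and 10σ/m
convention: σ is the **population** (n-divisor) standard deviation of
repeated back-calculated measurements at one probe concentration, and m
is the ordinary-least-squares slope of back-calculated versus true
concentration over the linear dynamic range, taken as 0.4–40 % saturation
by default. Computing σ and m on back-calculated concentrations makes m
dimensionless and close to one, so the limits come out directly in %
saturation. The population form is used because it reproduces the
conventional ±-spread reporting for small per-disk sets; `loq` is stored
as `lod * (10/3.3)` so the ratio between the two is exact by
construction, not merely to rounding. Reported limits are conventionally
printed at two decimals, summary statistics at one.

## 2. Imaging

Regions of interest are user-supplied circles (`disk_id`, centre,
radius), mirroring the manual circle-drawing workflow this replaces;
automatic disk detection is deliberately out of scope for the analysis
core. Conventions, chosen once and tested: 0-based pixel coordinates,
origin top-left, x rightward, y downward; a pixel belongs to an ROI when
its centre lies strictly inside the circle; 8- or 16-bit frames are
handled as digital-number arrays, with PNG for 8-bit and TIFF for 16-bit
storage. Per ROI the package records mean red, mean green, both ratio
definitions, the pixel count, and the fraction of pixels at full scale;
a sample fails QC when more than 1 % of its pixels are saturated. The
threshold is a package default: the acquisition practice is to expose
close to sensor saturation for signal-to-noise, so a small clipped
fraction is normal, but a large one biases the channel means. QC-failed
samples are carried through the pipeline with missing concentrations
rather than dropped, so time axes stay aligned.

The synthetic renderer is the forward model of the same physics: green
set to a constant reference level inside each disk, red set so the chosen
ratio definition reproduces the Stern–Volmer response exactly, i.i.d.
Gaussian pixel noise added, values clipped to the representable range.
If the requested ratio cannot be represented at the requested reference
level the renderer refuses with advice to lower `green_level` — clipping
silently would bias every downstream mean. A radius-10 disk contains
over 300 pixels, comparable to the pixel budget of real disks imaged at
better than 100 px/mm².

## 3. Gas exchange

Solubility at 100 % air saturation uses the Benson–Krause formulation in
temperature (valid 0–40 °C) scaled linearly by ambient pressure relative
to 1013.25 mbar. This choice reproduces the conventional published
fresh-water tables to two decimals (8.91 mg/L at 21 °C, 1013 mbar), which
is what ties the % saturation scale to mg/L. Salinity is handled as a
separate linear correction $DO_{salt} = DO - qS$ with $q = -0.1903\,t +
12.892$; $S$ is interpreted as mass fraction (`salinity_pct / 100`),
the reading consistent with the correction's magnitude over its
calibrated 0–3.5 % m/v range, and values outside that range extrapolate
with a warning. The ambient O₂ mole fraction is fixed at 0.2095, and the
Henry coefficient defaults to solubility divided by ambient partial
pressure, so that 100 % saturation and ambient equilibrium coincide by
construction.

The sealed-tube reaeration model treats the assembled reactor as a
single system with whole-tube permeability $r$ in mg/(min·bar) — wall
area, thickness, cap and O-ring absorbed into one coefficient, which is
the quantity actually identifiable from a tube-level test. Fitting the
closed-form curve frees $r$, $p_0$ and $H$ jointly (fixing only volume
and ambient pressure) so the first data point and small room-condition
drift cannot distort $r$. Two safeguards matter in practice: bounds keep
$r \ge 0$ and $H > 0$, and a series with no significant approach toward
ambient equilibrium (amplitude under four residual standard deviations)
is flagged `identifiable = FALSE` with a warning instead of returning an
arbitrary rate constant. The bundled reactor library carries the three
measured tube types (plastic centrifuge 50 mL: 3.02e-3; glass VOA 40 mL:
1.75e-3; double-ended VOA: 9.44e-4 mg/(min·bar)) with nominal volumes.
Note that published worst-case influx figures for such tubes depend on an
unstated effective-volume convention; the package computes influx from
nominal volume and 0.2095 bar-fraction ambient pressure, which gives
0.77 mg/(L·hr) for an anoxic plastic tube rather than attempting to match
any particular printed table.

## 4. Kinetics

Short sediment incubations typically show three regimes: an early
nonlinear (first-order-like) decline, a linear (zero-order) decline once
fast abiotic consumption is exhausted, and an anoxic plateau. No
published segmentation algorithm accompanies that narrative, so the
package uses an exhaustive changepoint search chosen for determinism and
testability: 0, 1 or 2 breakpoints placed on observed sampling times;
candidate phase sequences restricted to orderings of exponential → linear
→ constant; each candidate scored by AICc with breakpoints counted as
parameters; minimum four points per segment. The exponential segment is
fitted by profiling its rate constant with the two linear coefficients
solved exactly, which avoids nonlinear-optimiser failures inside the grid
search. Ties cannot occur in exact arithmetic; in floating point the
first minimiser encountered (fewer breakpoints first) wins, making the
procedure deterministic. When no candidate satisfies the minimum-points
rule the segmentation falls back to a single linear phase with an
explicit flag.

One behaviour worth understanding: on *noiseless* data from a constant
consumer inside a permeable tube, the criterion correctly prefers a
single exponential — the influx term really does make that curve convex.
At realistic sensor noise (≈0.1 mg/L after inversion) the parsimony
penalty dominates and the linear description wins. This is a feature of
information-criterion selection, not a defect; it is why the package's
kinetics validation uses sensor-scale noise.

Outlier handling is a Hampel filter: each point is compared to the median
of its window (default 5 points), scaled by the MAD within that same
window, masked beyond 3.5 scaled MADs. Per-window MAD matters: residuals
against a rolling median are zero at most points, so a global MAD
degenerates to zero and masks everything or nothing. A zero-MAD window
masks nothing (degenerate-case guard), and a warning fires if more than
20 % of points would be masked.

Rates: the zero-order consumption is the negated least-squares slope of
the linear phase, reported in mg/(L·hr) with consumption positive; the
first-order constant is the profiled exponential decay rate in 1/min.
The diffusion correction reconstructs metabolic consumption pointwise as
$-dC/dt$ plus the influx at each observed concentration. For the
zero-order phase, $-dC/dt$ is taken from the phase model's own derivative
(the LS slope): the mean of raw central differences telescopes to an
endpoint-only estimate whose variance at sensor-scale noise is several
percent of the rate, while the model derivative is exact for the phase
model and keeps the corrected-minus-uncorrected difference equal to the
mean influx — guaranteeing the corrected rate is never below the
uncorrected one whenever the tube sits below ambient equilibrium, the
direction of the bias the correction exists to remove. Central
differences are retained for the first-order phase, where $k$ is
re-estimated by regressing consumption on concentration through the
origin. Anoxia onset is reported only when the plateau mean falls below
the limit of quantification (when supplied) or 5 % saturation otherwise,
tying the kinetics output to the calibration metrology.

## 5. The synthetic campaign generator

The generator exists so every stage has a testable forward model. It
integrates per-tube consumption plus wall influx by forward Euler (step
≤ cadence/10), maps concentration through each disk's Stern–Volmer curve,
renders frames with pixel noise, and writes exactly the artefacts the
real pipeline reads (frames, manifest, ROI layout, registry, truth
tables). Forward Euler is deliberate: the fitter uses the analytical
reaeration curve, so generator and fitter are independent routes to the
same physics and can serve as each other's oracle; the integration error
is measurably first-order in the step.

Default scenario, fixed once: three tubes, frames every 2 minutes for
70 minutes (a realistic short-incubation cadence), initial concentration
6 mg/L (visibly below saturation, as samples consume oxygen during
preparation), first-order constant 0.03/min handing over to a zero-order
8 mg/(L·hr) decline at 10 minutes, anoxia floor 0.05 mg/L, plastic
50-mL tubes, disk-to-disk calibration spread R₀ 1.85–1.95 and K_SV
0.009–0.012 (the measured coefficient range), reference green level 80 DN
and pixel noise 1 DN at 8 bits. These choices make anoxia arrive around
46 minutes, reproducing the canonical three-phase shape.

What the generator emulates: quenching response with per-disk
coefficients, camera quantisation and additive noise, wall diffusion,
phase-structured kinetics, byte-identical reproducibility under a fixed
seed. What it does not: vignetting, demosaic artefacts, illumination
gradients, temperature drift, disk heterogeneity, or motion of rolling
tubes. Passing the pipeline-closure tests therefore demonstrates the
*software* chain is unbiased and consistent at realistic noise; it does
not certify any particular hardware configuration, which still needs its
own calibration and diffusion tests.

## 6. Validation problem sizes

The shipped tests validate: inversion against a bisection root-finder on
1000 random parameter draws (10⁻⁶ agreement); exact recovery of
generating parameters from noiseless response curves and reaeration
series (10⁻⁶); Monte-Carlo recovery over 100 seeds — $K_{SV}$ within 2 %
median relative error at ratio noise 0.005 on triplicate six-level
sweeps, permeability within 5 % at 0.05 mg/L noise on 15-minute/24-hour
series; first-order convergence of the Euler generator; full-pipeline
closure (simulate → extract → invert → segment → estimate) recovering
configured zero-order rates within 5 % on the default three-tube
campaign; and null-simulation type-I error of both statistical wrappers
within [0.025, 0.075] at 1000 replicates. These sizes keep the whole
suite under half a minute on one CPU while leaving each check's
Monte-Carlo error well inside its margin.

## 7. Known limitations

- No temperature-dependent calibration model: coefficients apply at
  their calibration temperature, and the package assumes thermal
  equilibrium with a controlled room.
- The salinity correction is a linear empirical fit over 0–3.5 % m/v
  NaCl; outside that range it extrapolates with a warning.
- Segmentation assumes the phase order exponential → linear → constant;
  regrowth, lag phases or multi-substrate kinetics are out of scope.
- The simple-ratio mode handles IR-filter-intact cameras, but no
  spectral modelling is attempted; switching cameras or filters requires
  recalibration.
- Within-disk heterogeneity is reduced to summary statistics per ROI; no
  2-D oxygen mapping.
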