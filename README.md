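# roptode

Data processing for camera-based ratiometric oxygen-optode arrays: from
time-lapse RGB images of sensor disks mounted in small sealed bioreactors,
through per-disk Stern–Volmer calibration, to dissolved-oxygen time series
and phase-resolved oxygen-consumption rates.

## Who this is for

Groups running parallel batch-reactor metabolism incubations (river or
marine sediment, soil slurries, water samples) with platinum-porphyrin
optode disks imaged by an ordinary colour camera under blue excitation.
Each disk's red emission is quenched by oxygen while its green reference
emission is not, so the red/green ratio encodes dissolved oxygen without
needing lifetime instrumentation. This package implements the full
analysis chain for such a system, plus a synthetic-frame simulator so the
chain can be validated end to end without hardware.

## The models at the core

**Sensing.** Each disk follows a modified Stern–Volmer quenching relation
on the ratio R = (red − green)/green:

    R(C) = R0 [ α + (1 − α) / (1 + Ksv · C) ]

with C dissolved oxygen in % air saturation, R0 the zero-oxygen ratio,
Ksv the quenching constant (per % saturation) and α the nonquenchable
signal fraction. The package fits this per disk (`fit_calibration`),
inverts it in closed form (`invert_calibration`), and derives limits of
detection and quantification as LOD = |3.3 σ/m| and LOQ = |10 σ/m| from
replicate noise σ and the response slope m over the 0.4–40 %-saturation
linear range (`compute_detection_limits`). When a camera's internal
IR-blocking filter is left in place, the simple ratio red/green can be
used instead (`ratio_def = "simple"`); the two differ by exactly 1.

**Units.** % air saturation converts to mg/L through a Benson–Krause
solubility model with linear pressure scaling (`sat_to_conc`,
`conc_to_sat`) and an empirical salinity correction
DO_salt = DO − q·S with q = −0.1903 t + 12.892 (`salinity_correct`).

**Wall diffusion.** A sealed tube admits oxygen at a rate proportional to
the partial-pressure gap with the room. The reaeration curve

    C(t) = pa·H − (pa − p0)·H·exp(−r t / (H V))

is fitted with the whole-tube permeability r, initial pressure p0 and
Henry coefficient H free (`fit_permeability`); the fitted r feeds a
pointwise influx correction that removes the downward bias wall diffusion
imparts to consumption rates.

**Kinetics.** Oxygen decline curves are segmented by exhaustive
changepoint search (0–2 breakpoints, AICc-selected) into a first-order
decline, a zero-order decline and an anoxic plateau
(`segment_phases`), and per-phase rates are estimated with optional
diffusion correction (`estimate_rates`).

## Worked example

Simulate a three-tube campaign (2-minute frames for 70 minutes, plastic
50-mL centrifuge tubes), extract, invert, and estimate rates:

```r
library(roptode)
env <- environment_conditions()          # 21 °C, 1013 mbar

cfg  <- scenario_config(seed = 42)       # truth: k = 0.03/min, then 8 mg/(L·hr)
camp <- simulate_campaign(cfg, dir = "demo_campaign")

out <- cli_extract(file.path("demo_campaign", "manifest.csv"),
                   file.path("demo_campaign", "roi_layout.csv"),
                   file.path("demo_campaign", "registry.json"), "demo_out")

concs <- out$concentrations
write.csv(data.frame(tube_id = concs$disk_id, time_min = concs$time_min,
                     conc_mg_L = pmax(sat_to_conc(concs$conc_pct_sat, env), 0)),
          "demo_conc.csv", row.names = FALSE)

cli_rates("demo_conc.csv", reactor_type = "plastic_centrifuge_50ml",
          correct_diffusion = TRUE)
```

which prints:

```
 tube_id zero_order_slope_mg_L_hr first_order_k_per_min anoxia_onset_min
   tube1                 7.950379            0.03105707               46
   tube2                 7.984682            0.03035104               46
   tube3                 7.977663            0.03001186               48
```

All three tubes were configured to consume 8 mg/(L·hr) in their zero-order
phase with a first-order constant of 0.03/min before the 10-minute
handover; the pipeline recovers the slopes within 0.6 % and the decay
constants within 4 % after a full round trip through rendered 8-bit
frames, ROI extraction, Stern–Volmer inversion and changepoint
segmentation. `anoxia_onset_min` is the start of the detected plateau,
reported because the plateau sits below the quantification threshold.

A shell entry point wrapping the same functions ships at
`inst/cli/roptode.R` (subcommands `calibrate`, `extract`, `rates`,
`simulate`).

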