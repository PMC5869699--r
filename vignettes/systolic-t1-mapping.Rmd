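---
title: "Systolic saturation-recovery T1 mapping: model, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systolic saturation-recovery T1 mapping: model, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sapphireT1)
```

## Scope

`sapphireT1` is a simulation + estimation toolkit for saturation-recovery
cardiac T1 mapping with a hybrid saturation/inversion (SAPPHIRE)
preparation, in both its conventional diastolic layout and the systolic
layout in which the saturation pulse is played in the heartbeat *before*
imaging. It operates entirely at the prepared-magnetization level: it
simulates longitudinal magnetization, preparation pulses and ECG-trigger
timing, not the imaging readout. Readout physics (bSSFP signal formation,
parallel-imaging acceleration, coil sensitivities, banding), through-plane
motion, flow and B0/B1 inhomogeneity are out of scope, as are in-vivo
analyses that require real anatomy.

## Signal model

All signals derive from mono-exponential longitudinal relaxation between
instantaneous preparation events. For equilibrium signal $M_0$ and
relaxation time $T_1$:

* unprepared frame: $S = M_0$ (the first frame of every schedule, modeled
  as fully recovered);
* saturation-only frame, saturation played $TS$ ms before readout:
  $S = M_0\,(1 - e^{-TS/T_1})$;
* hybrid frame, additionally an inversion of completeness $\delta$ at
  $TI \le TS$ ms before readout:
  $$S = M_0\left[1 - (1+\delta)\,e^{-TI/T_1} + \delta\,e^{-TS/T_1}\right].$$

The inversion contract is $M_z \mapsto -\delta M_z$: $\delta = 1$ is a
perfect adiabatic flip and $\delta = 0$ corresponds to a 90° pulse, which
*saturates* — so the $\delta = 0$ limit of the hybrid model is saturation
recovery over the remaining $TI$, and the $TI = TS$ limit is saturation
recovery over $TS$ for any $\delta$. An event-by-event piecewise
propagation (`bloch_piecewise()`) serves as the independent oracle; the
test suite sweeps a $T_1 \times TS \times TI$ grid and requires agreement
with the closed forms below $10^{-9}$ relative.

### The three fitted parameters

The estimator (`fit_three_param()`) fits $(M_0, T_1, \delta)$ with
saturation treated as ideal. The parameterization is a design choice: in
the systolic layout TS varies beat-by-beat, so the common trick of
absorbing preparation imperfection into a single apparent amplitude does
not transfer — a frame-independent physical parameter is needed, and
modern water-suppression (WET-type) saturation modules are near-ideal
while adiabatic inversions are the imperfection worth fitting. Bounds are
$T_1 \in [1, 5000]$ ms, $\delta \in [0, 1]$, $M_0 \in [0, 10\max|S|]$.

## Timing model

RR intervals are Gaussian draws with configurable mean and SD, clamped
below at a 300 ms floor — a physiological refractory bound; clamping
rather than redrawing was chosen so that the nominal mean/SD describe the
generating process and the mis-trigger probability stays available in
closed form (`mistrigger_probability()`).

**Diastolic schedule.** Saturation at the R-wave and readout at trigger
delay TD put $TS = TD$ for every prepared frame; only TI varies. The
default ten-frame TI list is
$[10000; 805; 113; 211; 309; 407; 505; 603; 701; 799]$ ms with
$TD = 805$ ms; the 10000 ms entry marks the unprepared frame and the
805 ms entry degenerates to saturation-only.

**Systolic schedule.** Saturation immediately after the previous readout
and readout at $TD_{sys}$ after the next R-wave give
$TS = $ the realized RR of the intervening beat. The default layout is
1 unprepared + 4 saturation-only + 5 hybrid frames (the 15-frame
1 + 7 + 7 variant is supported), hybrid TIs linearly spread over
$[100, TD_{sys}]$ ms. $TD_{sys}$ defaults to 300 ms — in practice it is
chosen visually from cine images and no canonical value exists; 300 ms is
a representative systolic trigger delay at typical heart rates. Every
frame records its realized (TS, TI) exactly, and frames whose realized TS
falls below their TI are flagged, dropped and warned about rather than
silently fitted.

**Mis-triggering.** Two modes relabel diastolic frames as systolic: a
mechanistic threshold rule (beat RR < TD) and a randomized-replacement
mode that computes the expected systolic share from the truncated-Gaussian
exceedance probability and relabels that many frames uniformly at random.
The threshold rule is the default because it is the actual failure
mechanism; the randomized mode reproduces simulation protocols that
replace a computed share of images in random order. Both are seeded.

## Phantom design

The cardiac phantom is a 650×650 mid-ventricular short-axis scene by
default: LV blood disc (T1 = 2048 ms), myocardial annulus (1578 ms), an
RV blood crescent hugging the septal side, and a thin epicardial fat rim
(382 ms). Only the grid size, the compartment T1s and the systolic
scaling (LV cavity diameter ×0.70, wall thickness ×1.40) are anchored
values; the radii (epicardial radius 0.231·grid, wall 0.0615·grid, fat
rim 0.0125·grid, RV crescent width 0.108·grid spanning 140° about the
leftward direction) are this package's own parameterization, chosen to
give plausible proportions and to keep the RV pool abutting the septum in
both phases so a horizontal LV→septum→RV line profile is well defined.
The RV crescent is implemented as a partial annulus around the epicardium,
which guarantees that property under systolic scaling. The vial phantom
places seven disjoint discs (T1 log-spaced 200–2000 ms by default — the
individual vial values are a package choice spanning the native and
post-contrast range) on a ring.

## Synthesis and noise

Frames are complex: $S\,e^{i(\phi_0 + \phi_{map})}$, with the sign of
$M_z$ carried on the real axis so inverted magnetization acquires a π
phase shift. Noise is i.i.d. complex Gaussian added per channel with
$\sigma = S_{ref}/\mathrm{SNR}$, where $S_{ref}$ is the unprepared
magnitude of a reference compartment (myocardium for the cardiac phantom,
the mean vial $M_0$ for vials) — anchoring SNR to the fully recovered
reference image that the phase-sensitive fit uses. Noise is added to the
complex data (required for phase-sensitive fitting) rather than to
magnitudes; at SNR 60 the Rician bias this induces in magnitude images is
negligible. Mis-triggered frames draw their pixel values from the
systolic geometry, so they differ from clean frames exactly inside the
moving-anatomy region.

## Polarity restoration

*Magnitude mode* sorts the inversion-prepared points by TI, flips the
first $k$ for $k = 0..n_{inv}$, refits each candidate and keeps the
smallest residual, breaking ties toward fewer flips (the physically
smoother solution). *Phase-sensitive mode* subtracts the phase of the
unprepared reference frame and assigns polarity −1 where
$|\Delta\phi| > \pi/2$. Because any static per-pixel phase cancels
exactly in the subtraction, the π/2 decision is invariant under $2\pi$
branches and is taken on the principal value by default; a 2D
path-following unwrapper (`unwrap_phase_2d()`, row-then-column, output
differing from input by exact multiples of $2\pi$) is available for
smooth foreground-only maps, but is off by default because on
noise-dominated background the unwrapping path accumulates arbitrary
branch jumps that corrupt downstream decisions.

## Numerical choices

* Fit initialization: $T_1$ from an 8-node logarithmic grid over
  50–3000 ms with the amplitude profiled out analytically, $M_0$ from the
  largest absolute signal, $\delta = 1$. This avoids the local minima a
  single fixed start suffers on short-T1 pixels without per-pixel tuning.
* Levenberg–Marquardt with analytic Jacobian; tolerance $10^{-8}$ on the
  relative sum-of-squares change, at most 200 iterations;
  non-convergence flags the pixel instead of raising.
* Background mask: unprepared-frame magnitude below 5% of its 99th
  percentile. Pure-noise pixels that leak through this threshold fit to
  garbage by construction; map-level comparisons in the tests therefore
  evaluate compartment pixels.
* Map fitting deduplicates exactly identical signal vectors and fits each
  once — exact on noiseless label phantoms (a handful of unique
  vectors per 650² map), a no-op on noisy data.
* FWHM: the blood plateau is the mean of the per-side medians of the
  outer 20% of the profile (robust to end noise), the half level is
  midway between plateau and septal minimum, and crossings are located
  with sub-sample linear interpolation on a profile sampled at 4× pixel
  density by bilinear interpolation.
* ECV uses the standard ΔR1 ratio
  $(1-\mathrm{hct})\,\Delta R_{1,myo}/\Delta R_{1,blood}$.
* Sector segmentation divides the annulus into equal angular sectors from
  the anterior RV insertion, counterclockwise; a single simulated slice
  means the full three-slice 16-segment analysis is supported but only
  exercised on one slice.

## What the generator does and does not emulate

It emulates: compartment-pure relaxation with the stated T1s, realistic
trigger schedules including arrhythmia and mis-triggering, systolic
geometry change, complex Gaussian noise at calibrated SNR. It does not
emulate: partial-volume mixing at borders (labels are crisp, so
border-pixel bias in real data is *under*-represented), readout-window
blurring, registration error, coil phase drift between frames, or
B0/B1-dependent preparation imperfection beyond the global $\delta$.
Passing tests therefore demonstrate correctness of the estimation
machinery and timing logic under the model's assumptions — not in-vivo
accuracy.

## Problem sizes

The acceptance computations use the full 650² grid for the noiseless
diastolic recovery and the FWHM ratio (deduplicated fitting makes these
cheap), ROI-level fits for the seven-vial RR-variability study, and a
128² grid with 10 repetitions for the mis-trigger precision-map study —
sizes at which every reported quantity is stable at the tolerances
asserted while keeping a full run in the minutes range on one core.

## Known limitations

* The three-parameter model assumes ideal saturation; a strongly
  imperfect saturation module would alias into $\delta$ and $T_1$.
* The path-following unwrapper is not residue-aware; genuinely wrapped
  noisy phase maps need a quality-guided method.
* The mis-trigger model swaps whole frames between two discrete phases;
  real mis-triggering produces a continuum of cardiac phases and
  in-plane deformation.
* ROI statistics assume label-pure regions; on real maps ROIs must be
  drawn conservatively to avoid border pixels.
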