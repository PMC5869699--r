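# sapphireT1

Desk-scale simulation and estimation toolkit for **systolic
saturation-recovery cardiac T1 mapping** with the SAPPHIRE
(Saturation-Pulse Prepared Heart-rate independent Inversion-REcovery)
preparation.

## The problem

Myocardial T1 mapping fits a relaxation model to a set of co-registered,
differently magnetization-prepared base-images acquired over several
heartbeats. Conventional diastolic imaging suffers from two coupled
problems:

* **Partial voluming** — the thin diastolic wall mixes myocardial and
  blood signal at the endo-/epicardial borders, biasing T1 upward.
* **Mis-triggering under arrhythmia** — a fixed trigger delay calibrated
  to diastole lands in the wrong cardiac phase whenever an RR interval
  shortens below it, so base-images stop being co-registered and the
  pixel-wise fit degrades.

Imaging in **systole** sidesteps both: the wall is ~40% thicker and the
systolic quiescent window is stable across common arrhythmias. But systole
begins too soon after the R-wave for a saturation prepared in the same
beat to recover usable signal. The systolic SAPPHIRE layout therefore
plays the saturation pulse in the *preceding* heartbeat, immediately after
the previous readout, and the inversion (when present) after the R-wave of
the imaging beat. The saturation-to-readout time TS then varies with the
realized RR interval — and the fit simply consumes the realized per-frame
(TS, TI), which is what makes the estimate heart-rate independent.

## The model

For a frame read out TS ms after an ideal saturation and TI ms after an
inversion of completeness δ (0 ≤ TI ≤ TS), the longitudinal signal is

    S(TS, TI) = M0 · [ 1 − (1 + δ)·e^(−TI/T1) + δ·e^(−TS/T1) ]

which reduces to saturation recovery `M0·(1 − e^(−TS/T1))` when TI = TS,
and to classical inversion recovery `M0·(1 − 2·e^(−TI/T1))` as TS → ∞ with
δ = 1. Unprepared frames read `M0`. Every closed form is verified in the
test suite against an event-by-event piecewise-Bloch propagation oracle to
better than 1e−9 relative.

T1 maps come from a pixel-wise 3-parameter Levenberg–Marquardt fit of
(M0, T1, δ). Signal polarity lost in magnitude images is restored either
by TI-sorted successive flipping with refit (diastole) or from the phase
difference to the unprepared reference image thresholded at π/2
(phase-sensitive fitting, required in systole where TS varies).

The package covers the full loop: numerical short-axis cardiac and
multi-vial phantoms → ECG-triggered frame schedules with RR variability
and mis-triggering → complex base-image synthesis with calibrated noise →
map/ROI fitting → accuracy, precision, CoV, septal FWHM, ECV, and sector
statistics. NIfTI + CSV/JSON sidecar I/O and `simulate`/`fit`/`report`
pipeline verbs (plus a thin CLI wrapper in `inst/cli/`) tie it together.

## Worked example

Seven agarose-style vials (T1 log-spaced 200–2000 ms), a systolic SAPPHIRE
schedule under heavy RR variability (SD 400 ms around a mean of 1125 ms),
SNR 60, phase-sensitive ROI fits:

```r
library(sapphireT1)
rr  <- generate_rr_series(mean_rr = 1125, sd_rr = 400, n = 11, seed = 7)
tim <- schedule_systolic(rr, td_sys = 300)
geo <- build_vial_phantom(grid = 128)
ser <- synthesize_series(geo, tim, snr = 60, seed = 7,
                         ref_compartment = "mean")
fit_t1_regions(ser, method = "phase_sensitive")
#>   region n_pixels     t1     m0 inv_eff       ssr
#> 1 vial_1      524  200.0 0.9999  1.0000 5.386e-06
#> 2 vial_2      520  293.3 0.9996  0.9998 4.622e-06
#> 3 vial_3      512  431.6 1.0001  0.9985 3.873e-06
#> 4 vial_4      512  632.4 0.9995  1.0000 1.605e-06
#> 5 vial_5      520  927.8 0.9992  1.0000 8.801e-06
#> 6 vial_6      512 1360.1 0.9996  0.9999 1.834e-06
#> 7 vial_7      512 2003.3 1.0011  1.0000 3.146e-06
```

Despite per-frame saturation times ranging from ~650 to ~2040 ms in this
draw, every fitted T1 lands within 0.2% of its vial's ground truth,
because each frame's realized (TS, TI) enters the model directly.

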