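#' Tissue relaxometry parameters
#'
#' Bundle of the per-compartment parameters that drive the longitudinal
#' signal model: the spin-lattice relaxation time `t1`, the equilibrium
#' signal `m0`, and an intrinsic receive phase `phase0` used when complex
#' base-images are synthesized.
#'
#' @param t1 Longitudinal relaxation time in ms; must be > 0.
#' @param m0 Equilibrium signal in arbitrary units; must be >= 0.
#' @param phase0 Intrinsic signal phase in radians, in (-pi, pi].
#' @return An object of class `tissue_params`.
#' @examples
#' myo <- tissue_params(t1 = 1578, m0 = 1)
#' saturation_signal(myo, ts = 805)
#' @export
tissue_params <- function(t1, m0 = 1, phase0 = 0) {
  if (!is.numeric(t1) || length(t1) != 1L || !is.finite(t1) || t1 <= 0)
    stop("t1 must be a single positive number (ms)")
  if (!is.numeric(m0) || length(m0) != 1L || !is.finite(m0) || m0 < 0)
    stop("m0 must be a single non-negative number")
  if (!is.numeric(phase0) || length(phase0) != 1L || !is.finite(phase0) ||
      phase0 <= -pi || phase0 > pi)
    stop("phase0 must lie in (-pi, pi]")
  structure(list(t1 = t1, m0 = m0, phase0 = phase0), class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("<tissue_params> T1 = %g ms, M0 = %g, phase0 = %g rad\n",
              x$t1, x$m0, x$phase0))
  invisible(x)
}

as_tissue <- function(x) {
  if (inherits(x, "tissue_params")) return(x)
  if (is.list(x) && all(c("t1", "m0") %in% names(x)))
    return(tissue_params(x$t1, x$m0, if (is.null(x$phase0)) 0 else x$phase0))
  stop("expected a tissue_params object")
}

#' Magnetization preparation event
#'
#' A single instantaneous event on the longitudinal-magnetization timeline:
#' a saturation pulse, an inversion pulse, or the readout that terminates
#' the frame. Preparations are treated as instantaneous; `efficiency` is
#' the residual fraction left by a saturation (0 = ideal) or the
#' completeness of an inversion (1 = perfect flip).
#'
#' @param kind One of `"saturation"`, `"inversion"`, `"readout"`.
#' @param time Event time in ms from the series origin; >= 0.
#' @param efficiency Dimensionless in \[0, 1\]; defaults to the ideal
#'   value for the kind (0 for saturation — complete null — and 1 for
#'   inversion — perfect flip).
#' @return An object of class `prep_event`.
#' @seealso [bloch_piecewise()]
#' @export
prep_event <- function(kind = c("saturation", "inversion", "readout"),
                       time, efficiency = NULL) {
  kind <- match.arg(kind)
  if (is.null(efficiency)) efficiency <- if (kind == "saturation") 0 else 1
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time) || time < 0)
    stop("event time must be a single non-negative number (ms)")
  if (!is.numeric(efficiency) || efficiency < 0 || efficiency > 1)
    stop("efficiency must lie in [0, 1]")
  structure(list(kind = kind, time = time, efficiency = efficiency),
            class = "prep_event")
}

#' Saturation-recovery signal
#'
#' Longitudinal signal at readout after an ideal saturation played `ts`
#' milliseconds earlier: `M0 * (1 - exp(-ts / T1))`. This is the
#' heart-rate independent saturation-recovery model; the signal grows
#' monotonically from 0 at `ts = 0` towards `M0`.
#'
#' @param tissue A [tissue_params()] object.
#' @param ts Saturation-to-readout delay in ms; vectorized, all >= 0.
#' @return Signal in the units of `m0`, same length as `ts`.
#' @export
saturation_signal <- function(tissue, ts) {
  tissue <- as_tissue(tissue)
  if (any(ts < 0)) stop("ts must be >= 0")
  tissue$m0 * (1 - exp(-ts / tissue$t1))
}

#' SAPPHIRE hybrid saturation/inversion signal
#'
#' Longitudinal signal at readout for the hybrid preparation: an ideal
#' saturation `ts` ms before readout, followed by an inversion of
#' completeness `inv_eff` at `ti` ms before readout, with free
#' mono-exponential relaxation in between:
#'
#' `M0 * (1 - (1 + inv_eff) * exp(-ti/T1) + inv_eff * exp(-ts/T1))`
#'
#' The saturation pins the starting condition (so the curve does not depend
#' on the magnetization history of earlier heartbeats), while the inversion
#' restores part of the inversion-recovery dynamic range. With `ti = ts` or
#' `inv_eff = 0` the expression reduces to [saturation_signal()]; with
#' `ts -> Inf` and `inv_eff = 1` it reduces to classical inversion recovery
#' `1 - 2 exp(-ti/T1)`.
#'
#' @param tissue A [tissue_params()] object.
#' @param ts Saturation-to-readout delay, ms (vectorized).
#' @param ti Inversion-to-readout delay, ms; `0 <= ti <= ts` elementwise.
#' @param inv_eff Inversion completeness in \[0, 1\]; 1 is a perfect flip.
#' @return Signal in the units of `m0`.
#' @export
sapphire_signal <- function(tissue, ts, ti, inv_eff = 1) {
  tissue <- as_tissue(tissue)
  if (any(ti < 0)) stop("ti must be >= 0")
  if (any(ti > ts)) stop("timing-order error: ti must not exceed ts")
  if (any(inv_eff < 0) || any(inv_eff > 1)) stop("inv_eff must lie in [0, 1]")
  tissue$m0 * (1 - (1 + inv_eff) * exp(-ti / tissue$t1) +
                 inv_eff * exp(-ts / tissue$t1))
}

#' Piecewise-Bloch longitudinal magnetization propagation
#'
#' Brute-force event-by-event propagation of Mz through a list of
#' instantaneous preparation events ending in a readout. Between events Mz
#' relaxes mono-exponentially, `Mz(t + d) = M0 + (Mz(t) - M0) * exp(-d/T1)`;
#' a saturation maps `Mz <- efficiency * Mz` (0 = ideal null) and an
#' inversion maps `Mz <- -efficiency * Mz`. This serves as the independent
#' oracle against which the closed-form signals are checked.
#'
#' @param tissue A [tissue_params()] object.
#' @param events List of [prep_event()] objects, strictly ordered in time,
#'   with exactly one terminal readout.
#' @param mz0 Initial longitudinal magnetization at time 0 (default `m0`,
#'   i.e. thermal equilibrium).
#' @return Mz at the readout, in the units of `m0`.
#' @export
bloch_piecewise <- function(tissue, events, mz0 = NULL) {
  tissue <- as_tissue(tissue)
  if (length(events) == 0L) stop("event list is empty")
  kinds <- vapply(events, function(e) e$kind, character(1))
  times <- vapply(events, function(e) e$time, numeric(1))
  if (is.unsorted(times, strictly = FALSE) || any(diff(times) < 0))
    stop("timing-order error: events must be ordered in time")
  if (kinds[length(kinds)] != "readout" || sum(kinds == "readout") != 1L)
    stop("exactly one readout must terminate the event list")
  mz <- if (is.null(mz0)) tissue$m0 else mz0
  t_now <- 0
  for (e in events) {
    mz <- tissue$m0 + (mz - tissue$m0) * exp(-(e$time - t_now) / tissue$t1)
    t_now <- e$time
    if (e$kind == "saturation") mz <- e$efficiency * mz
    if (e$kind == "inversion") mz <- -e$efficiency * mz
  }
  mz
}

#' Model signal for a vector of frame timings
#'
#' Vectorized dispatch of the signal model over a frame-timing table:
#' unprepared frames return `M0`, saturation-only frames the
#' saturation-recovery value at their realized TS, and hybrid frames the
#' SAPPHIRE value at their realized (TS, TI).
#'
#' @param tissue A [tissue_params()] object.
#' @param timings A [frame_timing()] data frame.
#' @param inv_eff Inversion completeness applied to hybrid frames.
#' @return Numeric vector of noiseless signals, one per frame.
#' @export
signal_series <- function(tissue, timings, inv_eff = 1) {
  tissue <- as_tissue(tissue)
  timings <- as_frame_timing(timings)
  n <- nrow(timings)
  out <- numeric(n)
  if (n == 0L) return(out)
  model_signal(timings$prep, timings$ts_ms, timings$ti_ms,
               t1 = tissue$t1, m0 = tissue$m0, inv_eff = inv_eff)
}

# Vectorized over frames; the workhorse shared by simulation and fitting.
model_signal <- function(prep, ts, ti, t1, m0, inv_eff) {
  e_ts <- exp(-ts / t1)
  e_ti <- exp(-ti / t1)
  out <- rep(m0, length(prep))
  sat <- prep == "sat"
  out[sat] <- m0 * (1 - e_ts[sat])
  si <- prep == "sat_inv"
  out[si] <- m0 * (1 - (1 + inv_eff) * e_ti[si] + inv_eff * e_ts[si])
  out
}
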