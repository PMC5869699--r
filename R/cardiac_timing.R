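#' Per-frame preparation timing table
#'
#' The timing contract every fit consumes: one row per base-image with its
#' preparation type and the *realized* saturation-to-readout (TS) and
#' inversion-to-readout (TI) delays in ms, plus the cardiac-phase label and
#' the RR interval of the beat the readout fell in. `ts_ms` is `Inf` for
#' unprepared frames; `ti_ms` is `NA` unless the frame carries an
#' inversion.
#'
#' @param index Integer frame numbers (0-based in sidecars, any base here).
#' @param prep Character, one of `"none"`, `"sat"`, `"sat_inv"` per frame.
#' @param ts_ms,ti_ms Realized delays in ms.
#' @param phase `"diastole"` or `"systole"` per frame.
#' @param rr_ms RR interval of the imaging beat, ms.
#' @return A `frame_timing` data frame.
#' @export
frame_timing <- function(index, prep, ts_ms, ti_ms = NA_real_,
                         phase = "diastole", rr_ms = NA_real_) {
  df <- data.frame(index = as.integer(index), prep = as.character(prep),
                   ts_ms = as.numeric(ts_ms), ti_ms = as.numeric(ti_ms),
                   phase = as.character(phase), rr_ms = as.numeric(rr_ms),
                   stringsAsFactors = FALSE)
  validate_frame_timing(df)
  class(df) <- c("frame_timing", "data.frame")
  df
}

validate_frame_timing <- function(df) {
  stopifnot(all(c("index", "prep", "ts_ms", "ti_ms", "phase", "rr_ms")
                %in% names(df)))
  if (!all(df$prep %in% c("none", "sat", "sat_inv")))
    stop("prep must be one of 'none', 'sat', 'sat_inv'")
  if (!all(df$phase %in% c("diastole", "systole")))
    stop("phase must be 'diastole' or 'systole'")
  si <- df$prep == "sat_inv"
  if (any(is.na(df$ti_ms[si])))
    stop("sat_inv frames must carry a TI")
  if (any(df$ti_ms[si] < 0 | df$ti_ms[si] > df$ts_ms[si]))
    stop("timing-order error: require 0 <= ti <= ts for sat_inv frames")
  invisible(df)
}

as_frame_timing <- function(x) {
  if (inherits(x, "frame_timing")) return(x)
  if (is.data.frame(x)) {
    validate_frame_timing(x)
    class(x) <- c("frame_timing", "data.frame")
    return(x)
  }
  stop("expected a frame_timing data frame")
}

#' Default diastolic TI schedule (ms)
#'
#' The ten-image inversion-time list used by the diastolic simulations:
#' a first effectively unprepared frame (TI sentinel 10000 ms, far beyond
#' any myocardial T1), one saturation-only frame at TI = TD = 805 ms, and
#' eight hybrid frames with TIs spanning 113-799 ms.
#' @return Numeric vector of length 10.
#' @export
default_ti_schedule <- function() {
  c(10000, 805, 113, 211, 309, 407, 505, 603, 701, 799)
}

#' RR-interval series with arrhythmia
#'
#' Draws RR intervals from a Gaussian with the requested mean and standard
#' deviation, truncated below at a physiological floor (redrawing values
#' under the floor would distort the mean; instead they are clamped, which
#' mimics a refractory bound). `sd_rr = 0` returns a constant series.
#'
#' @param mean_rr Mean RR interval, ms (> 0).
#' @param sd_rr Standard deviation of the RR interval, ms (>= 0).
#' @param n Number of intervals to draw (>= 1).
#' @param seed Integer seed; the series is reproducible under a fixed seed.
#' @param floor_ms Lower truncation bound, ms (default 300).
#' @return An `rr_series` list with fields `mean_rr`, `sd_rr`, `values`,
#'   `seed`, `floor_ms`.
#' @examples
#' rr <- generate_rr_series(667, 200, n = 11, seed = 7)
#' range(rr$values)
#' @export
generate_rr_series <- function(mean_rr, sd_rr, n, seed, floor_ms = 300) {
  stopifnot(mean_rr > 0, sd_rr >= 0, n >= 1)
  set.seed(as.integer(seed))
  values <- if (sd_rr == 0) rep(mean_rr, n) else
    pmax(stats::rnorm(n, mean_rr, sd_rr), floor_ms)
  structure(list(mean_rr = mean_rr, sd_rr = sd_rr, values = values,
                 seed = as.integer(seed), floor_ms = floor_ms),
            class = "rr_series")
}

#' Arrhythmia factor to RR standard deviation
#'
#' The arrhythmia severity convention used throughout: a factor expresses
#' the RR standard deviation as a fraction of the mean RR length.
#'
#' @param factor Fraction >= 0 (e.g. 0.30 for 30%).
#' @param mean_rr Mean RR, ms.
#' @return Standard deviation in ms.
#' @export
arrhythmia_factor_to_sd <- function(factor, mean_rr) {
  stopifnot(all(factor >= 0))
  factor * mean_rr
}

#' Diastolic SAPPHIRE frame schedule
#'
#' Conventional diastolic layout: the first frame is acquired without
#' preparation (full recovery); every following frame has both the
#' saturation (at the R-wave) and the inversion played within the imaging
#' beat, so TS equals the trigger delay `td` for all prepared frames and
#' only TI varies. A TI equal to `td` degenerates to a saturation-only
#' frame. The first TI in `ti_list` is a sentinel (>= 9999) marking the
#' unprepared frame.
#'
#' @param rr An `rr_series` (used for beat RR bookkeeping / mis-trigger).
#' @param td Trigger delay, ms (default 805).
#' @param ti_list TI list in ms, one per frame; defaults to
#'   [default_ti_schedule()].
#' @return A [frame_timing()] table, all frames labeled diastole.
#' @export
schedule_diastolic <- function(rr, td = 805, ti_list = default_ti_schedule()) {
  n <- length(ti_list)
  stopifnot(n >= 1, length(rr$values) >= n)
  prepped <- ti_list < 9999
  if (any(ti_list[prepped] > td))
    stop("schedule error: TI exceeds the trigger delay")
  prep <- ifelse(prepped, ifelse(ti_list == td, "sat", "sat_inv"), "none")
  frame_timing(index = seq_len(n) - 1L, prep = prep,
               ts_ms = ifelse(prepped, td, Inf),
               ti_ms = ifelse(prep == "sat_inv", ti_list, NA_real_),
               phase = "diastole", rr_ms = rr$values[seq_len(n)])
}

#' Systolic SAPPHIRE frame schedule
#'
#' Systolic layout: the narrow window between the R-wave and systolic
#' readout leaves no room for saturation recovery, so the saturation pulse
#' is played in the *preceding* heartbeat, immediately after the previous
#' readout. TS is therefore the realized interval between consecutive
#' readouts — it varies beat-by-beat with the RR series — while the
#' inversion (when present) is played after the R-wave of the imaging beat
#' at `ti` before readout. The realized (TS, TI) of every frame is recorded
#' exactly; downstream fits consume realized timing, which is what makes
#' the method heart-rate independent.
#'
#' Frames where the realized TS falls below the requested TI are flagged
#' and dropped with a warning (the preparation order would be violated).
#'
#' @param rr An `rr_series` with at least `n_frames + 1` values.
#' @param td_sys Systolic trigger delay, ms (default 300).
#' @param n_sat Number of saturation-only frames (default 4).
#' @param n_inv Number of hybrid saturation+inversion frames (default 5).
#' @param ti_spread Length-2 numeric `(min, max)` ms over which the hybrid
#'   TIs are linearly spread; max must not exceed `td_sys`.
#' @return A [frame_timing()] table of `1 + n_sat + n_inv` frames (minus
#'   any dropped), all labeled systole.
#' @examples
#' rr <- generate_rr_series(1125, 0, n = 11, seed = 1)
#' schedule_systolic(rr, td_sys = 300)
#' @export
schedule_systolic <- function(rr, td_sys = 300, n_sat = 4, n_inv = 5,
                              ti_spread = c(100, td_sys)) {
  n <- 1L + n_sat + n_inv
  stopifnot(length(rr$values) >= n, length(ti_spread) == 2)
  if (ti_spread[2] > td_sys)
    stop("schedule error: TI spread exceeds the systolic trigger delay")
  tis <- if (n_inv > 0) seq(ti_spread[1], ti_spread[2], length.out = n_inv)
         else numeric(0)
  prep <- c("none", rep("sat", n_sat), rep("sat_inv", n_inv))
  # readout i sits at R_i + td_sys; saturation for frame i is played at the
  # previous readout, so TS equals the realized RR of the intervening beat.
  ts <- c(Inf, rr$values[2:n])
  ti <- c(rep(NA_real_, 1 + n_sat), tis)
  bad <- prep == "sat_inv" & ts < ti
  if (any(bad)) {
    warning(sprintf("dropping %d frame(s) with realized TS < TI", sum(bad)))
    keep <- !bad
  } else keep <- rep(TRUE, n)
  frame_timing(index = (seq_len(n) - 1L)[keep], prep = prep[keep],
               ts_ms = ts[keep], ti_ms = ti[keep], phase = "systole",
               rr_ms = rr$values[seq_len(n)][keep])
}

#' Mis-trigger relabeling of a diastolic schedule
#'
#' When the diastolic phase shortens during imaging, the fixed trigger
#' delay can extend beyond the next R-wave and the readout lands in
#' systole. Two modes are provided:
#' \describe{
#'   \item{`"threshold"`}{a frame is relabeled systole when its beat RR is
#'     shorter than the trigger delay `td` (the mechanistic rule).}
#'   \item{`"random"`}{a target systolic share is computed as the
#'     truncated-Gaussian probability `P(RR < td)` under the RR-series
#'     parameters, and that share of frames, chosen uniformly at random,
#'     is relabeled (the randomized-replacement mode used to emulate the
#'     reference simulations).}
#' }
#'
#' @param timings A diastolic [frame_timing()] table.
#' @param rr The `rr_series` that generated the beats.
#' @param td Trigger delay, ms.
#' @param mode `"threshold"` (default) or `"random"`.
#' @param seed Seed for the `"random"` mode.
#' @return The timing table with updated `phase` labels.
#' @export
apply_mistrigger <- function(timings, rr, td = 805,
                             mode = c("threshold", "random"), seed = 1) {
  timings <- as_frame_timing(timings)
  mode <- match.arg(mode)
  if (mode == "threshold") {
    timings$phase[timings$rr_ms < td] <- "systole"
  } else {
    p <- mistrigger_probability(rr$mean_rr, rr$sd_rr, td, rr$floor_ms)
    n_swap <- round(p * nrow(timings))
    if (n_swap > 0) {
      set.seed(as.integer(seed))
      idx <- sample.int(nrow(timings), n_swap)
      timings$phase[idx] <- "systole"
    }
  }
  timings
}

#' Probability that a truncated-Gaussian RR interval undercuts the trigger
#' delay
#'
#' Exceedance probability `P(RR < td)` for RR drawn from a Gaussian with
#' the given mean/SD clamped below at `floor_ms` — the expected share of
#' mis-triggered frames under the threshold rule.
#'
#' @param mean_rr,sd_rr Gaussian parameters, ms.
#' @param td Trigger delay, ms.
#' @param floor_ms Truncation floor, ms.
#' @return Probability in \[0, 1\].
#' @export
mistrigger_probability <- function(mean_rr, sd_rr, td, floor_ms = 300) {
  if (sd_rr == 0) return(as.numeric(mean_rr < td))
  if (td <= floor_ms) return(0)
  # clamping (not redrawing) piles mass at the floor, which still lies
  # below td whenever td > floor: P(clamped RR < td) = P(raw RR < td)
  stats::pnorm((td - mean_rr) / sd_rr)
}

#' Write / read a frame-timing sidecar
#'
#' Serializes a timing table to CSV (and optionally a JSON twin) with
#' columns `index, prep, ts_ms, ti_ms, phase, rr_ms`; ms units, 0-based
#' frame indices. `read_timing_sidecar` round-trips either format.
#'
#' @param timings A [frame_timing()] table.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `write_timing_sidecar` returns `path` invisibly;
#'   `read_timing_sidecar` returns a [frame_timing()] table.
#' @export
write_timing_sidecar <- function(timings, path) {
  timings <- as_frame_timing(timings)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(timings), path, digits = NA,
                         na = "null")
  } else {
    utils::write.csv(as.data.frame(timings), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_timing_sidecar
#' @export
read_timing_sidecar <- function(path) {
  df <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  df$ts_ms <- as.numeric(df$ts_ms)  # "Inf" survives CSV as character
  df$ti_ms <- as.numeric(df$ti_ms)
  # JSON has no Inf: unprepared frames come back as null
  df$ts_ms[df$prep == "none" & is.na(df$ts_ms)] <- Inf
  as_frame_timing(df)
}
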