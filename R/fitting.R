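#' Three-parameter saturation/inversion-recovery fit
#'
#' Levenberg-Marquardt least-squares fit of the longitudinal recovery model
#' to signed (polarity-restored) signals. The three parameters are the
#' equilibrium signal M0, the relaxation time T1 and the inversion
#' completeness: with variable saturation delays in systole a single
#' apparent-amplitude parameterization cannot absorb timing variation, so
#' the model keeps saturation ideal and fits the inversion efficiency
#' instead. The model per frame is dispatched on the preparation type
#' (unprepared / saturation-only / saturation+inversion) at the frame's
#' realized (TS, TI).
#'
#' Initialization takes T1 from a coarse 8-node logarithmic grid search
#' (with the amplitude profiled out analytically), M0 from the largest
#' absolute signal, and inversion efficiency 1. Convergence tolerance is
#' 1e-8 on the relative sum-of-squares change, at most 200 iterations.
#'
#' @param signals Numeric vector of signed signals, one per frame.
#' @param timings A [frame_timing()] table with `nrow == length(signals)`;
#'   at least 4 frames (3 parameters + 1 dof).
#' @param init Optional named vector `c(t1=, m0=, inv_eff=)` overriding the
#'   grid-search initialization.
#' @param bounds Optional list with `lower`/`upper` named vectors; defaults
#'   T1 in \[1, 5000\] ms, inv_eff in \[0, 1\], M0 in \[0, 10 max|signal|\].
#' @return A list: `t1` (ms), `m0`, `inv_eff`, `ssr`, `converged`.
#' @examples
#' tim <- schedule_diastolic(generate_rr_series(667, 0, 11, 1))
#' s <- signal_series(tissue_params(1578), tim)
#' fit_three_param(s, tim)$t1
#' @export
fit_three_param <- function(signals, timings, init = NULL, bounds = NULL) {
  timings <- as_frame_timing(timings)
  n <- length(signals)
  if (n != nrow(timings)) stop("signals/timings length mismatch")
  if (n < 4L) stop("at least 4 frames are required for a 3-parameter fit")
  prep <- timings$prep; ts <- timings$ts_ms; ti <- timings$ti_ms
  smax <- max(abs(signals))
  if (smax == 0) return(list(t1 = NA_real_, m0 = 0, inv_eff = NA_real_,
                             ssr = 0, converged = FALSE))
  if (is.null(bounds))
    bounds <- list(lower = c(t1 = 1, m0 = 0, inv_eff = 0),
                   upper = c(t1 = 5000, m0 = 10 * smax, inv_eff = 1))
  if (is.null(init)) {
    t1_grid <- exp(seq(log(50), log(3000), length.out = 8))
    best <- Inf; t1_0 <- 1000; m0_0 <- smax
    for (t1g in t1_grid) {
      g <- model_signal(prep, ts, ti, t1 = t1g, m0 = 1, inv_eff = 1)
      m0g <- sum(signals * g) / max(sum(g * g), .Machine$double.eps)
      m0g <- min(max(m0g, bounds$lower["m0"]), bounds$upper["m0"])
      ssr <- sum((signals - m0g * g)^2)
      if (ssr < best) { best <- ssr; t1_0 <- t1g; m0_0 <- m0g }
    }
    init <- c(t1 = t1_0, m0 = max(m0_0, smax), inv_eff = 1)
  }
  resid_fn <- function(p)
    model_signal(prep, ts, ti, p[1], p[2], p[3]) - signals
  jac_fn <- function(p) {
    t1 <- p[1]; m0 <- p[2]; e <- p[3]
    e_ts <- exp(-ts / t1); e_ti <- exp(-ti / t1)
    w_ts <- ifelse(is.finite(ts), e_ts * ts, 0) / t1^2
    w_ti <- ifelse(is.finite(ti), e_ti * ti, 0) / t1^2
    J <- matrix(0, length(prep), 3)
    sat <- prep == "sat"; si <- prep == "sat_inv"; no <- prep == "none"
    J[no, 2] <- 1
    J[sat, 1] <- -m0 * w_ts[sat]
    J[sat, 2] <- 1 - e_ts[sat]
    J[si, 1] <- m0 * (-(1 + e) * w_ti[si] + e * w_ts[si])
    J[si, 2] <- 1 - (1 + e) * e_ti[si] + e * e_ts[si]
    J[si, 3] <- m0 * (e_ts[si] - e_ti[si])
    J
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = init, fn = resid_fn, jac = jac_fn,
                       lower = bounds$lower, upper = bounds$upper,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-8, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(t1 = NA_real_, m0 = NA_real_, inv_eff = NA_real_,
                ssr = NA_real_, converged = FALSE))
  p <- fit$par
  list(t1 = unname(p[1]), m0 = unname(p[2]), inv_eff = unname(p[3]),
       ssr = fit$deviance, converged = fit$info %in% 1:4)
}

#' Magnitude polarity restoration by successive flipping
#'
#' Recovers the sign of the longitudinal magnetization from magnitude-only
#' data: the inversion-prepared points are sorted by TI and the first k of
#' them are flipped negative for k = 0 .. n_inv; each candidate is fitted
#' and the sign pattern with the smallest residual wins (ties go to the
#' fewest flips, the physically smoother choice). Saturation-only and
#' unprepared frames are always non-negative and never flipped.
#'
#' @param magnitudes Numeric vector of magnitude signals, one per frame.
#' @param timings A [frame_timing()] table.
#' @return A list: `signed` (polarity-restored signals), `polarity`
#'   (+1/-1 per frame), `fit` (the winning [fit_three_param()] result),
#'   `n_flipped`.
#' @export
restore_polarity_magnitude <- function(magnitudes, timings) {
  timings <- as_frame_timing(timings)
  inv_idx <- which(timings$prep == "sat_inv")
  ord <- inv_idx[order(timings$ti_ms[inv_idx])]
  best <- NULL; best_sign <- NULL; best_k <- 0L
  for (k in 0:length(ord)) {
    sgn <- rep(1, length(magnitudes))
    if (k > 0) sgn[ord[seq_len(k)]] <- -1
    fit <- fit_three_param(sgn * magnitudes, timings)
    if (is.null(best) || (is.finite(fit$ssr) && fit$ssr < best$ssr)) {
      best <- fit; best_sign <- sgn; best_k <- k
    }
  }
  list(signed = best_sign * magnitudes, polarity = best_sign,
       fit = best, n_flipped = best_k)
}

#' Vector phase unwrapping (path-following)
#'
#' Adds integer multiples of 2*pi so that successive differences lie in
#' (-pi, pi].
#' @param v Numeric vector of phases, radians.
#' @return Unwrapped vector; `out - v` is a multiple of 2*pi elementwise.
#' @export
unwrap_vector <- function(v) {
  if (length(v) < 2) return(v)
  d <- diff(v)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(v[1], v[1] + cumsum(d))
}

#' 2D spatial phase unwrapping
#'
#' Row-then-column path-following unwrap: the first row is unwrapped as a
#' vector, then every column is unwrapped downward anchored at the first
#' row. The output differs from the input by integer multiples of 2*pi at
#' every pixel and is continuous along the unwrapping paths; adequate for
#' the smooth phase maps the simulator produces (it is not residue-aware).
#'
#' @param phase Matrix of wrapped phases, radians.
#' @return Matrix of unwrapped phases.
#' @export
unwrap_phase_2d <- function(phase) {
  if (nrow(phase) < 2 || ncol(phase) < 2) return(phase)
  row1 <- unwrap_vector(phase[1, ])
  d <- phase[-1, , drop = FALSE] - phase[-nrow(phase), , drop = FALSE]
  d <- d - 2 * pi * round(d / (2 * pi))
  cs <- apply(d, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
  out <- rbind(row1, sweep(cs, 2, row1, "+"))
  dimnames(out) <- NULL
  out
}

#' Phase-sensitive polarity map
#'
#' Determines the sign of the longitudinal magnetization from complex
#' base-images: the phase of the non-magnetization-prepared reference
#' frame is subtracted from every frame and pixels with |phase difference|
#' > pi/2 are assigned polarity -1, the rest +1. Because any static
#' per-pixel phase (coil, off-resonance) cancels exactly in the
#' subtraction, the decision can be taken on the principal value of the
#' difference — the pi/2 threshold is invariant under 2*pi branches.
#' Optional spatial unwrapping (re-anchored at the brightest reference
#' pixel, which is certainly non-inverted) is available for smooth
#' foreground-only data; on maps with noise-dominated background the
#' unwrapping path accumulates arbitrary branch jumps, so it is off by
#' default.
#'
#' @param frames Complex array `x * y * n_frames`.
#' @param reference_index Index of the unprepared frame.
#' @param unwrap Logical; spatially unwrap each difference image before
#'   thresholding (default FALSE).
#' @return Integer array of the same shape with values in \{-1, +1\}.
#' @export
polarity_from_phase <- function(frames, reference_index, unwrap = FALSE) {
  if (!is.complex(frames)) stop("phase-sensitive polarity needs complex data")
  dm <- dim(frames)
  ref <- frames[, , reference_index]
  anchor <- which.max(Mod(ref))
  pol <- array(1L, dim = dm)
  for (i in seq_len(dm[3])) {
    dphi <- Arg(frames[, , i] * Conj(ref))
    if (unwrap) {
      dphi <- unwrap_phase_2d(dphi)
      # remove the global 2*pi branch so the surely-positive anchor pixel
      # reads near its principal value
      a <- dphi[anchor]
      dphi <- dphi - 2 * pi * round((a - Arg((frames[, , i] * Conj(ref))[anchor])) / (2 * pi))
    }
    pol[, , i][abs(dphi) > pi / 2] <- -1L
  }
  pol
}

#' Pixel-wise T1 map estimation
#'
#' Restores signal polarity with the chosen strategy, masks out the
#' background, and runs the three-parameter fit per pixel. Identical
#' signal vectors are fitted once and the result broadcast (exact
#' deduplication — a large saving on noiseless label phantoms, a no-op on
#' noisy data).
#'
#' @param series A `phantom_series`, or a list with `frames` (complex or
#'   numeric array `x*y*n`) and `timings`.
#' @param method `"magnitude"` (flip-and-refit polarity restoration, the
#'   diastolic default) or `"phase_sensitive"` (phase-difference polarity,
#'   required in systole where TS varies).
#' @param mask Optional logical matrix of pixels to fit; default excludes
#'   background (unprepared-frame magnitude below 5% of its 99th
#'   percentile).
#' @param dedupe Fit unique signal vectors only (default TRUE).
#' @return A `t1_map_result` list of matrices `t1`, `m0`, `inv_eff`,
#'   `ssr`, `polarity` (of the last inversion frame), `converged`, `mask`,
#'   plus `method`.
#' @export
fit_t1_map <- function(series, method = c("magnitude", "phase_sensitive"),
                       mask = NULL, dedupe = TRUE) {
  method <- match.arg(method)
  frames <- series$frames
  timings <- as_frame_timing(series$timings)
  dm <- dim(frames)
  if (dm[3] != nrow(timings)) stop("frame/timing count mismatch")
  ref_idx <- which(timings$prep == "none")[1]
  if (is.na(ref_idx)) stop("series has no unprepared reference frame")
  mag <- Mod(frames)
  if (is.null(mask)) {
    ref_mag <- mag[, , ref_idx]
    mask <- ref_mag >= 0.05 * stats::quantile(ref_mag, 0.99)
  }
  n_px <- sum(mask)
  if (method == "phase_sensitive") {
    if (!is.complex(frames))
      stop("method-unavailable error: phase-sensitive fitting needs complex data")
    pol <- polarity_from_phase(frames, ref_idx)
    signed <- pol * mag
  } else {
    signed <- mag  # per-pixel flipping happens inside the fit loop
    pol <- array(1L, dm)
  }
  sigmat <- matrix(signed[rep(mask, dm[3])], nrow = n_px)  # pixels x frames
  fit_one <- function(s) {
    if (method == "magnitude") {
      r <- restore_polarity_magnitude(s, timings)
      c(r$fit$t1, r$fit$m0, r$fit$inv_eff, r$fit$ssr,
        as.numeric(r$fit$converged), r$polarity[length(r$polarity)])
    } else {
      f <- fit_three_param(s, timings)
      c(f$t1, f$m0, f$inv_eff, f$ssr, as.numeric(f$converged),
        sign(s[length(s)]))
    }
  }
  if (dedupe && n_px > 1) {
    key <- apply(sigmat, 1, paste, collapse = "\r")
    uk <- !duplicated(key)
    res_u <- apply(sigmat[uk, , drop = FALSE], 1, fit_one)
    res <- res_u[, match(key, key[uk]), drop = FALSE]
  } else {
    res <- apply(sigmat, 1, fit_one)
  }
  blank <- function() matrix(NA_real_, dm[1], dm[2])
  out <- list(t1 = blank(), m0 = blank(), inv_eff = blank(), ssr = blank(),
              polarity = blank(), converged = matrix(FALSE, dm[1], dm[2]),
              mask = mask, method = method, timings = timings)
  out$t1[mask] <- res[1, ]; out$m0[mask] <- res[2, ]
  out$inv_eff[mask] <- res[3, ]; out$ssr[mask] <- res[4, ]
  out$converged[mask] <- res[5, ] > 0
  out$polarity[mask] <- res[6, ]
  class(out) <- "t1_map_result"
  out
}

#' ROI-level T1 fits
#'
#' Averages the complex signal over each labeled region per frame (the way
#' manually drawn phantom ROIs are analyzed), restores polarity with the
#' chosen strategy on the region-mean signals, and fits the
#' three-parameter model once per region.
#'
#' @param series A `phantom_series` carrying `labels` and `regions`.
#' @param method `"phase_sensitive"` or `"magnitude"`.
#' @return Data frame: `region`, `n_pixels`, `t1`, `m0`, `inv_eff`, `ssr`.
#' @export
fit_t1_regions <- function(series,
                           method = c("phase_sensitive", "magnitude")) {
  method <- match.arg(method)
  timings <- as_frame_timing(series$timings)
  labels <- series$labels
  regions <- series$regions
  n <- nrow(timings)
  ref_idx <- which(timings$prep == "none")[1]
  out <- list()
  for (j in seq_len(nrow(regions))) {
    sel <- labels == regions$label[j]
    if (!any(sel)) next
    msig <- vapply(seq_len(n),
                   function(i) mean(series$frames[, , i][sel]),
                   complex(1))
    if (method == "phase_sensitive") {
      dphi <- Arg(msig * Conj(msig[ref_idx]))
      signed <- ifelse(abs(dphi) > pi / 2, -1, 1) * Mod(msig)
      fit <- fit_three_param(signed, timings)
    } else {
      fit <- restore_polarity_magnitude(Mod(msig), timings)$fit
    }
    out[[j]] <- data.frame(region = regions$name[j], n_pixels = sum(sel),
                           t1 = fit$t1, m0 = fit$m0, inv_eff = fit$inv_eff,
                           ssr = fit$ssr, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
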