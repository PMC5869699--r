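#' Numerical cardiac phantom specification
#'
#' Geometry of the mid-ventricular short-axis phantom: a left-ventricular
#' (LV) blood disc surrounded by a myocardial annulus, a crescent-shaped
#' right-ventricular (RV) blood pool hugging the septal side, and a thin
#' epicardial fat rim. All radii scale linearly with the grid so the same
#' spec renders at 650 (default) or any smaller desk-scale grid. Systolic
#' geometry shrinks the LV cavity diameter to `diameter_factor` (default
#' 0.70) and thickens the wall by `thickness_factor` (default 1.40) about
#' the LV center.
#'
#' @param grid Pixels per side (default 650).
#' @param pixel_mm Pixel spacing in mm (default 1.2).
#' @param lv_center Length-2 `(x, y)` pixel coordinates of the LV center;
#'   default places it slightly right of the image center.
#' @param lv_outer_radius Diastolic epicardial radius, pixels.
#' @param wall_thickness Diastolic myocardial wall thickness, pixels.
#' @param fat_rim_thickness Epicardial fat rim thickness, pixels (0 drops
#'   the fat compartment).
#' @param rv_pool_width Radial width of the RV crescent, pixels.
#' @param rv_span_deg Angular span of the RV crescent, degrees, centered on
#'   the leftward (septal) direction.
#' @param systolic_scale Named list with `diameter_factor` and
#'   `thickness_factor`.
#' @param compartments Named list mapping `myocardium`, `blood`, `fat` to
#'   [tissue_params()] objects; defaults T1 = 1578 / 2048 / 382 ms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = 650, pixel_mm = 1.2,
                         lv_center = c(round(0.58 * grid), round(0.50 * grid)),
                         lv_outer_radius = 0.231 * grid,
                         wall_thickness = 0.0615 * grid,
                         fat_rim_thickness = 0.0125 * grid,
                         rv_pool_width = 0.108 * grid,
                         rv_span_deg = 140,
                         systolic_scale = list(diameter_factor = 0.70,
                                               thickness_factor = 1.40),
                         compartments = list(
                           myocardium = tissue_params(1578),
                           blood = tissue_params(2048),
                           fat = tissue_params(382))) {
  stopifnot(wall_thickness < lv_outer_radius,
            systolic_scale$diameter_factor > 0,
            systolic_scale$thickness_factor > 0)
  spec <- list(grid = as.integer(grid), pixel_mm = pixel_mm,
               lv_center = lv_center, lv_outer_radius = lv_outer_radius,
               wall_thickness = wall_thickness,
               fat_rim_thickness = fat_rim_thickness,
               rv_pool_width = rv_pool_width, rv_span_deg = rv_span_deg,
               systolic_scale = systolic_scale,
               compartments = lapply(compartments, as_tissue))
  # systolic epicardial radius must stay inside the grid
  if (lv_outer_radius + rv_pool_width + fat_rim_thickness > grid / 2)
    stop("spec error: geometry overflows the grid")
  structure(spec, class = "phantom_spec")
}

#' Build the short-axis cardiac phantom label and truth maps
#'
#' Rasterizes the phantom for one cardiac phase. Labels: 0 background,
#' 1 LV myocardium, 2 LV blood, 3 RV blood, 4 epicardial fat. The
#' per-pixel ground-truth T1/M0/phase maps are derived from the
#' compartment table (LV and RV blood share the blood tissue).
#'
#' @param spec A [phantom_spec()].
#' @param phase `"diastole"` or `"systole"`.
#' @return A `phantom_geometry` list: `labels` (integer matrix, row = y),
#'   `truth_t1`, `truth_m0`, `truth_phase0` matrices, `regions`
#'   (label/name/tissue lookup), `spec`, `phase`.
#' @export
build_cardiac_phantom <- function(spec, phase = c("diastole", "systole")) {
  phase <- match.arg(phase)
  g <- spec$grid
  cav_r <- spec$lv_outer_radius - spec$wall_thickness
  wall <- spec$wall_thickness
  if (phase == "systole") {
    cav_r <- cav_r * spec$systolic_scale$diameter_factor
    wall <- wall * spec$systolic_scale$thickness_factor
  }
  out_r <- cav_r + wall
  cx <- spec$lv_center[1]; cy <- spec$lv_center[2]
  x <- matrix(rep(seq_len(g), each = g), nrow = g)   # column index
  y <- matrix(rep(seq_len(g), times = g), nrow = g)  # row index
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  ang <- atan2(-(y - cy), x - cx)                    # y-up convention
  # angular distance from the leftward (septal) direction
  d_left <- abs(atan2(sin(ang - pi), cos(ang - pi)))
  in_rv <- r >= out_r & r < out_r + spec$rv_pool_width &
    d_left <= (spec$rv_span_deg / 2) * pi / 180
  in_fat <- spec$fat_rim_thickness > 0 & r >= out_r &
    r < out_r + spec$fat_rim_thickness & !in_rv
  labels <- matrix(0L, g, g)
  labels[in_fat] <- 4L
  labels[in_rv] <- 3L
  labels[r < out_r] <- 1L
  labels[r < cav_r] <- 2L
  regions <- data.frame(
    label = 1:4,
    name = c("myocardium", "lv_blood", "rv_blood", "fat"),
    tissue = c("myocardium", "blood", "blood", "fat"),
    stringsAsFactors = FALSE)
  geometry_from_labels(labels, regions, spec, phase)
}

geometry_from_labels <- function(labels, regions, spec, phase) {
  t1v <- m0v <- phv <- c(0, numeric(nrow(regions)))
  for (i in seq_len(nrow(regions))) {
    tis <- spec$compartments[[regions$tissue[i]]]
    t1v[i + 1] <- tis$t1; m0v[i + 1] <- tis$m0; phv[i + 1] <- tis$phase0
  }
  idx <- labels + 1L
  shape <- dim(labels)
  structure(list(labels = labels,
                 truth_t1 = matrix(t1v[idx], shape[1], shape[2]),
                 truth_m0 = matrix(m0v[idx], shape[1], shape[2]),
                 truth_phase0 = matrix(phv[idx], shape[1], shape[2]),
                 regions = regions, spec = spec, phase = phase),
            class = "phantom_geometry")
}

#' Build a multi-vial phantom
#'
#' Disjoint circular vials on a ring (plus one in the center when the
#' count allows), each assigned its own T1; static across frames. The
#' default T1 list is log-spaced over 200-2000 ms to span the physiological
#' and post-contrast range.
#'
#' @param t1_list Vial T1s in ms (default 7 vials log-spaced 200-2000).
#' @param grid Pixels per side (default 256).
#' @param vial_radius Vial radius in pixels (default `grid/10`).
#' @param m0 Equilibrium signal shared by the vials.
#' @param pixel_mm Pixel spacing, mm.
#' @return A `phantom_geometry`; labels 1..n_vials, region names
#'   `vial_1` ... `vial_n`.
#' @export
build_vial_phantom <- function(t1_list = exp(seq(log(200), log(2000),
                                                 length.out = 7)),
                               grid = 256, vial_radius = grid / 10,
                               m0 = 1, pixel_mm = 1.2) {
  n <- length(t1_list)
  stopifnot(n >= 1)
  cx <- cy <- (grid + 1) / 2
  if (n == 1) {
    centers <- cbind(cx, cy)
  } else {
    ring_r <- grid / 2 - vial_radius - 2
    k <- n - 1
    th <- 2 * pi * (0:(k - 1)) / k
    centers <- rbind(c(cx, cy), cbind(cx + ring_r * cos(th),
                                      cy + ring_r * sin(th)))
    # vials on the ring must not touch each other or the center vial
    min_gap <- min(2 * ring_r * sin(pi / k), ring_r)
    if (min_gap <= 2 * vial_radius)
      stop("spec error: overlapping vials; reduce vial_radius or count")
  }
  x <- matrix(rep(seq_len(grid), each = grid), nrow = grid)
  y <- matrix(rep(seq_len(grid), times = grid), nrow = grid)
  labels <- matrix(0L, grid, grid)
  for (i in seq_len(n)) {
    labels[(x - centers[i, 1])^2 + (y - centers[i, 2])^2 <
             vial_radius^2] <- i
  }
  regions <- data.frame(label = seq_len(n),
                        name = paste0("vial_", seq_len(n)),
                        tissue = paste0("vial_", seq_len(n)),
                        stringsAsFactors = FALSE)
  comp <- stats::setNames(lapply(t1_list, function(t) tissue_params(t, m0)),
                          regions$tissue)
  spec <- structure(list(grid = as.integer(grid), pixel_mm = pixel_mm,
                         vial_radius = vial_radius, compartments = comp),
                    class = "phantom_spec")
  geometry_from_labels(labels, regions, spec, phase = "diastole")
}

#' Synthesize a complex base-image series from phantom truths
#'
#' Evaluates the signal model per frame and per compartment (all pixels of
#' a compartment share one noiseless value), assembles complex images
#' `Mz * exp(i (phase0 + phase_map))` — so the sign of the longitudinal
#' magnetization is carried on the real axis and inverted frames acquire a
#' pi phase shift — and adds i.i.d. complex Gaussian noise with per-channel
#' standard deviation `reference_signal / snr`. The reference signal is the
#' unprepared magnitude of `ref_compartment` (the fully recovered image the
#' phase-sensitive fit references); for vial phantoms it defaults to the
#' mean vial M0.
#'
#' Frames labeled `systole` in a diastolic series draw their pixel values
#' from the systolic geometry: that is how mis-triggered base-images enter
#' the stack.
#'
#' @param geometry A `phantom_geometry`, or a named list
#'   `list(diastole = ..., systole = ...)` when the timing table mixes
#'   phases.
#' @param timings A [frame_timing()] table.
#' @param snr Signal-to-noise ratio (> 0), or `Inf` for noiseless.
#' @param phase_map Optional matrix of extra per-pixel phase (radians),
#'   e.g. a smooth coil/off-resonance phase; default 0.
#' @param inv_eff True inversion completeness used in synthesis.
#' @param seed Integer seed; fixed seed gives a bit-identical series.
#' @return A `phantom_series` list: `frames` (complex array x*y*n),
#'   `timings`, `truth_t1`, `truth_m0`, `labels`, `regions`, `snr`, `seed`,
#'   `noise_sd`.
#' @export
synthesize_series <- function(geometry, timings, snr = Inf, phase_map = NULL,
                              inv_eff = 1, seed = 1,
                              ref_compartment = "myocardium") {
  timings <- as_frame_timing(timings)
  geoms <- if (inherits(geometry, "phantom_geometry"))
    list(diastole = geometry, systole = geometry) else geometry
  phases <- unique(timings$phase)
  for (p in phases)
    if (is.null(geoms[[p]]))
      stop(sprintf("missing %s geometry for frames labeled %s", p, p))
  base <- geoms[[timings$phase[1]]]
  g1 <- dim(base$labels)[1]; g2 <- dim(base$labels)[2]
  n <- nrow(timings)
  comp <- base$spec$compartments
  ref <- if (ref_compartment %in% names(comp)) comp[[ref_compartment]]$m0
         else mean(vapply(comp, function(t) t$m0, numeric(1)))
  noise_sd <- if (is.finite(snr)) ref / snr else 0
  if (is.null(phase_map)) phase_map <- matrix(0, g1, g2)
  frames <- array(complex(real = 0), dim = c(g1, g2, n))
  set.seed(as.integer(seed))
  for (i in seq_len(n)) {
    geo <- geoms[[timings$phase[i]]]
    tissues <- names(geo$spec$compartments)
    sig <- vapply(geo$spec$compartments, function(t)
      model_signal(timings$prep[i], timings$ts_ms[i], timings$ti_ms[i],
                   t1 = t$t1, m0 = t$m0, inv_eff = inv_eff), numeric(1))
    lut <- c(0, sig[geo$regions$tissue])       # label 0 = background
    mz <- matrix(lut[geo$labels + 1L], g1, g2)
    ph0 <- geo$truth_phase0
    img <- mz * exp(1i * (ph0 + phase_map))
    if (noise_sd > 0)
      img <- img + complex(real = stats::rnorm(g1 * g2, 0, noise_sd),
                           imaginary = stats::rnorm(g1 * g2, 0, noise_sd))
    frames[, , i] <- img
  }
  structure(list(frames = frames, timings = timings,
                 truth_t1 = base$truth_t1, truth_m0 = base$truth_m0,
                 labels = base$labels, regions = base$regions,
                 snr = snr, seed = as.integer(seed), noise_sd = noise_sd),
            class = "phantom_series")
}

#' Run a multi-condition, multi-repetition phantom experiment
#'
#' Loops arrhythmia conditions and repetitions, generating one seeded
#' series per (condition, repetition). Condition `c`, repetition `r` uses
#' seed `base_seed + 1009 * c + r`, so every series is independently
#' reproducible. Two experiment designs are supported:
#' \describe{
#'   \item{`"diastolic_mistrigger"`}{cardiac phantom, diastolic schedule,
#'     mis-trigger relabeling driven by the RR draw — the degradation
#'     study.}
#'   \item{`"systolic"`}{systolic schedule with realized per-frame timing
#'     (vial phantom by default) — the arrhythmia-insensitivity study.}
#' }
#'
#' @param config A list (see [default_run_config()]) with elements
#'   `phantom`, `schedule`, `rr`, `snr`, `repetitions`, `base_seed`.
#' @return A list with `series` (list of `phantom_series`) and `manifest`
#'   (data frame: condition, sd_rr, repetition, seed, n_frames,
#'   n_systolic_frames).
#' @export
simulate_experiment <- function(config) {
  cfg <- config
  sds <- cfg$rr$sd_list
  if (is.null(sds))
    sds <- arrhythmia_factor_to_sd(cfg$rr$factors, cfg$rr$mean_rr)
  reps <- cfg$repetitions
  variant <- cfg$schedule$variant
  geom <- if (cfg$phantom$type == "vial") {
    build_vial_phantom(t1_list = cfg$phantom$t1_list,
                       grid = cfg$phantom$grid)
  } else {
    sp <- phantom_spec(grid = cfg$phantom$grid)
    list(diastole = build_cardiac_phantom(sp, "diastole"),
         systole = build_cardiac_phantom(sp, "systole"))
  }
  series <- list()
  man <- list()
  k <- 0
  for (ci in seq_along(sds)) {
    for (r in seq_len(reps)) {
      k <- k + 1
      seed <- as.integer(cfg$base_seed + 1009 * ci + r)
      n_beats <- (if (variant == "systolic") cfg$schedule$n_frames
                  else length(cfg$schedule$ti_list)) + 1L
      rr <- generate_rr_series(cfg$rr$mean_rr, sds[ci], n_beats, seed,
                               floor_ms = cfg$rr$floor_ms)
      if (variant == "systolic") {
        tim <- schedule_systolic(rr, td_sys = cfg$schedule$td,
                                 n_sat = cfg$schedule$n_sat,
                                 n_inv = cfg$schedule$n_inv,
                                 ti_spread = cfg$schedule$ti_spread)
      } else {
        tim <- schedule_diastolic(rr, td = cfg$schedule$td,
                                  ti_list = cfg$schedule$ti_list)
        tim <- apply_mistrigger(tim, rr, td = cfg$schedule$td,
                                mode = cfg$schedule$mistrigger_mode,
                                seed = seed)
      }
      rc <- cfg$phantom$ref_compartment
      if (is.null(rc)) rc <- "myocardium"
      s <- synthesize_series(geom, tim, snr = cfg$snr, seed = seed,
                             ref_compartment = rc)
      series[[k]] <- s
      man[[k]] <- data.frame(condition = ci, sd_rr = sds[ci],
                             repetition = r, seed = seed,
                             n_frames = nrow(tim),
                             n_systolic_frames = sum(tim$phase == "systole"))
    }
  }
  list(series = series, manifest = do.call(rbind, man))
}
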