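#' Accuracy and precision maps across repetitions
#'
#' Per-pixel mean (accuracy, against known truth) and sample standard
#' deviation with n-1 denominator (precision) over a stack of repeated T1
#' maps of identical shape.
#'
#' @param t1_maps List of >= 2 numeric matrices of identical dimensions.
#' @return List with `mean_map` and `sd_map`.
#' @export
accuracy_precision_maps <- function(t1_maps) {
  if (length(t1_maps) < 2) stop("need at least 2 repetitions")
  dims <- lapply(t1_maps, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("shape mismatch across repetitions")
  stack <- simplify2array(t1_maps)
  mean_map <- apply(stack, c(1, 2), mean)
  sd_map <- apply(stack, c(1, 2), stats::sd)
  list(mean_map = mean_map, sd_map = sd_map)
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean; scale-invariant measure
#' of spread used to quantify arrhythmia (in)dependence of fitted T1.
#'
#' @param values Numeric vector; mean must be non-zero.
#' @return CoV as a fraction (multiply by 100 for percent).
#' @export
cov_fraction <- function(values) {
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  stats::sd(values) / m
}

#' Full width at half maximum of a septal line profile
#'
#' Samples a T1 map along a line from one blood pool through the septum to
#' the other (bilinear interpolation), estimates the blood plateau as the
#' average of the per-side medians of the outer 20% of the profile, takes
#' the septal extremum (minimum, since myocardial T1 < blood T1), sets the
#' half level midway between plateau and extremum, and measures the
#' distance between the two half-level crossings with sub-sample linear
#' interpolation.
#'
#' @param t1_map Numeric matrix (row = y, col = x).
#' @param line Numeric `c(x0, y0, x1, y1)` endpoints in pixel coordinates.
#' @param pixel_mm Pixel spacing, mm.
#' @param n_samples Samples along the line (default 4 per pixel length).
#' @return FWHM in mm.
#' @export
fwhm_profile <- function(t1_map, line, pixel_mm = 1,
                         n_samples = NULL) {
  stopifnot(length(line) == 4)
  len_px <- sqrt((line[3] - line[1])^2 + (line[4] - line[2])^2)
  if (is.null(n_samples)) n_samples <- max(64L, ceiling(4 * len_px))
  tt <- seq(0, 1, length.out = n_samples)
  xs <- line[1] + tt * (line[3] - line[1])
  ys <- line[2] + tt * (line[4] - line[2])
  prof <- pracma::interp2(x = seq_len(ncol(t1_map)),
                          y = seq_len(nrow(t1_map)),
                          Z = t1_map, xp = xs, yp = ys, method = "linear")
  fwhm_of_profile(prof, step_mm = len_px * pixel_mm / (n_samples - 1))
}

# Core FWHM on a sampled profile; exported for direct use on 1D profiles.
#' @rdname fwhm_profile
#' @param profile Numeric vector (a pre-sampled line profile).
#' @param step_mm Distance between successive profile samples, mm.
#' @export
fwhm_of_profile <- function(profile, step_mm = 1) {
  n <- length(profile)
  k <- max(2L, ceiling(0.2 * n))
  plateau <- (stats::median(profile[seq_len(k)]) +
                stats::median(profile[(n - k + 1):n])) / 2
  i_min <- which.min(profile)
  depth <- profile[i_min]
  if (depth >= plateau) stop("undefined-profile error: no septal dip found")
  half <- (plateau + depth) / 2
  cross_left <- NA_real_
  for (i in seq(i_min, 2)) {
    if (profile[i - 1] > half && profile[i] <= half) {
      frac <- (profile[i - 1] - half) / (profile[i - 1] - profile[i])
      cross_left <- (i - 1) + frac
      break
    }
  }
  cross_right <- NA_real_
  for (i in seq(i_min, n - 1)) {
    if (profile[i + 1] > half && profile[i] <= half) {
      frac <- (profile[i + 1] - half) / (profile[i + 1] - profile[i])
      cross_right <- (i + 1) - frac
      break
    }
  }
  if (is.na(cross_left) || is.na(cross_right))
    stop("undefined-profile error: half-level crossings not found")
  (cross_right - cross_left) * step_mm
}

#' Extracellular volume fraction
#'
#' Standard delta-R1 ratio definition from native and post-contrast T1 of
#' myocardium and blood, scaled by the blood plasma fraction:
#' `ECV = (1 - hct) * (1/post_myo - 1/native_myo) /
#' (1/post_blood - 1/native_blood)`.
#'
#' @param native_t1_myo,post_t1_myo Myocardial T1 before/after contrast, ms.
#' @param native_t1_blood,post_t1_blood Blood T1 before/after contrast, ms.
#' @param hct Hematocrit, fraction in (0, 1).
#' @return ECV as a fraction.
#' @examples
#' ecv_fraction(1563, 600, 2000, 350, hct = 0.42)
#' @export
ecv_fraction <- function(native_t1_myo, post_t1_myo,
                         native_t1_blood, post_t1_blood, hct) {
  stopifnot(all(c(native_t1_myo, post_t1_myo,
                  native_t1_blood, post_t1_blood) > 0),
            hct > 0, hct < 1)
  dr1_blood <- 1 / post_t1_blood - 1 / native_t1_blood
  if (dr1_blood <= 0)
    stop("non-positive blood delta-R1: post-contrast blood T1 must be shorter")
  dr1_myo <- 1 / post_t1_myo - 1 / native_t1_myo
  (1 - hct) * dr1_myo / dr1_blood
}

#' Angular sector segmentation of a myocardial annulus
#'
#' Divides an annular mask into `n_sectors` equal angular sectors starting
#' at the anterior RV insertion angle and proceeding counterclockwise —
#' the single-slice analogue of the standardized segment model (6 sectors
#' for basal/mid slices, 4 for apical).
#'
#' @param mask Logical matrix marking myocardial pixels.
#' @param lv_center `c(x, y)` pixel coordinates of the LV center.
#' @param rv_insertion_angle Angle of the anterior RV insertion, radians,
#'   measured counterclockwise from the +x axis (y up).
#' @param n_sectors 6 or 4.
#' @return Integer matrix: 0 outside the mask, sector index 1..n inside.
#' @export
segment_sectors <- function(mask, lv_center, rv_insertion_angle = pi / 2,
                            n_sectors = 6) {
  if (!any(mask)) stop("empty myocardial mask")
  stopifnot(n_sectors %in% c(4, 6))
  g1 <- nrow(mask); g2 <- ncol(mask)
  x <- matrix(rep(seq_len(g2), each = g1), nrow = g1)
  y <- matrix(rep(seq_len(g1), times = g2), nrow = g1)
  ang <- atan2(-(y - lv_center[2]), x - lv_center[1])
  rel <- (ang - rv_insertion_angle) %% (2 * pi)
  sec <- matrix(0L, g1, g2)
  sec[mask] <- as.integer(floor(rel[mask] / (2 * pi / n_sectors))) + 1L
  sec
}

#' Per-region summary statistics of a T1 map
#'
#' Mean T1, intra-region standard deviation (the precision measure), and
#' coefficient of variation per labeled region.
#'
#' @param t1_map Numeric matrix.
#' @param labels Integer matrix of region labels (0 = background).
#' @param region_names Optional character vector naming labels 1..n.
#' @return Data frame: `region_id`, `region`, `n_pixels`, `mean_t1`,
#'   `precision`, `cov`.
#' @export
region_report <- function(t1_map, labels, region_names = NULL) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  if (length(ids) == 0) stop("no labeled regions")
  rows <- lapply(ids, function(id) {
    v <- t1_map[labels == id]
    v <- v[is.finite(v)]
    m <- mean(v)
    data.frame(region_id = id,
               region = if (!is.null(region_names)) region_names[id]
                        else paste0("region_", id),
               n_pixels = length(v), mean_t1 = m,
               precision = stats::sd(v),
               cov = if (m > 0) stats::sd(v) / m else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
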