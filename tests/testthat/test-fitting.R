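test_that("three-parameter fit recovers noiseless ground truth", {
  tim <- diastolic_timings()
  for (t1 in c(382, 1578, 2048)) {
    s <- signal_series(tissue_params(t1), tim)
    f <- fit_three_param(s, tim)
    expect_lt(abs(f$t1 - t1) / t1, 0.001)
    expect_equal(f$m0, 1, tolerance = 1e-3)
    expect_equal(f$inv_eff, 1, tolerance = 1e-3)
    expect_true(f$converged)
  }
  # imperfect inversion is identified too
  s <- signal_series(tissue_params(1578), tim, inv_eff = 0.9)
  f <- fit_three_param(s, tim)
  expect_lt(abs(f$t1 - 1578) / 1578, 0.001)
  expect_equal(f$inv_eff, 0.9, tolerance = 1e-3)
  expect_error(fit_three_param(s[1:3], tim[1:3, ]), "at least 4")
})

test_that("systolic fits with realized timing are invariant to RR
           variability", {
  # same vial, four very different RR streams: identical fitted T1
  fits <- vapply(c(0, 200, 400, 500), function(sd_rr) {
    rr <- generate_rr_series(1125, sd_rr, 11, seed = 21)
    tim <- schedule_systolic(rr, td_sys = 300)
    s <- signal_series(tissue_params(900), tim)
    fit_three_param(s, tim)$t1
  }, numeric(1))
  expect_lt(max(abs(fits - 900)) / 900, 0.001)
})

test_that("magnitude polarity restoration finds the true sign pattern", {
  tim <- diastolic_timings()
  # all-positive signals: no flips (T1 short enough that even the first
  # inversion point has recovered past zero)
  s_pos <- signal_series(tissue_params(150), tim)
  expect_true(all(s_pos > 0))
  r <- restore_polarity_magnitude(abs(s_pos), tim)
  expect_equal(r$n_flipped, 0)
  # long T1: early-TI points truly negative; exhaustive k recovers them
  s <- signal_series(myo_tissue(), tim)
  n_neg <- sum(s < 0)
  expect_gt(n_neg, 0)
  r2 <- restore_polarity_magnitude(abs(s), tim)
  expect_equal(r2$n_flipped, n_neg)
  expect_lt(abs(r2$fit$t1 - 1578) / 1578, 0.001)
  expect_equal(r2$signed, s, tolerance = 1e-9)
})

test_that("phase polarity equals the true Mz sign on noiseless data", {
  pm <- outer(seq(0, 0.4, length.out = 96), seq(0, 0.7, length.out = 96),
              "+")
  ser <- small_cardiac_series(grid = 96, snr = Inf, phase_map = pm)
  pol <- polarity_from_phase(ser$frames, 1)
  tim <- ser$timings
  for (lab in 1:4) {
    tis <- ser$regions$tissue[lab]
    truth <- signal_series(
      tissue_params(c(myocardium = 1578, blood = 2048, fat = 382)[tis]),
      tim)
    sel <- ser$labels == lab
    for (i in seq_len(nrow(tim))) {
      expected <- if (truth[i] < 0) -1L else 1L
      expect_true(all(pol[, , i][sel] == expected),
                  label = sprintf("label %d frame %d", lab, i))
    }
  }
  # trivial cases: zero / pi phase difference
  fr <- array(complex(real = 1), dim = c(4, 4, 2))
  expect_true(all(polarity_from_phase(fr, 1) == 1))
  fr[, , 2] <- -1 + 0i
  expect_true(all(polarity_from_phase(fr, 1)[, , 2] == -1))
  expect_error(polarity_from_phase(array(1, dim = c(2, 2, 2)), 1),
               "complex")
})

test_that("2D phase unwrapping changes values by multiples of 2*pi", {
  set.seed(3)
  smooth <- outer(seq(0, 6, length.out = 40), seq(0, 5, length.out = 40),
                  "+")
  wrapped <- Arg(exp(1i * smooth))
  un <- unwrap_phase_2d(wrapped)
  k <- (un - wrapped) / (2 * pi)
  expect_equal(k, round(k), tolerance = 1e-9)
  # a smooth surface is recovered up to one global branch
  expect_equal(max(abs(un - smooth - (un - smooth)[1, 1])), 0,
               tolerance = 1e-9)
  expect_equal(unwrap_vector(c(0.1, 3.0, -3.0)), c(0.1, 3.0, 2 * pi - 3.0))
})

test_that("noiseless T1 maps reproduce compartment truth to 0.1%", {
  ser <- small_cardiac_series(grid = 96, snr = Inf)
  fit <- fit_t1_map(ser, method = "phase_sensitive")
  rep <- region_report(fit$t1, ser$labels, ser$regions$name)
  truth <- c(myocardium = 1578, lv_blood = 2048, rv_blood = 2048, fat = 382)
  expect_lt(max(abs(rep$mean_t1 - truth[rep$region]) / truth[rep$region]),
            0.001)
  # magnitude and phase-sensitive agree exactly without noise
  fit_m <- fit_t1_map(ser, method = "magnitude")
  expect_equal(fit_m$t1[fit$mask], fit$t1[fit$mask], tolerance = 1e-6)
})

test_that("map fitting is invariant to frame order given correct timing", {
  ser <- small_cardiac_series(grid = 48, snr = Inf)
  perm <- c(4, 1, 9, 2, 10, 3, 7, 5, 8, 6)
  shuf <- ser
  shuf$frames <- ser$frames[, , perm]
  shuf$timings <- ser$timings[perm, ]
  f1 <- fit_t1_map(ser, method = "phase_sensitive")
  f2 <- fit_t1_map(shuf, method = "phase_sensitive")
  expect_equal(f2$t1, f1$t1, tolerance = 1e-9)
})

test_that("ROI-level fits match pixel-level results on noiseless vials", {
  geo <- build_vial_phantom(grid = 128)
  rr <- generate_rr_series(1125, 400, 11, seed = 13)
  tim <- schedule_systolic(rr, td_sys = 300)
  ser <- synthesize_series(geo, tim, snr = Inf, seed = 1,
                           ref_compartment = "mean")
  roi <- fit_t1_regions(ser, method = "phase_sensitive")
  truths <- vapply(geo$spec$compartments, function(t) t$t1, numeric(1))
  expect_equal(roi$t1, unname(truths[roi$region]), tolerance = 1e-3)
})

test_that("ROI mean T1 bias under noise stays below 1% on the diastolic
           schedule", {
  tim <- diastolic_timings()
  truth <- signal_series(myo_tissue(), tim)
  set.seed(77)
  n_px <- 400
  t1s <- replicate(20, {
    # ROI-mean over complex pixels: noise shrinks by sqrt(n_px)
    noisy <- truth + stats::rnorm(10, 0, 1 / 60 / sqrt(n_px))
    fit_three_param(noisy, tim)$t1
  })
  expect_lt(abs(mean(t1s) - 1578) / 1578, 0.01)
})
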