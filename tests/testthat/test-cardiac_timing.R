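test_that("RR series honors mean, spread, floor and seed", {
  # zero-variance: constant series
  rr0 <- generate_rr_series(667, 0, 10, seed = 99)
  expect_equal(rr0$values, rep(667, 10))
  # seed determinism
  a <- generate_rr_series(1125, 500, 15, seed = 1)
  b <- generate_rr_series(1125, 500, 15, seed = 1)
  expect_identical(a$values, b$values)
  # Monte-Carlo: sample mean of the pre-truncation Gaussian within 3 SE
  set.seed(42)
  raw <- stats::rnorm(10000, 667, 466.9)
  rr <- generate_rr_series(667, 466.9, 10000, seed = 42)
  expect_equal(rr$values, pmax(raw, 300))
  expect_lt(abs(mean(raw) - 667), 3 * 466.9 / sqrt(10000))
  # floor is respected
  expect_true(all(rr$values >= 300))
})

test_that("arrhythmia factor converts to RR standard deviation", {
  expect_equal(arrhythmia_factor_to_sd(0.30, 667), 200.1)
  expect_equal(arrhythmia_factor_to_sd(0, 667), 0)
  expect_equal(arrhythmia_factor_to_sd(0.70, 667), 466.9)
})

test_that("diastolic schedule pins TS to the trigger delay", {
  tim <- diastolic_timings()
  expect_equal(nrow(tim), 10)
  expect_equal(tim$prep[1], "none")
  prepped <- tim$prep != "none"
  expect_true(all(tim$ts_ms[prepped] == 805))
  # TI = TD frame degenerates to saturation-only
  expect_equal(sum(tim$prep == "sat"), 1)
  expect_equal(tim$ti_ms[tim$prep == "sat_inv"],
               c(113, 211, 309, 407, 505, 603, 701, 799))
  # single unprepared frame schedule
  one <- schedule_diastolic(generate_rr_series(667, 0, 2, 1),
                            ti_list = 10000)
  expect_equal(one$prep, "none")
  expect_error(schedule_diastolic(generate_rr_series(667, 0, 11, 1),
                                  td = 805, ti_list = c(10000, 900)),
               "schedule error")
})

test_that("systolic schedule records realized timing from the RR stream", {
  # constant RR: TS equals the RR interval for every prepared frame
  rr <- generate_rr_series(1000, 0, 11, seed = 1)
  tim <- schedule_systolic(rr, td_sys = 300)
  expect_equal(tim$ts_ms[tim$prep != "none"], rep(1000, 9))
  # linearly spread TIs
  tim2 <- schedule_systolic(generate_rr_series(1000, 0, 11, 1),
                            td_sys = 500, ti_spread = c(100, 500))
  expect_equal(tim2$ti_ms[tim2$prep == "sat_inv"],
               c(100, 200, 300, 400, 500))
  # healthy-volunteer (1+4+5) and patient (1+7+7) layouts
  expect_equal(table(tim$prep)[c("none", "sat", "sat_inv")],
               table(factor(c("none", rep("sat", 4), rep("sat_inv", 5))))[
                 c("none", "sat", "sat_inv")])
  pat <- schedule_systolic(generate_rr_series(800, 0, 16, 1), td_sys = 300,
                           n_sat = 7, n_inv = 7)
  expect_equal(nrow(pat), 15)
  # variable RR: each frame stores its own realized TS
  rrv <- generate_rr_series(1125, 400, 11, seed = 3)
  timv <- schedule_systolic(rrv, td_sys = 300)
  expect_equal(timv$ts_ms[-1], rrv$values[2:10])
  expect_error(schedule_systolic(rr, td_sys = 300, ti_spread = c(100, 400)),
               "schedule error")
})

test_that("frames with realized TS below TI are dropped with a warning", {
  rr <- generate_rr_series(1000, 0, 11, seed = 1)
  rr$values[8] <- 150  # shorter than the largest TI
  expect_warning(tim <- schedule_systolic(rr, td_sys = 300,
                                          ti_spread = c(100, 300)),
                 "dropping")
  expect_lt(nrow(tim), 10)
})

test_that("mis-trigger relabeling matches mechanism and statistics", {
  rr <- generate_rr_series(667, 0, 11, seed = 1)
  tim <- schedule_diastolic(rr)
  # no variability, TD below mean RR: nothing relabeled
  expect_true(all(apply_mistrigger(tim, rr, td = 600)$phase == "diastole"))
  # threshold rule flags exactly the short beats
  rr2 <- generate_rr_series(667, 466.9, 11, seed = 7)
  tim2 <- apply_mistrigger(schedule_diastolic(rr2), rr2, td = 805)
  expect_equal(tim2$phase == "systole", rr2$values[1:10] < 805)
  # random mode is seed-reproducible
  r1 <- apply_mistrigger(tim, rr, td = 805, mode = "random", seed = 5)
  r2 <- apply_mistrigger(tim, rr, td = 805, mode = "random", seed = 5)
  expect_identical(r1$phase, r2$phase)
})

test_that("mis-trigger fraction converges to the truncated-Gaussian
           exceedance probability", {
  p_pred <- mistrigger_probability(667, 466.9, 805)
  expect_equal(p_pred, stats::pnorm((805 - 667) / 466.9))
  rr <- generate_rr_series(667, 466.9, 20000, seed = 11)
  p_emp <- mean(rr$values < 805)
  se <- sqrt(p_pred * (1 - p_pred) / 20000)
  expect_lt(abs(p_emp - p_pred), 4 * se)
})

test_that("timing sidecars round-trip through CSV and JSON", {
  tim <- diastolic_timings()
  for (ext in c("csv", "json")) {
    path <- file.path(tempdir(), paste0("timing.", ext))
    write_timing_sidecar(tim, path)
    back <- read_timing_sidecar(path)
    expect_equal(as.data.frame(back), as.data.frame(tim))
  }
})
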