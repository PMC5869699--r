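# Shared fixtures: reference tissues, schedules and small phantoms built in
# code at test time.

myo_tissue <- function() tissue_params(1578)
blood_tissue <- function() tissue_params(2048)
fat_tissue <- function() tissue_params(382)

diastolic_timings <- function(mean_rr = 667, sd_rr = 0, seed = 1) {
  schedule_diastolic(generate_rr_series(mean_rr, sd_rr, 11, seed))
}

small_cardiac_series <- function(grid = 96, snr = Inf, seed = 2,
                                 phase_map = NULL) {
  sp <- phantom_spec(grid = grid)
  geo <- build_cardiac_phantom(sp, "diastole")
  synthesize_series(geo, diastolic_timings(), snr = snr, seed = seed,
                    phase_map = phase_map)
}

# Event list realizing the hybrid preparation for the piecewise oracle.
sapphire_events <- function(ts, ti, inv_eff = 1) {
  list(prep_event("saturation", 0),
       prep_event("inversion", ts - ti, efficiency = inv_eff),
       prep_event("readout", ts))
}
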