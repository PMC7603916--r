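# Shared fixtures: schedules, input functions and small studies built in
# code at test time.

fix_grid <- function(total, dt = 0.25) seq(0, total, by = dt)

# Smooth non-negative blood curves on [0, total]
fix_inputs <- function(total = 240, bolus = bolus_model()) {
  make_input_function(bolus, fix_grid(total))
}

fix_water_schedule <- function() framing_scheme("clinical-water")$schedule

fix_rb_schedule <- function() framing_scheme("lortie-rubidium")$schedule

# Ground-truth water study (uniform parameters across segments)
fix_water_study <- function(mbf = 2.5, ptf = 0.7, v_lv = 0.25, v_rv = 0.1,
                            noise = 0, seed = 1) {
  simulate_study("water", fix_water_schedule(),
                 water_params(mbf, ptf, v_lv, v_rv),
                 noise_level = noise, seed = seed)
}

# Per-frame noise standard deviation the generator targets (for checks)
fix_noise_sd <- function(study) {
  surv <- 2^(-(study$schedule$start_s + study$schedule$duration_s / 2) /
               study$tracer$half_life_s)
  dur <- study$schedule$duration_s
  peak <- max(vapply(study$noise_free, max, numeric(1)))
  rate_peak <- max(peak / (dur * surv))
  function(clean_values)
    study$noise_level * peak *
      sqrt(pmax(clean_values, 0) / (dur * surv) / rate_peak)
}
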