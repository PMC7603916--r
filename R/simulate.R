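# Synthetic dynamic rest/stress study generator with known ground truth.
#
# The generator emulates a fast automated bolus injection (gamma-variate
# first pass plus an exponentially dispersed recirculation tail), forms
# frame-averaged noise-free model curves for 17 myocardial segments, and
# adds zero-mean Gaussian noise whose variance follows counting statistics
# on the decay-corrected values: var ~ value / (frame_duration * decay
# survival). All randomness is driven by an explicit seed.

#' Bolus model for the arterial input function
#'
#' A gamma-variate first-pass bolus
#' `A * (u / (shape*scale))^shape * exp(shape - u/scale)` with `u = t -
#' delay` (peak value `A` at `u = shape*scale`), plus a recirculation
#' component obtained by convolving the first pass with an exponential
#' dispersion kernel of time constant `recirc_tau_s`, scaled by
#' `recirc_fraction`.
#'
#' @param delay_s bolus arrival delay in seconds.
#' @param amplitude peak first-pass concentration, kBq/mL.
#' @param shape,scale gamma-variate shape (unitless) and scale (seconds).
#' @param recirc_fraction fraction of the first-pass amplitude recirculating.
#' @param recirc_tau_s recirculation dispersion time constant, seconds.
#' @return object of class `bolus_model`.
#' @export
bolus_model <- function(delay_s = 8, amplitude = 60, shape = 3, scale = 4.5,
                        recirc_fraction = 0.15, recirc_tau_s = 40) {
  assert_scalar_num(delay_s, "delay_s", 0)
  assert_scalar_num(amplitude, "amplitude", 0)
  assert_scalar_num(shape, "shape", 0, strict_lower = TRUE)
  assert_scalar_num(scale, "scale", 0, strict_lower = TRUE)
  assert_scalar_num(recirc_fraction, "recirc_fraction", 0, 1)
  assert_scalar_num(recirc_tau_s, "recirc_tau_s", 0, strict_lower = TRUE)
  structure(list(delay_s = delay_s, amplitude = amplitude, shape = shape,
                 scale = scale, recirc_fraction = recirc_fraction,
                 recirc_tau_s = recirc_tau_s),
            class = "bolus_model")
}

# First-pass gamma-variate evaluated at times t (seconds)
gamma_variate <- function(bolus, t, delay_shift_s = 0) {
  u <- t - (bolus$delay_s + delay_shift_s)
  out <- numeric(length(t))
  pos <- u > 0
  up <- u[pos] / (bolus$shape * bolus$scale)
  out[pos] <- bolus$amplitude * up^bolus$shape *
    exp(bolus$shape * (1 - up))
  out
}

#' Generate arterial and right-ventricular input curves
#'
#' Evaluates the bolus model on a time grid and returns the left-ventricular
#' arterial curve C_A and the right-ventricular curve C_RV. The RV curve is
#' a time-advanced (blood reaches the right heart first) and
#' amplitude-scaled variant of C_A.
#'
#' @param bolus a [bolus_model()].
#' @param eval_grid time grid in seconds (fine, e.g. 0.25 s steps).
#' @param transit_delay_s RV-to-LV transit delay in seconds (C_RV precedes
#'   C_A by this much).
#' @param rv_scale amplitude scale of C_RV relative to C_A.
#' @return list with [plin_curve()] elements `C_A` and `C_RV`.
#' @export
make_input_function <- function(bolus, eval_grid,
                                transit_delay_s = 4, rv_scale = 1.15) {
  stopifnot(inherits(bolus, "bolus_model"))
  assert_scalar_num(transit_delay_s, "transit_delay_s", 0)
  assert_scalar_num(rv_scale, "rv_scale", 0)
  build <- function(shift, amp_scale) {
    fp <- amp_scale * gamma_variate(bolus, eval_grid, delay_shift_s = shift)
    y <- fp
    if (bolus$recirc_fraction > 0 && any(fp > 0)) {
      fp_curve <- plin_curve(eval_grid, fp)
      recirc <- bolus$recirc_fraction / bolus$recirc_tau_s *
        conv_exp_plin(fp_curve, 1 / bolus$recirc_tau_s, eval_grid)
      y <- fp + recirc
    }
    plin_curve(eval_grid, y)
  }
  list(C_A = build(0, 1),
       C_RV = build(-min(transit_delay_s, bolus$delay_s), rv_scale))
}

# Frame averages of a piecewise-linear curve by exact integration over each
# frame (running integral differences).
frame_average_plin <- function(curve, schedule) {
  Ia <- cumint_plin(curve, schedule$start_s)
  Ib <- cumint_plin(curve, frame_end(schedule))
  (Ib - Ia) / schedule$duration_s
}

# Forward-model dispatch on a kinetic_params object (frame-averaged)
forward_model_frames <- function(params, C_A, C_RV, schedule, ...) {
  if (inherits(params, "water_params"))
    pet_signal_water(params, C_A, C_RV, schedule = schedule, ...)
  else if (inherits(params, "two_tissue_irr_params"))
    pet_signal_2tc_irr(params, C_A, C_RV, schedule = schedule, ...)
  else if (inherits(params, "one_tissue_params"))
    pet_signal_1tc(params, C_A, C_RV, schedule = schedule, ...)
  else stop_invalid("unsupported parameter bundle of class %s",
                    paste(class(params), collapse = "/"))
}

#' Simulate a synthetic dynamic perfusion study
#'
#' Produces frame-averaged myocardial time-activity curves for each of the
#' 17 AHA segments from known ground-truth kinetic parameters, together
#' with the blood curves, and adds frame noise. Noise is zero-mean Gaussian
#' with variance proportional to `value / (frame_duration * decay
#' survival)`, calibrated so that the coefficient of variation at the peak
#' myocardial frame equals `noise_level`. Curves are returned
#' decay-corrected; the decay survival factor enters only the noise model,
#' as it does for reconstructed decay-corrected PET frames.
#'
#' @param tracer a [tracer_spec()] or tracer name.
#' @param schedule a [frame_schedule()] (or a scheme name from
#'   [framing_scheme()]).
#' @param true_params a single `kinetic_params` object (replicated over all
#'   17 segments) or a list of 17 of them.
#' @param noise_level CoV at the peak myocardial frame (0 = noise-free;
#'   typical reconstructed studies are about 0.05).
#' @param seed integer seed; identical seeds give bit-identical studies.
#' @param bolus a [bolus_model()].
#' @param grid_dt_s fine simulation grid step in seconds.
#' @param blood_noise add noise to the measured blood curves too (default
#'   TRUE; the noise-free fine input curves are always kept as ground
#'   truth).
#' @return object of class `synthetic_study`: tracer, schedule, ground
#'   truth (`truth`, list of 17 parameter bundles), `curves` (list of 17
#'   [tac()]s), measured blood TACs `C_A`/`C_RV`, noise-free fine input
#'   curves in `input_fine`, the noise-free frame curves in
#'   `noise_free`, and the seed.
#' @export
simulate_study <- function(tracer, schedule, true_params,
                           noise_level = 0.05, seed = 1L,
                           bolus = bolus_model(), grid_dt_s = 0.25,
                           blood_noise = TRUE) {
  if (is.character(tracer)) tracer <- tracer_spec(tracer)
  if (is.character(schedule)) schedule <- framing_scheme(schedule)$schedule
  if (!inherits(schedule, "frame_schedule") || nrow(schedule) == 0L)
    stopf("invalid or empty frame schedule", class = "mbfpet_schedule_error")
  if (noise_level < 0) stop_invalid("noise_level must be >= 0")
  if (inherits(true_params, "kinetic_params"))
    true_params <- rep(list(true_params), 17L)
  if (length(true_params) != 17L)
    stop_invalid("true_params must be one bundle or a list of 17")

  total <- schedule_total(schedule)
  grid <- seq(0, total, by = grid_dt_s)
  if (grid[length(grid)] < total) grid <- c(grid, total)
  inp <- make_input_function(bolus, grid)

  ca_frames <- frame_average_plin(inp$C_A, schedule)
  crv_frames <- frame_average_plin(inp$C_RV, schedule)
  # segments sharing identical parameters share one forward-model curve
  keys <- vapply(true_params, function(p)
    paste(class(p)[1], paste(unlist(p), collapse = ","), sep = ":"),
    character(1))
  uniq <- !duplicated(keys)
  clean_uniq <- lapply(true_params[uniq], forward_model_frames,
                       C_A = inp$C_A, C_RV = inp$C_RV, schedule = schedule)
  clean <- clean_uniq[match(keys, keys[uniq])]

  surv <- decay_survival(tracer, frame_mid(schedule))
  dur <- schedule$duration_s
  peak <- max(vapply(clean, max, numeric(1)))
  noisy <- clean
  ca_noisy <- ca_frames; crv_noisy <- crv_frames
  if (noise_level > 0 && peak > 0) {
    # sd = noise_level * peak at the frame maximizing value/(dur*surv)
    rate_peak <- max(peak / (dur * surv))
    sd_for <- function(v) noise_level * peak *
      sqrt(pmax(v, 0) / (dur * surv) / rate_peak)
    with_seed(seed, {
      noisy <- lapply(clean, function(v) v + stats::rnorm(length(v),
                                                          sd = sd_for(v)))
      if (blood_noise) {
        ca_noisy <- ca_frames + stats::rnorm(length(ca_frames),
                                             sd = sd_for(ca_frames))
        crv_noisy <- crv_frames + stats::rnorm(length(crv_frames),
                                               sd = sd_for(crv_frames))
      }
    })
  }

  seg_names <- sprintf("seg%02d", 1:17)
  curves <- lapply(noisy, function(v) tac(schedule, v))
  names(curves) <- seg_names
  names(clean) <- seg_names
  names(true_params) <- seg_names
  structure(list(
    tracer = tracer, schedule = schedule, truth = true_params,
    curves = curves,
    C_A = tac(schedule, ca_noisy), C_RV = tac(schedule, crv_noisy),
    input_fine = inp,
    noise_free = clean, blood_frames = list(C_A = ca_frames,
                                            C_RV = crv_frames),
    noise_level = noise_level, seed = seed, bolus = bolus,
    motion_frames = integer(0), residual_interval_s = NULL
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %s, %d frames (%g s), noise %g, seed %s\n",
    x$tracer$name, nrow(x$schedule), schedule_total(x$schedule),
    x$noise_level, format(x$seed)))
  invisible(x)
}

#' Inject patient-motion corruption into a study
#'
#' Emulates the characteristic late-phase hump of patient motion: in the
#' affected frames the myocardial signal is replaced by a mixture
#' `(1 - f) * tissue + f * blood`, as happens when the sampling region
#' slides into the blood pool. Affected frame indices are recorded in the
#' study metadata.
#'
#' @param study a [simulate_study()] result.
#' @param motion_spec list with `frames` (integer indices of affected
#'   frames) and `fraction` (blood mixing fraction f in `[0, 1]`).
#' @return the perturbed study.
#' @export
apply_motion <- function(study, motion_spec) {
  stopifnot(inherits(study, "synthetic_study"))
  idx <- as.integer(motion_spec$frames)
  f <- motion_spec$fraction
  assert_scalar_num(f, "fraction", 0, 1)
  if (length(idx) && (min(idx) < 1L || max(idx) > nrow(study$schedule)))
    stop_domain("motion frame range outside the schedule (1..%d)",
                nrow(study$schedule))
  if (f == 0 || length(idx) == 0L) return(study)
  blood <- study$blood_frames$C_A[idx]
  study$curves <- lapply(study$curves, function(cv) {
    cv$values[idx] <- (1 - f) * cv$values[idx] + f * blood
    cv
  })
  study$motion_frames <- sort(unique(c(study$motion_frames, idx)))
  study$motion_fraction <- f
  study
}

# Mono-exponential extrapolation of a curve's late phase. Fits
# log(value) ~ t on the last `tail_fraction` of frames (log-linear least
# squares); non-positive tails fall back to a zero extrapolation. Returns a
# function of time (seconds, same clock as the curve).
tail_extrapolate <- function(curve, tail_fraction = 1 / 3) {
  mids <- frame_mid(curve$schedule)
  n <- length(mids)
  idx <- seq.int(max(1L, ceiling(n * (1 - tail_fraction))), n)
  if (length(idx) < 2L)
    stop_validate("too few late frames to extrapolate the tail")
  tt <- mids[idx]; vv <- curve$values[idx]
  if (any(vv <= 0)) {
    if (all(vv <= 0)) return(function(t) rep(0, length(t)))
    keep <- vv > 0
    if (sum(keep) < 2L) return(function(t) rep(0, length(t)))
    tt <- tt[keep]; vv <- vv[keep]
  }
  fit <- stats::lm.fit(cbind(1, tt), log(vv))
  a <- fit$coefficients[1]; b <- min(fit$coefficients[2], 0)  # no growth
  function(t) exp(a + b * t)
}

#' Contaminate a stress study with residual rest activity
#'
#' Emulates a shortened protocol in which the stress injection follows the
#' rest study after `interval_s` seconds, before the rest activity has
#' fully decayed. The rest curves' late phase is extrapolated
#' mono-exponentially (biological washout, on the decay-corrected curves)
#' and added to the stress curves scaled by the physical decay factor
#' `2^(-interval_s / T1/2)`: in the stress study's decay-corrected frame of
#' reference the contamination at stress time t is
#' `rest_extrapolation(interval_s + t) * 2^(-interval_s / T1/2)`.
#'
#' @param rest_study,stress_study studies from [simulate_study()] with the
#'   same tracer and schedule.
#' @param interval_s time between rest and stress injections, >= 0.
#' @return the contaminated stress study, with `residual_interval_s` set.
#' @export
add_residual_activity <- function(rest_study, stress_study, interval_s) {
  stopifnot(inherits(rest_study, "synthetic_study"),
            inherits(stress_study, "synthetic_study"))
  if (!identical(rest_study$tracer$name, stress_study$tracer$name))
    stop_validate("rest and stress studies use different tracers (%s vs %s)",
                  rest_study$tracer$name, stress_study$tracer$name)
  if (!isTRUE(all.equal(rest_study$schedule, stress_study$schedule)))
    stop_validate("rest and stress studies have different schedules")
  assert_scalar_num(interval_s, "interval_s", 0)
  decay <- decay_survival(rest_study$tracer, interval_s)
  mids <- frame_mid(stress_study$schedule)
  for (nm in names(stress_study$curves)) {
    extrap <- tail_extrapolate(rest_study$curves[[nm]])
    stress_study$curves[[nm]]$values <-
      stress_study$curves[[nm]]$values + decay * extrap(interval_s + mids)
  }
  for (bl in c("C_A", "C_RV")) {
    extrap <- tail_extrapolate(rest_study[[bl]])
    stress_study[[bl]]$values <-
      stress_study[[bl]]$values + decay * extrap(interval_s + mids)
  }
  stress_study$residual_interval_s <- interval_s
  stress_study
}
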