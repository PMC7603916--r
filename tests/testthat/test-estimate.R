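# Parameter estimation: recovery, estimator agreement, retention and
# residual correction.

test_that("noise-free one-tissue fit recovers the generating parameters", {
  tr <- tracer_spec("rubidium")
  k1 <- mbf_to_k1(2.0, tr$extraction)
  truth <- c(K1 = k1, k2 = k1 / 0.8, V_LV = 0.3, V_RV = 0.1)
  st <- simulate_study("rubidium", fix_rb_schedule(),
                       one_tissue_params(truth[1], truth[2], truth[3],
                                         truth[4]),
                       noise_level = 0, seed = 1)
  f <- fit_1tc(st$curves$seg01, st$input_fine$C_A, st$input_fine$C_RV,
               tracer = tr)
  expect_true(f$converged)
  expect_true(all(abs(f$estimates / truth - 1) < 0.005))
  # determinism: identical inputs and options give identical results
  f2 <- fit_1tc(st$curves$seg01, st$input_fine$C_A, st$input_fine$C_RV,
                tracer = tr)
  expect_identical(f$estimates, f2$estimates)
  expect_error(fit_1tc(tac(frame_schedule(rep(5, 5)), rep(1, 5)),
                       st$input_fine$C_A, st$input_fine$C_RV),
               class = "mbfpet_validation_error")  # too few frames
})

test_that("fitting a pure-blood curve returns V_LV near 1 and K1 near 0", {
  st <- fix_water_study(noise = 0)
  blood <- tac(st$schedule, st$blood_frames$C_A)
  # without the (1 - V_LV - V_RV) pre-factor the tissue term must vanish
  # explicitly: K1 is driven to 0
  f <- fit_1tc(blood, st$input_fine$C_A, st$input_fine$C_RV,
               tracer = st$tracer,
               options = fit_options(prefactor = FALSE))
  expect_true(f$estimates[["V_LV"]] > 0.98)
  expect_true(f$estimates[["K1"]] < 0.02)
  # with the pre-factor, V_LV = 1 already nulls the tissue term; the
  # effective uptake (1 - V_LV - V_RV) K1 must then be ~0
  f2 <- fit_1tc(blood, st$input_fine$C_A, st$input_fine$C_RV,
                tracer = st$tracer)
  eff <- (1 - f2$estimates[["V_LV"]] - f2$estimates[["V_RV"]]) *
    f2$estimates[["K1"]]
  expect_true(f2$estimates[["V_LV"]] > 0.98)
  expect_true(abs(eff) < 0.02)
})

test_that("noise-free two-tissue fit recovers the generating parameters", {
  sch <- framing_scheme("hutchins-ammonia")$schedule
  tr <- tracer_spec("ammonia")
  k1 <- mbf_to_k1(2.0, tr$extraction)
  truth <- c(K1 = k1, k2 = 0.6, k3 = 0.12, V_LV = 0.3, V_RV = 0.1)
  st <- simulate_study("ammonia", sch,
                       two_tissue_irr_params(truth[1], truth[2], truth[3],
                                             truth[4], truth[5]),
                       noise_level = 0, seed = 5)
  f <- fit_2tc_irr(st$curves$seg01, st$input_fine$C_A, st$input_fine$C_RV,
                   tracer = tr)   # default 4-min window
  expect_true(f$converged)
  expect_true(all(abs(f$estimates / truth - 1) < 0.005))
})

test_that("basis fit recovers on-grid flows exactly and off-grid to < 1%", {
  grid <- basis_grid()
  on_grid_mbf <- as.numeric(grid)[20]
  st <- fix_water_study(mbf = on_grid_mbf, noise = 0)
  f <- fit_water_basis(st$curves$seg01, st$input_fine$C_A,
                       st$input_fine$C_RV, grid = grid, tracer = st$tracer)
  expect_equal(f$estimates[["MBF"]], on_grid_mbf, tolerance = 1e-5)
  expect_equal(f$estimates[["PTF"]], 0.7, tolerance = 1e-4)
  # off-grid: best grid point within one spacing, refined to < 1%
  off <- 2.5
  expect_true(min(abs(as.numeric(grid) - off)) > 1e-3)  # genuinely off-grid
  st2 <- fix_water_study(mbf = off, noise = 0)
  f2 <- fit_water_basis(st2$curves$seg01, st2$input_fine$C_A,
                        st2$input_fine$C_RV, grid = grid,
                        tracer = st2$tracer)
  i0 <- f2$diagnostics$grid_index
  spacing <- diff(as.numeric(grid))[max(i0 - 1, 1)]
  expect_true(abs(as.numeric(grid)[i0] - off) <= spacing)
  expect_true(abs(f2$estimates[["MBF"]] - off) / off < 0.01)
  expect_true(all(abs(f2$estimates - c(off, 0.7, 0.25, 0.1)) /
                    c(off, 0.7, 0.25, 0.1) < 0.005))
})

test_that("basis and general nonlinear water fits agree on noise-free data", {
  st <- fix_water_study(mbf = 2.5, noise = 0)
  fb <- fit_water_basis(st$curves$seg01, st$input_fine$C_A,
                        st$input_fine$C_RV, tracer = st$tracer)
  f1 <- fit_1tc(st$curves$seg01, st$input_fine$C_A, st$input_fine$C_RV,
                tracer = st$tracer,
                options = fit_options(prefactor = FALSE))
  mbf_from_k2 <- f1$estimates[["k2"]] * 0.91
  expect_true(abs(fb$estimates[["MBF"]] - mbf_from_k2) / mbf_from_k2 < 0.005)
})

test_that("an all-zero curve is flagged unidentifiable", {
  st <- fix_water_study(noise = 0)
  zero <- tac(st$schedule, rep(0, nrow(st$schedule)))
  f <- fit_water_basis(zero, st$input_fine$C_A, st$input_fine$C_RV)
  expect_true(f$diagnostics$unidentifiable)
  expect_equal(unname(f$estimates[["MBF"]]), 0)
})

test_that("MBF recovery degrades gracefully with noise (factorial design)", {
  flows <- c(0.5, 1, 2, 4)
  noise_bound <- c("0" = 0.005, "0.02" = 0.03, "0.05" = 0.08)
  nrep <- 11
  for (noise in as.numeric(names(noise_bound))) {
    errs <- c()
    for (mbf in flows) {
      for (r in seq_len(if (noise == 0) 1 else nrep)) {
        st <- fix_water_study(mbf = mbf, noise = noise,
                              seed = 7000 + 100 * mbf + r)
        f <- fit_water_basis(st$curves$seg01, st$input_fine$C_A,
                             st$input_fine$C_RV, tracer = st$tracer)
        errs <- c(errs, abs(f$estimates[["MBF"]] - mbf) / mbf)
      }
    }
    expect_lt(stats::median(errs), noise_bound[[as.character(noise)]])
  }
})

test_that("reported standard errors track the Monte-Carlo spread", {
  nrep <- 100
  truth <- c(2.5, 0.7, 0.25, 0.1)
  est <- matrix(NA_real_, nrep, 4); ses <- matrix(NA_real_, nrep, 4)
  for (i in seq_len(nrep)) {
    st <- fix_water_study(noise = 0.05, seed = 5000 + i)
    f <- fit_water_basis(st$curves$seg01, st$input_fine$C_A,
                         st$input_fine$C_RV, tracer = st$tracer)
    est[i, ] <- f$estimates; ses[i, ] <- f$se
  }
  ratio <- apply(ses, 2, stats::median) / apply(est, 2, stats::sd)
  expect_true(all(ratio > 0.7 & ratio < 1.3))
})

test_that("parametric maps fit masked voxels and flag background", {
  st_lo <- fix_water_study(mbf = 1, noise = 0)
  st_hi <- fix_water_study(mbf = 3, noise = 0)
  nx <- 6; ny <- 6
  vol <- array(0, dim = c(nx, ny, 1, nrow(st_lo$schedule)))
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (i <= 2) vol[i, j, 1, ] <- st_lo$curves$seg01$values
    else if (i >= 5) vol[i, j, 1, ] <- st_hi$curves$seg01$values
    # rows 3-4 stay at zero: background
  }
  maps <- fit_parametric_map(vol, st_lo$input_fine$C_A,
                             st_lo$input_fine$C_RV, st_lo$schedule,
                             mask_threshold = 1, tracer = st_lo$tracer)
  expect_true(all(is.na(maps$MBF[3:4, , 1])))          # sentinel outside mask
  expect_true(all(abs(maps$MBF[1:2, , 1] - 1) < 0.01)) # first mode
  expect_true(all(abs(maps$MBF[5:6, , 1] - 3) < 0.02)) # second mode
  expect_true(all(abs(maps$PTF[c(1:2, 5:6), , 1] - 0.7) < 0.01))
  expect_error(fit_parametric_map(vol[, , , 1:3], st_lo$input_fine$C_A,
                                  st_lo$input_fine$C_RV, st_lo$schedule),
               class = "mbfpet_validation_error")
})

test_that("retention estimator is constructive, conservative and scale-free", {
  inp <- fix_inputs(240)
  sch <- fix_water_schedule()
  # constructive: tissue built as exactly Ki * int C_A returns Ki
  ki_true <- 0.5
  cum_frames <- mbfpet:::cumint_frames(inp$C_A, sch) / 60
  built <- tac(sch, ki_true * cum_frames)
  est <- retention_ki(built, inp$C_A, window = c(90, 240))
  expect_equal(est$Ki, ki_true, tolerance = 5e-3)
  # doubling both curves leaves Ki unchanged
  built2 <- tac(sch, 2 * built$values)
  ca2 <- plin_curve(inp$C_A$t, 2 * inp$C_A$y)
  est2 <- retention_ki(built2, ca2, window = c(90, 240))
  expect_equal(est2$Ki, est$Ki, tolerance = 1e-12)
  # on a 1TC-generated curve, Ki underestimates K1
  st <- simulate_study("rubidium", fix_rb_schedule(),
                       one_tissue_params(1.2, 0.5, 0, 0),
                       noise_level = 0, seed = 3)
  ki <- retention_ki(st$curves$seg01, st$input_fine$C_A,
                     window = c(120, 600))
  expect_lt(ki$Ki, 1.2)
  expect_gt(ki$Ki, 0)
  # window and integral validation
  expect_error(retention_ki(built, inp$C_A, window = c(90, 500)),
               class = "mbfpet_domain_error")
  zero_ca <- plin_curve(c(0, 240), c(0, 0))
  expect_error(retention_ki(built, zero_ca, window = c(90, 240)),
               class = "mbfpet_domain_error")
})

test_that("residual correction inverts the simulated contamination", {
  sch <- framing_scheme("hutchins-ammonia")$schedule
  tr <- tracer_spec("ammonia")
  rest <- simulate_study("ammonia", sch, one_tissue_params(1, 0.3, 0.25, 0.1),
                         noise_level = 0, seed = 21)
  stress_clean <- simulate_study("ammonia", sch,
                                 one_tissue_params(2.4, 0.7, 0.25, 0.1),
                                 noise_level = 0, seed = 22)
  interval <- 20 * 60
  contaminated <- add_residual_activity(rest, stress_clean, interval)
  corrected <- correct_residual(contaminated$curves$seg01,
                                rest$curves$seg01, interval, tr)
  clean <- stress_clean$curves$seg01$values
  late <- corrected$schedule$start_s + corrected$schedule$duration_s > 120
  expect_true(all(abs(corrected$values[late] - clean[late]) /
                    clean[late] < 0.02))
  # interval -> Inf is a no-op
  noop <- correct_residual(contaminated$curves$seg01, rest$curves$seg01,
                           Inf, tr)
  expect_equal(noop$values, contaminated$curves$seg01$values)
  # corrected-then-fitted stress MBF within 3% of the uncontaminated fit
  f_clean <- fit_1tc(stress_clean$curves$seg01, stress_clean$input_fine$C_A,
                     stress_clean$input_fine$C_RV, tracer = tr)
  f_corr <- fit_1tc(corrected, stress_clean$input_fine$C_A,
                    stress_clean$input_fine$C_RV, tracer = tr)
  expect_true(abs(f_corr$estimates[["K1"]] / f_clean$estimates[["K1"]] - 1)
              < 0.03)
})
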