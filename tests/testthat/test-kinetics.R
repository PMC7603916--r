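# Forward-model correctness against closed forms and independent
# quadrature / ODE oracles.

test_that("one-tissue tissue response matches closed forms", {
  inp <- fix_inputs(200)
  times <- seq(5, 200, by = 15)
  # zero uptake
  expect_equal(tissue_response_1tc(inp$C_A, 0, 0.9, times = times),
               rep(0, length(times)))
  # constant input, no clearance: linear accumulation K1 * c * t (minutes)
  const <- plin_curve(c(0, 300), c(4, 4))
  got <- tissue_response_1tc(const, 0.8, 0, times = c(60, 150, 300))
  expect_equal(got, 0.8 * 4 * c(60, 150, 300) / 60, tolerance = 1e-12)
  expect_error(tissue_response_1tc(inp$C_A, -0.1, 0.9, times = times),
               class = "mbfpet_invalid_parameter")
  expect_error(tissue_response_1tc(inp$C_A, 0.8, 0.9, times = 1e5),
               class = "mbfpet_domain_error")
})

test_that("exponential convolution matches 1-ms trapezoidal quadrature", {
  inp <- fix_inputs(200, bolus_model(recirc_fraction = 0))
  K1 <- 0.8; k2 <- 0.9
  times <- c(20, 45, 90, 150, 200)
  mine <- tissue_response_1tc(inp$C_A, K1, k2, times = times)
  oracle <- vapply(times, function(tq) {
    tt <- seq(0, tq, by = 0.001)
    ca <- plin_eval(inp$C_A, tt)
    integrand <- ca * exp(-(k2 / 60) * (tq - tt))
    (K1 / 60) * sum((integrand[-1] + integrand[-length(tt)]) / 2) * 0.001
  }, numeric(1))
  expect_true(all(abs(mine - oracle) / oracle < 1e-3))
})

test_that("forward models are linear in the input amplitude", {
  inp <- fix_inputs(200)
  times <- seq(10, 200, by = 10)
  base <- tissue_response_1tc(inp$C_A, 0.8, 0.9, times = times)
  scaled_input <- plin_curve(inp$C_A$t, 3 * inp$C_A$y)
  expect_equal(tissue_response_1tc(scaled_input, 0.8, 0.9, times = times),
               3 * base, tolerance = 1e-12)
})

test_that("PET signal mixes tissue and blood components correctly", {
  inp <- fix_inputs(200)
  times <- seq(10, 200, by = 10)
  # pure blood voxel: V_LV = 1 reproduces C_A exactly (pre-factor on)
  p_blood <- one_tissue_params(0.8, 0.9, V_LV = 1, V_RV = 0)
  expect_equal(pet_signal_1tc(p_blood, inp$C_A, inp$C_RV, times = times),
               plin_eval(inp$C_A, times))
  # no uptake, no blood: identically zero
  p0 <- one_tissue_params(0, 0, 0, 0)
  expect_equal(pet_signal_1tc(p0, inp$C_A, inp$C_RV, times = times),
               rep(0, length(times)))
  # equals the sum of separately computed components
  p <- one_tissue_params(0.9, 1.1, 0.25, 0.12)
  tissue <- tissue_response_1tc(inp$C_A, p$K1, p$k2, times = times)
  expect_equal(pet_signal_1tc(p, inp$C_A, inp$C_RV, times = times),
               (1 - 0.25 - 0.12) * tissue +
                 0.25 * plin_eval(inp$C_A, times) +
                 0.12 * plin_eval(inp$C_RV, times),
               tolerance = 1e-12)
  # invalid blood fractions
  expect_error(one_tissue_params(0.9, 1.1, 0.7, 0.4),
               class = "mbfpet_invalid_parameter")
})

test_that("the water model ties clearance to flow via the partition coefficient", {
  inp <- fix_inputs(200)
  times <- seq(10, 200, by = 10)
  # MBF = 0: blood only
  p0 <- water_params(0, 0.7, 0.3, 0.1)
  expect_equal(pet_signal_water(p0, inp$C_A, inp$C_RV, times = times),
               0.3 * plin_eval(inp$C_A, times) +
                 0.1 * plin_eval(inp$C_RV, times))
  # partition-coefficient identity
  expect_equal(water_params(0.91, 0.7)$k2, 1.0)
  # algebraic cross-check against the generic one-tissue form
  p <- water_params(2.2, 0.65, 0.2, 0.1)
  p1 <- one_tissue_params(K1 = 0.65 * 2.2, k2 = 2.2 / 0.91, 0.2, 0.1)
  expect_equal(pet_signal_water(p, inp$C_A, inp$C_RV, times = times),
               pet_signal_1tc(p1, inp$C_A, inp$C_RV, times = times,
                              prefactor = FALSE),
               tolerance = 1e-12)
})

test_that("irreversible two-tissue model nests the one-tissue model", {
  inp <- fix_inputs(200)
  times <- seq(10, 200, by = 10)
  p2 <- two_tissue_irr_params(0.9, 1.1, 0, 0.25, 0.12)
  p1 <- one_tissue_params(0.9, 1.1, 0.25, 0.12)
  expect_equal(pet_signal_2tc_irr(p2, inp$C_A, inp$C_RV, times = times),
               pet_signal_1tc(p1, inp$C_A, inp$C_RV, times = times),
               tolerance = 1e-12)
  # k2 = 0: all extracted tracer trapped, tissue = K1 * int C_A
  ptrap <- two_tissue_irr_params(0.9, 0, 0.5, 0, 0)
  got <- pet_signal_2tc_irr(ptrap, inp$C_A, inp$C_RV, times = times)
  want <- tissue_response_1tc(inp$C_A, 0.9, 0, times = times)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("two-tissue model matches a stiff ODE integration", {
  inp <- fix_inputs(400)
  p <- two_tissue_irr_params(0.8, 0.6, 0.12, 0.2, 0.08)
  times <- seq(15, 400, by = 25)
  mine <- pet_signal_2tc_irr(p, inp$C_A, inp$C_RV, times = times)
  caf <- function(t) plin_eval(inp$C_A, t, extend = TRUE)
  sol <- deSolve::ode(
    c(0, 0), c(0, times),
    function(t, y, parms) list(c(
      p$K1 / 60 * caf(t) - (p$k2 + p$k3) / 60 * y[1],
      p$k3 / 60 * y[1])),
    NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  tissue <- rowSums(sol[-1, 2:3, drop = FALSE])
  oracle <- (1 - p$V_LV - p$V_RV) * tissue +
    p$V_LV * caf(times) + p$V_RV * plin_eval(inp$C_RV, times)
  expect_true(max(abs(mine - oracle) / pmax(oracle, 1e-9)) < 1e-3)
})

test_that("noise-free model outputs are non-negative for valid inputs", {
  inp <- fix_inputs(240)
  times <- seq(0, 240, by = 5)
  cases <- list(
    pet_signal_1tc(one_tissue_params(1.2, 2.5, 0.3, 0.15), inp$C_A,
                   inp$C_RV, times = times),
    pet_signal_water(water_params(4, 0.9, 0.1, 0.05), inp$C_A, inp$C_RV,
                     times = times),
    pet_signal_2tc_irr(two_tissue_irr_params(1, 0.5, 0.3, 0.2, 0.2),
                       inp$C_A, inp$C_RV, times = times))
  for (y in cases) expect_true(all(y >= 0))
})

test_that("derived water quantities follow their closed forms", {
  expect_equal(transmural_mbf(water_params(2, 1, 0, 0)), 2)
  expect_equal(transmural_mbf(water_params(2, 0.6, 0.2, 0.2)),
               2 * 0.6 / 1.4)
  expect_equal(transmural_mbf(water_params(0, 0.6, 0.2, 0.2)), 0)
  expect_equal(perfusable_tissue_index(0.45, 0.60), 0.75)
  expect_equal(perfusable_tissue_index(0.6, 0.6), 1)
  expect_equal(perfusable_tissue_index(0, 0.5), 0)
  expect_error(perfusable_tissue_index(0.5, 0),
               class = "mbfpet_invalid_parameter")
})

test_that("frame-averaged evaluation matches direct integration", {
  inp <- fix_inputs(240)
  sch <- fix_water_schedule()
  p <- water_params(2, 0.7, 0.25, 0.1)
  avg <- pet_signal_water(p, inp$C_A, inp$C_RV, schedule = sch)
  # oracle: dense instantaneous samples averaged per frame
  oracle <- vapply(seq_len(nrow(sch)), function(i) {
    tt <- seq(sch$start_s[i], sch$start_s[i] + sch$duration_s[i],
              length.out = 201)
    y <- pet_signal_water(p, inp$C_A, inp$C_RV, times = tt)
    mean((y[-1] + y[-201]) / 2)
  }, numeric(1))
  # pointwise below 0.1%; relative to the curve peak below 0.01%
  expect_true(max(abs(avg - oracle) / pmax(oracle, 1e-9)) < 1e-3)
  expect_true(max(abs(avg - oracle)) / max(oracle) < 1e-4)
})
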