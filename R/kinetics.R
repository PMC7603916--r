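# Forward tracer-kinetic models.
#
# All models are driven by a continuous arterial input C_A(t) (and an RV
# blood curve C_RV(t)) represented as piecewise-linear curves; the
# convolution with an exponential kernel is then available in closed form
# and is evaluated by an exact per-segment recursion (no quadrature error).
#
# Unit convention: times are seconds at the interface; rate constants are
# per minute (K1 in mL/g/min, k2/k3 in 1/min). Conversion happens once,
# here.

# Exact convolution integral I(t) = \int_0^t C(s) exp(-k (t - s)) ds for a
# piecewise-linear C and k in 1/s, evaluated at (sorted or unsorted) times.
# On each linear segment with slope b the update is
#   I(t1) = I(t0) E + C(t1) g1 - b g2,   E = exp(-k dt),
#   g1 = (1 - E)/k,  g2 = (dt - g1)/k,
# with series fallbacks for small k dt to avoid cancellation.
conv_exp_plin <- function(curve, k_s, times) {
  stopifnot(inherits(curve, "plin_curve"), k_s >= 0)
  if (length(times) == 0L) return(numeric(0))
  if (any(times < 0)) stop_domain("evaluation times must be >= 0")
  tmax <- curve$t[length(curve$t)]
  if (any(times > tmax + 1e-9))
    stop_domain("evaluation time %g beyond input support [0, %g]",
                max(times), tmax)
  ord <- order(times)
  tq <- times[ord]
  grid <- sort(unique(c(curve$t[curve$t <= tmax], pmin(tq, tmax))))
  yg <- stats::approx(curve$t, curve$y, xout = grid)$y
  n <- length(grid)
  I <- numeric(n)
  if (n > 1L) {
    dt <- diff(grid)
    b <- diff(yg) / dt
    x <- k_s * dt
    E <- exp(-x)
    small <- x < 1e-5
    if (k_s == 0) {
      g1 <- dt
      g2 <- dt^2 / 2
    } else {
      g1 <- ifelse(small, dt * (1 - x / 2 + x^2 / 6 - x^3 / 24), (1 - E) / k_s)
      g2 <- ifelse(small, dt^2 * (1 / 2 - x / 3 + x^2 / 8 - x^3 / 30),
                   (dt - (1 - E) / k_s) / k_s)
    }
    for (j in seq_len(n - 1L))
      I[j + 1L] <- I[j] * E[j] + yg[j + 1L] * g1[j] - b[j] * g2[j]
  }
  out <- I[match(pmin(tq, tmax), grid)]
  out[order(ord)] <- out
  out
}

# Running integral \int_0^t C(s) ds of a piecewise-linear curve (k = 0 case)
cumint_plin <- function(curve, times) conv_exp_plin(curve, 0, times)

# Simpson frame-averaging of an instantaneous model f(times). n_sub must be
# even; accuracy O(h^4) on the smooth model curves.
frame_average_fun <- function(f, schedule, n_sub = 8L) {
  stopifnot(n_sub %% 2L == 0L)
  k <- n_sub + 1L
  offs <- seq(0, 1, length.out = k)
  tmat <- outer(schedule$start_s, rep(1, k)) +
    outer(schedule$duration_s, offs)
  vals <- f(as.numeric(t(tmat)))
  vmat <- matrix(vals, ncol = k, byrow = TRUE)
  w <- c(1, rep(c(4, 2), length.out = k - 2L), 1)
  w[k] <- 1
  as.numeric(vmat %*% w) / (3 * n_sub)
}

# Resolve the times/schedule evaluation convention shared by the forward
# models: a `schedule` asks for frame-averaged values, `times` for
# instantaneous samples.
eval_model <- function(f, times, schedule, n_sub = 8L) {
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "frame_schedule"))
    frame_average_fun(f, schedule, n_sub)
  } else {
    if (is.null(times)) stop_invalid("supply either 'times' or 'schedule'")
    f(times)
  }
}

#' Single-tissue compartment tissue response
#'
#' The tissue concentration of the one-tissue compartment model,
#' `C_T(t) = K1 * (C_A conv exp(-k2 t))`, computed with the analytic
#' convolution of a piecewise-linear input with an exponential kernel.
#'
#' @param input_curve arterial input function: a [plin_curve()] or a [tac()]
#'   (interpreted at frame mid-times).
#' @param K1 transport rate constant, mL/g/min (>= 0).
#' @param k2 clearance rate constant, 1/min (>= 0).
#' @param times evaluation times in seconds (instantaneous samples), or
#' @param schedule a [frame_schedule()] for frame-averaged evaluation.
#' @return numeric vector of tissue concentrations (kBq/mL).
#' @export
tissue_response_1tc <- function(input_curve, K1, k2, times = NULL,
                                schedule = NULL) {
  assert_scalar_num(K1, "K1", 0)
  assert_scalar_num(k2, "k2", 0)
  ca <- as_plin(input_curve)
  eval_model(function(tt) (K1 / 60) * conv_exp_plin(ca, k2 / 60, tt),
             times, schedule)
}

# --- parameter bundles -----------------------------------------------------

#' Parameters of the one-tissue compartment model with blood terms
#'
#' @param K1 mL/g/min, >= 0.
#' @param k2 1/min, >= 0.
#' @param V_LV,V_RV fractional left-/right-ventricular blood contributions
#'   (blood volume plus spill-over); both >= 0 and `V_LV + V_RV <= 1`
#'   (equality is the degenerate pure-blood voxel).
#' @return object of class `one_tissue_params` (and `kinetic_params`).
#' @export
one_tissue_params <- function(K1, k2, V_LV = 0, V_RV = 0) {
  assert_scalar_num(K1, "K1", 0); assert_scalar_num(k2, "k2", 0)
  assert_scalar_num(V_LV, "V_LV", 0); assert_scalar_num(V_RV, "V_RV", 0)
  if (V_LV + V_RV > 1)
    stop_invalid("V_LV + V_RV must be <= 1 (got %g)", V_LV + V_RV)
  structure(list(K1 = K1, k2 = k2, V_LV = V_LV, V_RV = V_RV),
            class = c("one_tissue_params", "kinetic_params"))
}

#' Parameters of the water perfusion model
#'
#' For freely diffusible water, K1 equals MBF and the clearance rate is
#' tied to flow by the tissue partition coefficient:
#' `k2 = MBF / 0.91` (1/min). The amplitude is the perfusable tissue
#' fraction PTF (g/mL), an intrinsic partial-volume correction.
#'
#' @param MBF myocardial blood flow, mL/g/min.
#' @param PTF perfusable tissue fraction, g/mL.
#' @param V_LV,V_RV blood fractions as in [one_tissue_params()].
#' @param partition_coefficient g/mL, default 0.91 for myocardium.
#' @return object of class `water_params` (and `kinetic_params`), with the
#'   implied `k2` retrievable via `$k2()`-style field `k2`.
#' @export
water_params <- function(MBF, PTF, V_LV = 0, V_RV = 0,
                         partition_coefficient = 0.91) {
  assert_scalar_num(MBF, "MBF", 0); assert_scalar_num(PTF, "PTF", 0)
  assert_scalar_num(V_LV, "V_LV", 0); assert_scalar_num(V_RV, "V_RV", 0)
  assert_scalar_num(partition_coefficient, "partition_coefficient", 0,
                    strict_lower = TRUE)
  if (V_LV + V_RV > 1)
    stop_invalid("V_LV + V_RV must be <= 1 (got %g)", V_LV + V_RV)
  structure(list(MBF = MBF, PTF = PTF, V_LV = V_LV, V_RV = V_RV,
                 partition_coefficient = partition_coefficient,
                 k2 = MBF / partition_coefficient),
            class = c("water_params", "kinetic_params"))
}

#' Parameters of the irreversible two-tissue compartment model
#'
#' Free tissue compartment fed at K1 with efflux k2 and irreversible
#' trapping at k3 (metabolic incorporation, e.g. the ammonia glutamine
#' pool).
#'
#' @param K1 mL/g/min; @param k2,k3 1/min; all >= 0.
#' @param V_LV,V_RV blood fractions as in [one_tissue_params()].
#' @return object of class `two_tissue_irr_params` (and `kinetic_params`).
#' @export
two_tissue_irr_params <- function(K1, k2, k3, V_LV = 0, V_RV = 0) {
  assert_scalar_num(K1, "K1", 0); assert_scalar_num(k2, "k2", 0)
  assert_scalar_num(k3, "k3", 0)
  assert_scalar_num(V_LV, "V_LV", 0); assert_scalar_num(V_RV, "V_RV", 0)
  if (V_LV + V_RV > 1)
    stop_invalid("V_LV + V_RV must be <= 1 (got %g)", V_LV + V_RV)
  structure(list(K1 = K1, k2 = k2, k3 = k3, V_LV = V_LV, V_RV = V_RV),
            class = c("two_tissue_irr_params", "kinetic_params"))
}

#' Retention-model parameters
#'
#' @param Ki net retention rate, mL/g/min (>= 0).
#' @param integration_window `(t0_s, t1_s)` late-uptake window, t1 > t0.
#' @return object of class `retention_params` (and `kinetic_params`).
#' @export
retention_params <- function(Ki, integration_window) {
  assert_scalar_num(Ki, "Ki", 0)
  stopifnot(length(integration_window) == 2L)
  if (integration_window[2] <= integration_window[1])
    stop_invalid("integration window must have t1 > t0")
  structure(list(Ki = Ki,
                 integration_window = as.numeric(integration_window)),
            class = c("retention_params", "kinetic_params"))
}

# --- full PET signal models ------------------------------------------------

blood_mix <- function(tissue, ca_vals, crv_vals, V_LV, V_RV, prefactor) {
  pf <- if (prefactor) 1 - V_LV - V_RV else 1
  pf * tissue + V_LV * ca_vals + V_RV * crv_vals
}

#' Model PET signal of the one-tissue compartment model
#'
#' The measured myocardial PET signal mixes the tissue response with
#' left- and right-ventricular blood (blood volume plus spill-over):
#' `C_PET = (1 - V_LV - V_RV) K1 C_A conv exp(-k2 t) + V_LV C_A + V_RV C_RV`.
#' The `(1 - V_LV - V_RV)` pre-factor is the default convention; it is
#' sometimes omitted, which `prefactor = FALSE` reproduces.
#'
#' @param params a [one_tissue_params()].
#' @param C_A,C_RV arterial and right-ventricular blood curves
#'   ([plin_curve()] or [tac()]).
#' @param times,schedule evaluation convention as in
#'   [tissue_response_1tc()].
#' @param prefactor logical; apply the `(1 - V_LV - V_RV)` factor.
#' @return numeric vector of model PET values.
#' @export
pet_signal_1tc <- function(params, C_A, C_RV, times = NULL, schedule = NULL,
                           prefactor = TRUE) {
  stopifnot(inherits(params, "one_tissue_params"))
  ca <- as_plin(C_A); crv <- as_plin(C_RV)
  tissue_fun <- function(tt)
    (params$K1 / 60) * conv_exp_plin(ca, params$k2 / 60, tt)
  mix_model(tissue_fun, ca, crv, params$V_LV, params$V_RV, prefactor,
            times, schedule)
}

# Shared tissue + blood mixing with the two evaluation conventions. For
# frame-averaged evaluation the smooth tissue term uses Simpson
# sub-sampling while the piecewise-linear blood terms are averaged
# exactly (their kinks would otherwise degrade the Simpson rule).
mix_model <- function(tissue_fun, ca, crv, V_LV, V_RV, prefactor,
                      times, schedule, n_sub = 8L) {
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "frame_schedule"))
    tissue <- frame_average_fun(tissue_fun, schedule, n_sub)
    blood_mix(tissue, frame_average_plin(ca, schedule),
              frame_average_plin(crv, schedule), V_LV, V_RV, prefactor)
  } else {
    if (is.null(times)) stop_invalid("supply either 'times' or 'schedule'")
    blood_mix(tissue_fun(times), plin_eval(ca, times),
              plin_eval(crv, times), V_LV, V_RV, prefactor)
  }
}

#' Model PET signal of the water perfusion model
#'
#' `C_PET = PTF * MBF * C_A conv exp(-(MBF/0.91) t) + V_LV C_A + V_RV C_RV`.
#' The amplitude convention follows the standard water model: PTF multiplies
#' the tissue term directly and no `(1 - V_LV - V_RV)` pre-factor is
#' applied (PTF itself absorbs the tissue-fraction scaling); setting
#' `ptf_absorbs_blood_fraction = FALSE` instead applies the pre-factor, for
#' cross-checks against the generic one-tissue form.
#'
#' @param params a [water_params()].
#' @inheritParams pet_signal_1tc
#' @param ptf_absorbs_blood_fraction convention flag, default `TRUE`.
#' @return numeric vector of model PET values.
#' @export
pet_signal_water <- function(params, C_A, C_RV, times = NULL,
                             schedule = NULL,
                             ptf_absorbs_blood_fraction = TRUE) {
  stopifnot(inherits(params, "water_params"))
  ca <- as_plin(C_A); crv <- as_plin(C_RV)
  amp <- params$PTF * params$MBF
  tissue_fun <- function(tt)
    (amp / 60) * conv_exp_plin(ca, params$k2 / 60, tt)
  mix_model(tissue_fun, ca, crv, params$V_LV, params$V_RV,
            prefactor = !ptf_absorbs_blood_fraction, times, schedule)
}

#' Model PET signal of the irreversible two-tissue compartment model
#'
#' Free compartment `C1' = K1 C_A - (k2 + k3) C1`, trapped compartment
#' `C2' = k3 C1`. The total tissue activity has the closed form
#' `C_T = K1 [ k2/(k2+k3) * C_A conv exp(-(k2+k3) t) + k3/(k2+k3) * int C_A ]`,
#' mixed with blood terms as in [pet_signal_1tc()]. With `k3 = 0` this is
#' exactly the one-tissue model; with `k2 = 0` all extracted tracer is
#' trapped and the tissue term is `K1 * int C_A`.
#'
#' @param params a [two_tissue_irr_params()].
#' @inheritParams pet_signal_1tc
#' @return numeric vector of model PET values.
#' @export
pet_signal_2tc_irr <- function(params, C_A, C_RV, times = NULL,
                               schedule = NULL, prefactor = TRUE) {
  stopifnot(inherits(params, "two_tissue_irr_params"))
  ca <- as_plin(C_A); crv <- as_plin(C_RV)
  k23 <- params$k2 + params$k3
  tissue_fun <- function(tt) {
    if (k23 == 0) (params$K1 / 60) * cumint_plin(ca, tt)
    else (params$K1 / 60) *
      (params$k2 / k23 * conv_exp_plin(ca, k23 / 60, tt) +
       params$k3 / k23 * cumint_plin(ca, tt))
  }
  mix_model(tissue_fun, ca, crv, params$V_LV, params$V_RV, prefactor,
            times, schedule)
}

# --- derived quantities ----------------------------------------------------

#' Transmural myocardial blood flow from water-model parameters
#'
#' The water model measures MBF in perfusable tissue only. Transmural MBF,
#' comparable to what extracted tracers measure, is computed indirectly as
#' `MBF * PTF / (1 + V_LV + V_RV)`.
#'
#' @param params a [water_params()].
#' @return transmural MBF in mL/g/min.
#' @export
transmural_mbf <- function(params) {
  stopifnot(inherits(params, "water_params"))
  params$MBF * params$PTF / (1 + params$V_LV + params$V_RV)
}

#' Perfusable tissue index
#'
#' PTI = PTF / ATF, the fraction of anatomical tissue that is perfusable; a
#' marker of myocardial viability (unity in fully perfusable tissue).
#'
#' @param PTF perfusable tissue fraction, g/mL (>= 0).
#' @param ATF anatomical tissue fraction, g/mL (> 0).
#' @return PTI, unitless.
#' @export
perfusable_tissue_index <- function(PTF, ATF) {
  assert_scalar_num(PTF, "PTF", 0)
  if (!is.numeric(ATF) || length(ATF) != 1L || !is.finite(ATF) || ATF <= 0)
    stop_invalid("ATF must be > 0")
  PTF / ATF
}
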