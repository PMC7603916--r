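# Parameter estimation: weighted nonlinear fitting of the compartment
# models, basis-function parametric mapping for water, the retention
# estimator, and residual-activity correction.
#
# Weighting follows counting statistics on decay-corrected frames:
# w_i proportional to frame_duration_i * decay_survival_i (inverse of the
# frame variance up to a constant). Optimization uses bounded
# Levenberg-Marquardt least squares (minpack.lm) with a fixed multi-start
# grid over the clearance rate to guard against the K1/k2 trade-off;
# everything is deterministic given inputs and options.

#' Fitting options
#'
#' @param prefactor apply the `(1 - V_LV - V_RV)` pre-factor in the
#'   one/two-tissue models (convention flag, recorded in the result).
#' @param lower,upper box constraints, named `(K1, k2, k3, V_LV, V_RV)`;
#'   defaults K1 in `[0, 6]` mL/g/min, k2 (and k3) in `[0, 8]` 1/min,
#'   volume fractions in `[0, 1]`.
#' @param k2_starts multi-start grid of initial clearance rates (1/min).
#' @param n_sub Simpson subdivisions per frame for frame-averaged model
#'   evaluation.
#' @param window_s restrict the fit to frames ending within this many
#'   seconds from scan start (`Inf` = all frames). The irreversible
#'   two-tissue fit defaults to a 4-min window to stay ahead of late
#'   metabolism.
#' @return a list of options.
#' @export
fit_options <- function(prefactor = TRUE,
                        lower = c(K1 = 0, k2 = 0, k3 = 0, V_LV = 0, V_RV = 0),
                        upper = c(K1 = 6, k2 = 8, k3 = 8, V_LV = 1, V_RV = 1),
                        k2_starts = c(0.2, 0.6, 1.5, 3),
                        n_sub = 8L, window_s = Inf) {
  list(prefactor = prefactor, lower = lower, upper = upper,
       k2_starts = k2_starts, n_sub = n_sub, window_s = window_s)
}

# Frame weights: duration * physical decay survival at frame mid-time,
# normalized to mean 1. Without a tracer, duration-only weights.
frame_weights <- function(schedule, tracer = NULL) {
  w <- schedule$duration_s
  if (!is.null(tracer)) w <- w * decay_survival(tracer, frame_mid(schedule))
  w / mean(w)
}

fit_result <- function(model, estimates, se, wrss, converged, diagnostics,
                       conventions = list(), params = NULL) {
  structure(list(model = model, estimates = estimates, params = params,
                 se = se, wrss = wrss, converged = converged,
                 diagnostics = diagnostics, conventions = conventions),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model %s, wrss %.4g, %s\n", x$model, x$wrss,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$estimates, 4))
  invisible(x)
}

# Shared bounded LM driver with multi-start. `model_fun(par)` returns model
# frame values; `starts` is a list of named start vectors.
run_lm_multistart <- function(y, w, model_fun, starts, lower, upper) {
  sw <- sqrt(w)
  resid_fun <- function(par) sw * (model_fun(par) - y)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(NULL)
  best
}

# Model-based heteroscedastic covariance for a weighted LS fit. Frame
# noise follows counting statistics on decay-corrected values:
# var_i = phi * m_i / w_i (m_i = model value, w_i = duration * decay
# weight), with the single scale phi estimated from the residuals. The
# covariance is the sandwich (J'WJ)^-1 (J'W diag(var) WJ) (J'WJ)^-1 under
# that variance model; a classical sigma^2 (J'WJ)^-1 would under-report
# because the weights deliberately ignore the value-dependence.
sandwich_cov <- function(J, r, w, m) {
  n <- length(r); p <- ncol(J)
  if (n <= p) return(NULL)
  A <- crossprod(J * sqrt(w))
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ai)) return(NULL)
  v <- pmax(m, 0.02 * max(m)) / w       # variance shape per frame
  phi <- sum(r^2 / v) / (n - p)
  meat <- crossprod(J * sqrt(phi * v * w^2))
  Ai %*% meat %*% Ai
}

# Numerical Jacobian of model_fun at par (central differences)
num_jacobian <- function(model_fun, par) {
  p <- length(par)
  f0 <- model_fun(par)
  J <- matrix(0, length(f0), p)
  for (j in seq_len(p)) {
    h <- max(1e-6, 1e-6 * abs(par[j]))
    up <- par; up[j] <- par[j] + h
    dn <- par; dn[j] <- max(par[j] - h, 0)
    J[, j] <- (model_fun(up) - model_fun(dn)) / (up[j] - dn[j])
  }
  J
}

robust_se <- function(model_fun, par, y, w) {
  J <- num_jacobian(model_fun, par)
  m <- model_fun(par)
  cv <- sandwich_cov(J, y - m, w, m)
  se <- if (is.null(cv)) rep(NA_real_, length(par))
        else sqrt(pmax(diag(cv), 0))
  names(se) <- names(par)
  se
}

restrict_window <- function(pet_curve, window_s) {
  if (!is.finite(window_s)) return(pet_curve)
  keep <- frame_end(pet_curve$schedule) <= window_s + 1e-9
  if (sum(keep) < 2L)
    stop_validate("fit window of %g s leaves fewer than 2 frames", window_s)
  sch <- frame_schedule(pet_curve$schedule$duration_s[keep],
                        pet_curve$schedule$start_s[keep])
  tac(sch, pet_curve$values[keep], pet_curve$decay_corrected)
}

#' Fit the one-tissue compartment model
#'
#' Weighted bounded least squares over `(K1, k2, V_LV, V_RV)` against a
#' measured myocardial time-activity curve, with a fixed multi-start grid
#' over k2. The model is evaluated frame-averaged over the curve's
#' schedule. Non-convergence is flagged in the result, not thrown.
#'
#' @param pet_curve measured myocardial [tac()] (at least 8 frames).
#' @param C_A,C_RV blood curves ([plin_curve()] or [tac()]).
#' @param init optional named start values `(K1, k2, V_LV, V_RV)`.
#' @param tracer optional [tracer_spec()]; adds decay-survival weighting.
#' @param options a [fit_options()] list.
#' @return a `fit_result` with `estimates`, standard errors `se`, weighted
#'   residual sum `wrss`, and diagnostics.
#' @export
fit_1tc <- function(pet_curve, C_A, C_RV, init = NULL, tracer = NULL,
                    options = fit_options()) {
  stopifnot(inherits(pet_curve, "tac"))
  pet_curve <- restrict_window(pet_curve, options$window_s)
  n <- nrow(pet_curve$schedule)
  if (n < 8L) stop_validate("need at least 8 frames, got %d", n)
  ca <- as_plin(C_A); crv <- as_plin(C_RV)
  sch <- pet_curve$schedule
  w <- frame_weights(sch, tracer)
  pn <- c("K1", "k2", "V_LV", "V_RV")
  model_fun <- function(par) {
    tissue <- (par[["K1"]] / 60) *
      conv_exp_plin_frames(ca, par[["k2"]] / 60, sch, options$n_sub)
    blood_mix(tissue, frame_average_plin(ca, sch),
              frame_average_plin(crv, sch),
              par[["V_LV"]], par[["V_RV"]], options$prefactor)
  }
  starts <- if (!is.null(init)) list(init[pn]) else
    lapply(options$k2_starts, function(g)
      c(K1 = max(0.3, 0.5 * g), k2 = g, V_LV = 0.3, V_RV = 0.1))
  fit <- run_lm_multistart(pet_curve$values, w, model_fun, starts,
                           options$lower[pn], options$upper[pn])
  if (is.null(fit))
    return(fit_result("1tc", stats::setNames(rep(NA_real_, 4), pn),
                      stats::setNames(rep(NA_real_, 4), pn), Inf, FALSE,
                      list(message = "all starts failed"),
                      list(prefactor = options$prefactor)))
  est <- fit$par
  params <- tryCatch(one_tissue_params(est[["K1"]], est[["k2"]],
                                       est[["V_LV"]], est[["V_RV"]]),
                     error = function(e) NULL)
  fit_result("1tc", est, robust_se(model_fun, est, pet_curve$values, w),
             fit$deviance,
             fit$info %in% 1:3,
             list(info = fit$info, message = fit$message,
                  niter = fit$niter),
             list(prefactor = options$prefactor), params)
}

# Frame-averaged exponential convolution of a piecewise-linear input:
# Simpson within frames on the instantaneous convolution.
conv_exp_plin_frames <- function(curve, k_s, schedule, n_sub = 8L) {
  frame_average_fun(function(tt) conv_exp_plin(curve, k_s, tt),
                    schedule, n_sub)
}

#' Fit the irreversible two-tissue compartment model
#'
#' As [fit_1tc()] but over `(K1, k2, k3, V_LV, V_RV)`. By default the fit
#' is restricted to the first 4 minutes of the acquisition, ahead of late
#' tracer metabolism; pass `options = fit_options(window_s = Inf)` for the
#' full window.
#'
#' @inheritParams fit_1tc
#' @return a `fit_result`.
#' @export
fit_2tc_irr <- function(pet_curve, C_A, C_RV, init = NULL, tracer = NULL,
                        options = fit_options(window_s = 240)) {
  stopifnot(inherits(pet_curve, "tac"))
  pet_curve <- restrict_window(pet_curve, options$window_s)
  n <- nrow(pet_curve$schedule)
  if (n < 8L) stop_validate("need at least 8 frames, got %d", n)
  ca <- as_plin(C_A); crv <- as_plin(C_RV)
  sch <- pet_curve$schedule
  w <- frame_weights(sch, tracer)
  pn <- c("K1", "k2", "k3", "V_LV", "V_RV")
  ca_bar <- frame_average_plin(ca, sch)
  crv_bar <- frame_average_plin(crv, sch)
  model_fun <- function(par) {
    k23 <- par[["k2"]] + par[["k3"]]
    tissue <- if (k23 == 0) {
      (par[["K1"]] / 60) * cumint_frames(ca, sch)
    } else {
      (par[["K1"]] / 60) *
        (par[["k2"]] / k23 *
           conv_exp_plin_frames(ca, k23 / 60, sch, options$n_sub) +
         par[["k3"]] / k23 * cumint_frames(ca, sch))
    }
    blood_mix(tissue, ca_bar, crv_bar, par[["V_LV"]], par[["V_RV"]],
              options$prefactor)
  }
  starts <- if (!is.null(init)) list(init[pn]) else
    lapply(options$k2_starts, function(g)
      c(K1 = max(0.3, 0.5 * g), k2 = g, k3 = 0.1, V_LV = 0.3, V_RV = 0.1))
  fit <- run_lm_multistart(pet_curve$values, w, model_fun, starts,
                           options$lower[pn], options$upper[pn])
  if (is.null(fit))
    return(fit_result("2tc_irr", stats::setNames(rep(NA_real_, 5), pn),
                      stats::setNames(rep(NA_real_, 5), pn), Inf, FALSE,
                      list(message = "all starts failed"),
                      list(prefactor = options$prefactor,
                           window_s = options$window_s)))
  est <- fit$par
  params <- tryCatch(two_tissue_irr_params(est[["K1"]], est[["k2"]],
                                           est[["k3"]], est[["V_LV"]],
                                           est[["V_RV"]]),
                     error = function(e) NULL)
  fit_result("2tc_irr", est,
             robust_se(model_fun, est, pet_curve$values, w),
             fit$deviance, fit$info %in% 1:3,
             list(info = fit$info, message = fit$message,
                  niter = fit$niter),
             list(prefactor = options$prefactor,
                  window_s = options$window_s), params)
}

# Frame averages of the running integral of a piecewise-linear curve
# (exact: second antiderivative differences via Simpson is unnecessary --
# the running integral is piecewise quadratic, Simpson is exact for it).
cumint_frames <- function(curve, sch, n_sub = 8L) {
  frame_average_fun(function(tt) cumint_plin(curve, tt), sch, n_sub)
}

# --- basis-function water fit ----------------------------------------------

#' Basis grid of candidate MBF values
#'
#' @param n number of grid points (>= 20).
#' @param range MBF interval in mL/g/min; must cover at least `[0.2, 6]`.
#' @param log_spaced logical; geometric spacing (default) resolves low
#'   flows better.
#' @return object of class `basis_grid`: numeric vector of MBF values with
#'   range/spacing metadata.
#' @export
basis_grid <- function(n = 30L, range = c(0.2, 6), log_spaced = TRUE) {
  if (n < 20L) stop_invalid("basis grid needs at least 20 points")
  if (range[1] > 0.2 + 1e-9 || range[2] < 6 - 1e-9)
    stop_invalid("basis grid must span at least [0.2, 6] mL/g/min")
  mbf <- if (log_spaced) exp(seq(log(range[1]), log(range[2]),
                                 length.out = n))
         else seq(range[1], range[2], length.out = n)
  structure(mbf, class = "basis_grid", range = range,
            spacing = if (log_spaced) "log" else "linear")
}

# Exact weighted nonnegative least squares for up to 3 columns by active-set
# enumeration: try every subset of free columns, keep the feasible solution
# with smallest weighted residual sum. Returns list(coef, wrss).
nnls_small <- function(X, y, w) {
  p <- ncol(X)
  sw <- sqrt(w)
  Xw <- X * sw; yw <- y * sw
  best <- list(coef = rep(0, p), wrss = sum(yw^2))
  subsets <- lapply(seq_len(2^p - 1), function(m) which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0))
  for (S in subsets) {
    cf <- tryCatch(qr.coef(qr(Xw[, S, drop = FALSE]), yw),
                   error = function(e) NULL)
    if (is.null(cf) || any(is.na(cf)) || any(cf < -1e-12)) next
    full <- rep(0, p); full[S] <- pmax(cf, 0)
    r <- yw - Xw %*% full
    wrss <- sum(r^2)
    if (wrss < best$wrss - 1e-15) best <- list(coef = full, wrss = wrss)
  }
  best
}

# Precompute everything the basis fit needs for one (C_A, C_RV, schedule):
# frame-averaged blood regressors and one basis column per grid MBF.
water_basis_prepare <- function(C_A, C_RV, schedule, grid = basis_grid(),
                                tracer = NULL, n_sub = 8L,
                                partition_coefficient = 0.91) {
  ca <- as_plin(C_A); crv <- as_plin(C_RV)
  basis <- vapply(as.numeric(grid), function(mbf)
    conv_exp_plin_frames(ca, mbf / partition_coefficient / 60, schedule,
                         n_sub) / 60,
    numeric(nrow(schedule)))
  list(grid = as.numeric(grid), basis = basis,
       ca_bar = frame_average_plin(ca, schedule),
       crv_bar = frame_average_plin(crv, schedule),
       w = frame_weights(schedule, tracer),
       ca = ca, schedule = schedule, n_sub = n_sub,
       partition_coefficient = partition_coefficient)
}

# Basis column for an arbitrary (off-grid) MBF
water_basis_column <- function(prep, mbf) {
  conv_exp_plin_frames(prep$ca, mbf / prep$partition_coefficient / 60,
                       prep$schedule, prep$n_sub) / 60
}

# Core solver: for given frame values, scan the grid, refine, return
# estimates. Used by both fit_water_basis and fit_parametric_map.
water_basis_solve <- function(values, prep) {
  ng <- length(prep$grid)
  wrss <- numeric(ng)
  sols <- vector("list", ng)
  for (i in seq_len(ng)) {
    X <- cbind(prep$basis[, i], prep$ca_bar, prep$crv_bar)
    sols[[i]] <- nnls_small(X, values, prep$w)
    wrss[i] <- sols[[i]]$wrss
  }
  # smallest MBF among (numerically) equal minima
  i0 <- which(wrss <= min(wrss) * (1 + 1e-12))[1]
  solve_at <- function(mbf) {
    X <- cbind(water_basis_column(prep, mbf), prep$ca_bar, prep$crv_bar)
    nnls_small(X, values, prep$w)
  }
  mbf_hat <- prep$grid[i0]
  sol <- sols[[i0]]
  if (i0 > 1L && i0 < ng) {
    # parabolic interpolation of wrss on log(MBF), then a bounded polish
    lx <- log(prep$grid[(i0 - 1):(i0 + 1)])
    fy <- wrss[(i0 - 1):(i0 + 1)]
    dd <- (fy[3] - 2 * fy[2] + fy[1])
    if (dd > 0) {
      xv <- lx[2] - 0.5 * (lx[3] - lx[1]) / 2 * (fy[3] - fy[1]) / dd
      xv <- min(max(xv, lx[1]), lx[3])
      mbf_hat <- exp(xv)
    }
    opt <- stats::optimize(function(m) solve_at(m)$wrss,
                           interval = c(prep$grid[i0 - 1],
                                        prep$grid[i0 + 1]),
                           tol = 1e-5)
    if (opt$objective < wrss[i0]) mbf_hat <- opt$minimum
    sol <- solve_at(mbf_hat)
    if (sol$wrss > wrss[i0]) { mbf_hat <- prep$grid[i0]; sol <- sols[[i0]] }
  }
  theta <- sol$coef
  list(MBF = mbf_hat,
       PTF = if (mbf_hat > 0) theta[1] / mbf_hat else 0,
       V_LV = theta[2], V_RV = theta[3], wrss = sol$wrss,
       grid_index = i0, grid_wrss = wrss)
}

#' Basis-function fit of the water perfusion model
#'
#' For each candidate MBF on a [basis_grid()], the model is linear in
#' `(PTF * MBF, V_LV, V_RV)`; that sub-problem is solved by weighted
#' non-negative least squares, and the grid point minimizing the weighted
#' residual sum (refined locally between its neighbours) is returned. Ties
#' resolve to the smallest MBF. This is the fast path used for parametric
#' imaging.
#'
#' @inheritParams fit_1tc
#' @param grid a [basis_grid()].
#' @return a `fit_result` with estimates `(MBF, PTF, V_LV, V_RV)`. An
#'   all-zero input curve is flagged unidentifiable in the diagnostics.
#' @export
fit_water_basis <- function(pet_curve, C_A, C_RV, grid = basis_grid(),
                            tracer = NULL, options = fit_options()) {
  stopifnot(inherits(pet_curve, "tac"), inherits(grid, "basis_grid"))
  prep <- water_basis_prepare(C_A, C_RV, pet_curve$schedule, grid, tracer,
                              options$n_sub)
  pn <- c("MBF", "PTF", "V_LV", "V_RV")
  if (all(pet_curve$values == 0))
    return(fit_result("water_basis",
                      stats::setNames(c(0, 0, 0, 0), pn),
                      stats::setNames(rep(NA_real_, 4), pn), 0, TRUE,
                      list(unidentifiable = TRUE),
                      list(ptf_absorbs_blood_fraction = TRUE)))
  sol <- water_basis_solve(pet_curve$values, prep)
  est <- stats::setNames(c(sol$MBF, sol$PTF, sol$V_LV, sol$V_RV), pn)
  # Joint sandwich SEs of the full nonlinear model in (MBF, PTF*MBF, V_LV,
  # V_RV); PTF by the delta method.
  se <- stats::setNames(rep(NA_real_, 4), pn)
  if (length(pet_curve$values) > 4L && sol$MBF > 0) {
    model4 <- function(par)
      par[2] * water_basis_column(prep, par[1]) +
        par[3] * prep$ca_bar + par[4] * prep$crv_bar
    par4 <- c(sol$MBF, sol$PTF * sol$MBF, sol$V_LV, sol$V_RV)
    J <- num_jacobian(model4, par4)
    m4 <- model4(par4)
    cv <- sandwich_cov(J, pet_curve$values - m4, prep$w, m4)
    if (!is.null(cv)) {
      se[c("MBF", "V_LV", "V_RV")] <- sqrt(pmax(diag(cv)[c(1, 3, 4)], 0))
      g <- c(-par4[2] / par4[1]^2, 1 / par4[1], 0, 0)
      se["PTF"] <- sqrt(max(drop(t(g) %*% cv %*% g), 0))
    }
  }
  params <- tryCatch(water_params(est[["MBF"]], est[["PTF"]],
                                  est[["V_LV"]], est[["V_RV"]]),
                     error = function(e) NULL)
  fit_result("water_basis", est, se, sol$wrss, TRUE,
             list(grid_index = sol$grid_index, unidentifiable = FALSE),
             list(ptf_absorbs_blood_fraction = TRUE), params)
}

#' Voxel-wise parametric maps from a dynamic volume
#'
#' Applies the basis-function water fit to every voxel of a 4-D dynamic
#' volume (x, y, z, frame). Voxels whose peak value is below
#' `mask_threshold` are not fitted and carry the sentinel `NA` in all
#' output maps.
#'
#' @param dynamic_volume 4-D numeric array, last dimension = frames.
#' @param C_A,C_RV blood curves.
#' @param schedule the common [frame_schedule()] of all voxels.
#' @param grid a [basis_grid()].
#' @param mask_threshold activity threshold (kBq/mL) on the voxel peak.
#' @param tracer optional [tracer_spec()] for weighting.
#' @return list of 3-D arrays `MBF`, `PTF`, `V_LV`, `V_RV` plus the logical
#'   `mask`, all carrying the input geometry.
#' @export
fit_parametric_map <- function(dynamic_volume, C_A, C_RV, schedule,
                               grid = basis_grid(), mask_threshold = 1,
                               tracer = NULL) {
  d <- dim(dynamic_volume)
  if (length(d) != 4L)
    stop_validate("dynamic_volume must be a 4-D array (x, y, z, frame)")
  if (d[4] != nrow(schedule))
    stop_validate("volume has %d frames but schedule has %d", d[4],
                  nrow(schedule))
  prep <- water_basis_prepare(C_A, C_RV, schedule, grid, tracer)
  nxyz <- prod(d[1:3])
  vmat <- matrix(dynamic_volume, nrow = nxyz, ncol = d[4])
  mask <- apply(vmat, 1L, max) >= mask_threshold
  out <- matrix(NA_real_, nrow = nxyz, ncol = 4)
  idx <- which(mask)
  for (v in idx) {
    sol <- water_basis_solve(vmat[v, ], prep)
    out[v, ] <- c(sol$MBF, sol$PTF, sol$V_LV, sol$V_RV)
  }
  shape <- function(col) array(col, dim = d[1:3])
  list(MBF = shape(out[, 1]), PTF = shape(out[, 2]),
       V_LV = shape(out[, 3]), V_RV = shape(out[, 4]),
       mask = array(mask, dim = d[1:3]))
}

# --- retention estimator ---------------------------------------------------

#' Retention-model estimate of the net uptake rate Ki
#'
#' Divides the late-window tissue signal by the cumulative arterial input
#' integral: `Ki = C_PET(window) / int_0^tmid C_A(tau) dtau`, with
#' trapezoidal integration on the frame grid. The tissue value is the
#' duration-weighted mean over frames whose mid-times fall in the window,
#' optionally blood-corrected by subtracting `V_LV * C_A`.
#'
#' @param pet_curve myocardial [tac()].
#' @param C_A arterial input ([tac()] or [plin_curve()]).
#' @param window `(t0_s, t1_s)` late-uptake window (within the schedule).
#' @param blood_correction optional list with element `V_LV`: subtract
#'   `V_LV * C_A` from the tissue signal before dividing.
#' @return a [retention_params()].
#' @export
retention_ki <- function(pet_curve, C_A, window = NULL,
                         blood_correction = NULL) {
  stopifnot(inherits(pet_curve, "tac"))
  sch <- pet_curve$schedule
  total <- schedule_total(sch)
  if (is.null(window)) window <- c(min(90, total / 2), total)
  if (window[1] < 0 || window[2] > total + 1e-9 || window[2] <= window[1])
    stop_domain("retention window [%g, %g] not within schedule [0, %g]",
                window[1], window[2], total)
  mids <- frame_mid(sch)
  sel <- mids >= window[1] & mids <= window[2]
  if (!any(sel)) stop_domain("no frames inside the retention window")
  w <- sch$duration_s[sel]
  tissue <- pet_curve$values[sel]
  ca <- as_plin(C_A)
  if (!is.null(blood_correction)) {
    vlv <- blood_correction$V_LV
    assert_scalar_num(vlv, "V_LV", 0, 1)
    ca_bar <- frame_average_plin(ca, sch)[sel]
    tissue <- tissue - vlv * ca_bar
  }
  tissue_mean <- sum(w * tissue) / sum(w)
  t_mid <- mean(window)
  integral <- cumint_plin(ca, t_mid)  # kBq/mL * s
  if (integral <= 0)
    stop_domain("cumulative input integral is zero over [0, %g]", t_mid)
  ki <- tissue_mean / (integral / 60)
  retention_params(max(ki, 0), window)
}

# --- residual-activity correction ------------------------------------------

#' Correct a stress curve for residual rest activity
#'
#' Inverse of the shortened-protocol contamination: the rest curve's late
#' phase is extrapolated mono-exponentially and its physically decayed
#' continuation (`2^(-interval_s / T1/2)` in the stress decay-corrected
#' frame of reference) is subtracted from the stress curve. Negative
#' results are floored at zero and flagged.
#'
#' @param stress_curve,rest_curve [tac()]s on the same schedule.
#' @param interval_s time between rest and stress injections.
#' @param tracer a [tracer_spec()] or tracer name.
#' @return the corrected stress [tac()], with attribute `floored` (logical
#'   per frame) when any frame was clipped.
#' @export
correct_residual <- function(stress_curve, rest_curve, interval_s, tracer) {
  stopifnot(inherits(stress_curve, "tac"), inherits(rest_curve, "tac"))
  if (is.character(tracer)) tracer <- tracer_spec(tracer)
  if (!isTRUE(all.equal(stress_curve$schedule, rest_curve$schedule)))
    stop_validate("stress and rest curves are on different schedules")
  if (!is.numeric(interval_s) || length(interval_s) != 1L ||
      is.na(interval_s) || interval_s < 0)
    stop_invalid("interval_s must be a single number >= 0 (Inf allowed)")
  extrap <- tail_extrapolate(rest_curve)
  mids <- frame_mid(stress_curve$schedule)
  cont <- decay_survival(tracer, interval_s) * extrap(interval_s + mids)
  corrected <- stress_curve$values - cont
  floored <- corrected < 0
  if (any(floored)) {
    warning("residual correction floored ", sum(floored),
            " frame(s) at zero")
    corrected[floored] <- 0
  }
  out <- tac(stress_curve$schedule, corrected, stress_curve$decay_corrected)
  attr(out, "floored") <- floored
  out
}
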