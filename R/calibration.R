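#' Behavioral observables of a drug-free channel model
#'
#' Computes the quantities against which the channel parameters are
#' calibrated, using the same protocol engine and fits as the rest of the
#' package: the fast and slow recovery time constants from a biexponential
#' fit to the recovery (`Rec_t`) curve; the fast- and slow-inactivated
#' fractions after 5 s at -20 mV; the percentage of fast-inactivated
#' channels recovering during the 10 ms / -150 mV gap; the slow-inactivated
#' fraction at the end of 0.1 s and 2 s pre-pulses at the most depolarized
#' voltage of the fast-inactivation protocol (-30 mV); the midpoint shift
#' of the fast-inactivation availability curve between 0.1 s and 2 s
#' pre-pulses; and the difference between the equilibrium midpoints of fast
#' and slow inactivation (closed form from the gate rate laws).
#'
#' @param model A drug-free tetracube `channel_model`.
#' @param points_per_decade,voltage_step Protocol grid density.
#' @return A named list of observables (`tau_fast_ms`, `tau_slow_ms`,
#'   `fast_frac_5s_pct`, `slow_frac_5s_pct`, `gap_recovery_pct`,
#'   `slow_frac_100ms_pct`, `slow_frac_2s_pct`, `dvhalf_finact_mV`,
#'   `vhalf_fast_minus_slow_mV`).
#' @export
behavioral_observables <- function(model, points_per_decade = 8,
                                   voltage_step = 5) {
  st <- model$states
  fast_inact <- !st$fast_open & st$slow_open
  slow_inact <- !st$slow_open
  Qh <- assemble_rate_matrix(model, voltage = -150)
  Q20 <- assemble_rate_matrix(model, voltage = -20)
  Q30 <- assemble_rate_matrix(model, voltage = -30)
  eq <- equilibrium(Qh)

  rec <- run_sweep(model, standard_protocol(
    "Rec_t", points_per_decade = points_per_decade))
  bi <- fit_biexponential(rec, condition = "control")

  occ5 <- solve_oracle(Q20, 5, eq)
  occ_c <- solve_oracle(Q20, 0.1, eq)
  f0 <- sum(occ_c[!st$fast_open])
  occ_g <- solve_oracle(Qh, 0.01, occ_c)
  f1 <- sum(occ_g[!st$fast_open])

  occ01 <- solve_oracle(Q30, 0.1, eq)
  occ2 <- solve_oracle(Q30, 2, eq)

  fit_v <- function(dur) {
    sw <- run_sweep(model, standard_protocol(
      "FInact_V", pre_duration = dur, voltage_step = voltage_step))
    fit_boltzmann(sw, condition = "control")
  }
  v01 <- fit_v(0.1)
  v2 <- fit_v(2)

  gates <- model$params$gates
  list(
    tau_fast_ms = 1e3 * bi$tau_fast,
    tau_slow_ms = 1e3 * bi$tau_slow,
    fast_frac_5s_pct = 100 * sum(occ5[fast_inact]),
    slow_frac_5s_pct = 100 * sum(occ5[slow_inact]),
    gap_recovery_pct = 100 * (f0 - f1) / f0,
    slow_frac_100ms_pct = 100 * sum(occ01[slow_inact]),
    slow_frac_2s_pct = 100 * sum(occ2[slow_inact]),
    dvhalf_finact_mV = abs(v2$Vhalf - v01$Vhalf),
    vhalf_fast_minus_slow_mV =
      gate_vhalf(gates$fast_inactivation) -
      gate_vhalf(gates$slow_inactivation))
}

#' Behavioral constraint set for channel calibration
#'
#' The eight constraints the shipped default parameters satisfy: recovery
#' time constants of 2.21 ms and 58.25 ms; at least 95% recovery from fast
#' inactivation within the 10 ms / -150 mV gap; slow-inactivated fractions
#' of about 5% after 0.1 s and 40% after 2 s of depolarization; a
#' fast-inactivation midpoint shift of less than 4 mV between 0.1 s and 2 s
#' pre-pulses; about 45% fast-inactivated channels after 5 s at -20 mV
#' (with the complementary ~55% slow-inactivated); and a fast-inactivation
#' equilibrium midpoint more negative than the slow one. Tolerances are
#' deliberately generous (20% relative on time constants and fractions,
#' +/- 2 percentage points on the smallest fraction) because the targets
#' are approximate behavioral values, not exact measurements.
#'
#' @return A tibble with columns `observable`, `target`, `tolerance`,
#'   `weight`, `cmp` (`"eq"`, `"ge"`, `"le"`).
#' @export
default_constraints <- function() {
  tibble::tribble(
    ~observable,                 ~target, ~tolerance, ~weight, ~cmp,
    "tau_fast_ms",                  2.21,      0.442,       6, "eq",
    "tau_slow_ms",                 58.25,      11.65,       6, "eq",
    "gap_recovery_pct",               95,          1,       1, "ge",
    "slow_frac_100ms_pct",             5,          2,       2, "eq",
    "slow_frac_2s_pct",               40,          8,       2, "eq",
    "dvhalf_finact_mV",                4,        0.5,       1, "le",
    "fast_frac_5s_pct",               45,         10,       2, "eq",
    "vhalf_fast_minus_slow_mV",        0,          2,       1, "le")
}

constraint_residuals <- function(obs, constraints) {
  v <- unlist(obs[constraints$observable])
  r <- numeric(nrow(constraints))
  for (i in seq_len(nrow(constraints))) {
    tgt <- constraints$target[i]; tol <- constraints$tolerance[i]
    r[i] <- switch(constraints$cmp[i],
                   eq = (v[i] - tgt) / tol,
                   ge = max(0, (tgt - v[i]) / tol),
                   le = max(0, (v[i] - tgt) / tol))
  }
  tibble(observable = constraints$observable, value = unname(v),
         target = constraints$target, tolerance = constraints$tolerance,
         cmp = constraints$cmp, residual = r,
         pass = ifelse(constraints$cmp == "eq", abs(r) <= 1,
                       r <= 0))
}

calibration_objective <- function(params, constraints, ...) {
  obs <- tryCatch(
    behavioral_observables(tetracube_model(params = params), ...),
    error = function(e) NULL)
  if (is.null(obs) || any(!is.finite(unlist(obs)))) return(1e6)
  d <- constraint_residuals(obs, constraints)
  sum(constraints$weight * d$residual^2)
}

#' Analytic starting point for calibration
#'
#' Because the three gates are independent, each behavioral constraint maps
#' almost directly onto one gate's two-state kinetics: the limiting opening
#' rates of the inactivation gates are fixed by the recovery time constants
#' at the gap potential, and the closing laws of the slow gate by the onset
#' time course and equilibrium at the conditioning potentials. The
#' activation gate only needs to be fast relative to inactivation and
#' mostly open at the test potential. The returned set satisfies most
#' constraints outright and is polished by [calibrate()].
#'
#' @param constraints A constraint tibble, see [default_constraints()].
#' @return Named list of the 18 tetracube parameters.
#' @export
init_from_constraints <- function(constraints = default_constraints()) {
  tget <- function(nm, default) {
    i <- match(nm, constraints$observable)
    if (is.na(i)) default else constraints$target[i]
  }
  tau_f <- tget("tau_fast_ms", 2.21) * 1e-3
  tau_s <- tget("tau_slow_ms", 58.25) * 1e-3
  # opening (recovery) laws saturate at hyperpolarized potentials, so the
  # limiting rate is set by the recovery time constant at the -150 mV gap
  A_fo <- (1 / tau_f) / (1 / (1 + exp((-150 + 80) / 14)))
  A_so <- (1 / tau_s) / (1 / (1 + exp((-150 + 69) / 12)))
  list(
    act_open_A = 10000, act_open_Vhalf = -35, act_open_r = 9,
    act_close_A = 5000, act_close_Vhalf = -60, act_close_r = 12,
    fast_open_A = A_fo, fast_open_Vhalf = -80, fast_open_r = 14,
    fast_close_A = 1200, fast_close_Vhalf = -55, fast_close_r = 8,
    slow_open_A = A_so, slow_open_Vhalf = -69, slow_open_r = 12,
    slow_close_A = 0.42, slow_close_Vhalf = -52, slow_close_r = 9)
}

#' Search box for calibration
#'
#' Physiological bounds around a reference parameter set: limiting rates
#' within a factor of `A_factor`, slope factors within a factor of
#' `r_factor` (a Boltzmann slope of a fraction of a mV would satisfy
#' constraints numerically but is not channel-like), midpoint voltages
#' within `vhalf_pad` mV.
#'
#' @param reference Named 18-parameter list.
#' @param A_factor,r_factor,vhalf_pad Half-ranges per parameter class.
#' @return Tibble with columns `name`, `low`, `high`.
#' @export
parameter_bounds <- function(reference, A_factor = 20, r_factor = 3,
                             vhalf_pad = 20) {
  reference <- tetracube_params(reference)
  nm <- names(reference)
  x <- unlist(reference)
  is_v <- grepl("Vhalf", nm)
  is_r <- grepl("_r$", nm)
  fac <- ifelse(is_r, r_factor, A_factor)
  tibble(name = nm,
         low = ifelse(is_v, x - vhalf_pad, x / fac),
         high = ifelse(is_v, x + vhalf_pad, x * fac))
}

#' Calibrate channel parameters against behavioral constraints
#'
#' Weighted least-squares optimization of the 18 tetracube parameters
#' against a behavioral constraint set. Residuals are measured in units of
#' each constraint's tolerance (relative for rates and fractions, absolute
#' in mV for voltages); inequality constraints contribute one-sided hinge
#' penalties. The search runs Nelder-Mead polishing from a
#' constraint-derived analytic start plus seeded multiplicative
#' perturbations (rates on the log scale, midpoint voltages linearly); if
#' the starting set already satisfies every constraint it is returned
#' unchanged. If no parameter set within tolerance is found within the
#' budget, the best set found is returned flagged infeasible.
#'
#' @param constraints Constraint tibble, see [default_constraints()].
#' @param start Starting parameter set; default [init_from_constraints()].
#' @param bounds Search box, see [parameter_bounds()]; keeps the search
#'   inside a physiologically sensible region (slope factors of fractions
#'   of a mV, say, satisfy the constraints numerically but describe no real
#'   channel). Excursions outside the box are clamped and penalized.
#' @param seed RNG seed for the start perturbations.
#' @param n_starts Number of optimization starts.
#' @param maxit Nelder-Mead iteration budget per start.
#' @param points_per_decade,voltage_step Protocol grid density used in the
#'   objective (matching the density used to evaluate the result).
#' @param polish Keep optimizing even when the start already satisfies
#'   every constraint (drives the equality residuals toward zero instead of
#'   returning the passing start unchanged).
#' @return Object of class `calibration`: `params`, `diagnostics` (one row
#'   per constraint with value, residual and pass flag), `objective`,
#'   `feasible`.
#' @export
calibrate <- function(constraints = default_constraints(), start = NULL,
                      bounds = NULL, seed = 1, n_starts = 3, maxit = 400,
                      points_per_decade = 8, voltage_step = 5,
                      polish = FALSE) {
  start <- start %||% init_from_constraints(constraints)
  start <- tetracube_params(start)
  bounds <- bounds %||% parameter_bounds(start)
  nms <- names(start)
  is_v <- grepl("Vhalf", nms)
  to_theta <- function(p) {
    x <- unlist(p)
    x[!is_v] <- log(x[!is_v])
    x
  }
  from_theta <- function(th) {
    x <- ifelse(is_v, th, exp(th))
    stats::setNames(as.list(x), nms)
  }
  b <- bounds[match(nms, bounds$name), ]
  lo <- to_theta(stats::setNames(as.list(b$low), nms))
  hi <- to_theta(stats::setNames(as.list(b$high), nms))
  obj <- function(th) {
    pen <- 100 * sum(pmax(0, th - hi)^2 + pmax(0, lo - th)^2)
    th <- pmin(pmax(th, lo), hi)
    calibration_objective(from_theta(th), constraints,
                          points_per_decade = points_per_decade,
                          voltage_step = voltage_step) + pen
  }

  d0 <- constraint_residuals(
    behavioral_observables(tetracube_model(params = start),
                           points_per_decade = points_per_decade,
                           voltage_step = voltage_step), constraints)
  if (all(d0$pass) && !polish) {
    return(structure(list(params = start, diagnostics = d0,
                          objective = sum(constraints$weight * d0$residual^2),
                          feasible = TRUE),
                     class = "calibration"))
  }

  set.seed(seed)
  th0 <- to_theta(start)
  best <- list(theta = th0, value = obj(th0))
  for (k in seq_len(n_starts)) {
    th_start <- if (k == 1) th0 else
      th0 + stats::rnorm(length(th0), sd = ifelse(is_v, 3, 0.15))
    fit <- stats::optim(th_start, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (fit$value < best$value) best <- list(theta = fit$par,
                                             value = fit$value)
  }
  params <- from_theta(pmin(pmax(best$theta, lo), hi))
  diag <- constraint_residuals(
    behavioral_observables(tetracube_model(params = params),
                           points_per_decade = points_per_decade,
                           voltage_step = voltage_step), constraints)
  structure(list(params = params, diagnostics = diag,
                 objective = best$value, feasible = all(diag$pass)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> objective %.4g, %s\n", x$objective,
              if (x$feasible) "all constraints satisfied"
              else "INFEASIBLE: best set found"))
  print(x$diagnostics)
  invisible(x)
}
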