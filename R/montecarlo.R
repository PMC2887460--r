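#' Sampling constraints for random channel parameters
#'
#' Bounds for the 18 tetracube parameters used by the Monte Carlo
#' robustness study. Midpoint voltages are sampled linearly within
#' `vhalf_pad` mV of the reference set; limiting rates `A` and slope
#' factors `r` are sampled logarithmically within a factor of `rate_factor`
#' of the reference. These bounds are a reconstruction bracketing the
#' calibrated set and are fully adjustable.
#'
#' @param reference Named parameter list to bracket (default: the shipped
#'   calibrated set).
#' @param vhalf_pad Half-width of the linear `Vhalf` bounds, mV.
#' @param rate_factor Multiplicative half-range of the log-sampled `A` and
#'   `r` bounds.
#' @return A tibble with columns `name`, `low`, `high`, `scale`
#'   (`"linear"` or `"log"`).
#' @export
parameter_constraints <- function(reference = default_tetracube_params(),
                                  vhalf_pad = 30, rate_factor = 30) {
  reference <- tetracube_params(reference)
  nm <- names(reference)
  x <- unlist(reference)
  is_v <- grepl("Vhalf", nm)
  tibble(name = nm,
         low = ifelse(is_v, x - vhalf_pad, x / rate_factor),
         high = ifelse(is_v, x + vhalf_pad, x * rate_factor),
         scale = ifelse(is_v, "linear", "log"))
}

#' Draw one random channel parameter set
#'
#' Uniform random numbers in `[0, 1]` are transformed linearly (midpoint
#' voltages) or logarithmically (limiting rates and slope factors) onto the
#' constraint bounds. Setting the seed makes each draw independently
#' reproducible.
#'
#' @param constraints Tibble from [parameter_constraints()].
#' @param seed Optional integer; when given, the RNG is seeded before the
#'   draw.
#' @return Named list of parameters within bounds.
#' @export
random_model <- function(constraints, seed = NULL) {
  stopifnot(all(constraints$low < constraints$high))
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(nrow(constraints))
  val <- constraints$low + u * (constraints$high - constraints$low)
  lg <- constraints$scale == "log"
  val[lg] <- exp(log(constraints$low[lg]) +
                   u[lg] * (log(constraints$high[lg]) -
                              log(constraints$low[lg])))
  stats::setNames(as.list(val), constraints$name)
}

# per-gate two-state relaxation, closed form (gates are independent)
gate_open_after <- function(gate, voltage, t, p0) {
  a <- rate_law_eval(gate$opening, voltage)
  b <- rate_law_eval(gate$closing, voltage)
  pinf <- a / (a + b)
  pinf + (p0 - pinf) * exp(-(a + b) * t)
}

# validity screen for a random parameter set: availability must survive a
# 0.1 s pre-pulse at -120 mV and 10 s at -20 mV must produce measurable
# slow inactivation
screen_random_model <- function(params, holding = -150) {
  gates <- gates_from_params(params)
  f0 <- gate_open_prob(gates$fast_inactivation, holding)
  s0 <- gate_open_prob(gates$slow_inactivation, holding)
  avail120 <-
    gate_open_after(gates$fast_inactivation, -120, 0.1, f0) *
    gate_open_after(gates$slow_inactivation, -120, 0.1, s0)
  slow10s <- 1 - gate_open_after(gates$slow_inactivation, -20, 10, s0)
  if (!is.finite(avail120) || avail120 < 0.5) {
    "abnormal gating: availability < 0.5 at -120 mV"
  } else if (!is.finite(slow10s) || slow10s < 0.05) {
    "no substantial slow inactivation"
  } else {
    NA_character_
  }
}

#' Monte Carlo robustness study of drug effectiveness
#'
#' Generates `n_sets` random channel parameter sets within the sampling
#' constraints, screens out sets with abnormal gating or without
#' substantial slow inactivation, and for every valid set quantifies the
#' four prototypical drugs: the midpoint shift of the steady-state
#' slow-inactivation curve (`SInact_V`) and of the fast-inactivation curve
#' (`FInact_V`) under the slowly-binding fast-inactivated-state drug
#' `FI_sb`, and the normalized sum-of-differences (nSOD) of all four drugs
#' in the onset (`SInact_t`) and recovery (`Rec_t`) protocols. The
#' difference between the equilibrium midpoints of slow and fast
#' inactivation is computed in closed form from the drawn rate laws.
#' Individual model failures are recorded in the `invalid_reason` column
#' and never abort the batch.
#'
#' @param n_sets Number of random parameter sets.
#' @param constraints Sampling bounds, see [parameter_constraints()].
#' @param drugs The four prototype drugs ([prototype_drugs()]).
#' @param seed Study seed; per-record seeds are fanned out from it so each
#'   record is independently reproducible.
#' @param points_per_decade,voltage_step Protocol grid density.
#' @return A list of class `mc_study`: `records` (one tibble row per set)
#'   and `summary` (valid count, most-effective-drug tallies for both
#'   protocols, fraction of sets with a `SInact_V` shift beyond -5 mV).
#' @export
run_mc_study <- function(n_sets,
                         constraints = parameter_constraints(),
                         drugs = prototype_drugs(),
                         seed = 1,
                         points_per_decade = 6,
                         voltage_step = 5) {
  stopifnot(n_sets >= 1)
  drug_names <- names(drugs)
  record_seed <- function(i) {
    as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
  }
  sv <- standard_protocol("SInact_V", voltage_step = voltage_step)
  fv <- standard_protocol("FInact_V", voltage_step = voltage_step)
  st <- standard_protocol("SInact_t", points_per_decade = points_per_decade)
  rt <- standard_protocol("Rec_t", points_per_decade = points_per_decade)

  records <- purrr::map_dfr(seq_len(n_sets), function(i) {
    params <- random_model(constraints, seed = record_seed(i))
    reason <- screen_random_model(params)
    base <- tibble(set = i, valid = is.na(reason), invalid_reason = reason)
    if (!is.na(reason)) return(base)
    out <- tryCatch({
      model <- tetracube_model(params = params)
      gates <- model$params$gates
      dv_eq <- gate_vhalf(gates$slow_inactivation) -
        gate_vhalf(gates$fast_inactivation)
      shift_of <- function(proto) {
        res <- run_sweep(model, proto, drug = drugs$FI_sb)
        fc <- fit_boltzmann(res, condition = "control")
        fd <- fit_boltzmann(res, condition = "drug")
        if (fc$undefined || fd$undefined) NA_real_ else fd$Vhalf - fc$Vhalf
      }
      ns <- function(proto) {
        vapply(drugs, function(d) nsod(run_sweep(model, proto, drug = d)),
               numeric(1))
      }
      n_on <- ns(st)
      n_rec <- ns(rt)
      dplyr::bind_cols(base, tibble(
        dvhalf_eq_slow_minus_fast = dv_eq,
        shift_sinact_v = shift_of(sv),
        shift_finact_v = shift_of(fv),
        best_onset = drug_names[which.max(n_on)],
        best_recovery = drug_names[which.max(n_rec)],
        !!!stats::setNames(as.list(n_on), paste0("nsod_onset_", drug_names)),
        !!!stats::setNames(as.list(n_rec),
                           paste0("nsod_recovery_", drug_names))))
    }, error = function(e) {
      base$valid <- FALSE
      base$invalid_reason <- paste("simulation failure:",
                                   conditionMessage(e))
      base
    })
    out
  })

  valid <- dplyr::filter(records, .data$valid)
  tally <- function(col) {
    tab <- table(factor(valid[[col]], levels = drug_names))
    stats::setNames(as.integer(tab), names(tab))
  }
  shift <- valid$shift_sinact_v
  summary <- list(
    n_sets = n_sets,
    n_valid = nrow(valid),
    best_onset = tally("best_onset"),
    best_recovery = tally("best_recovery"),
    frac_onset_best_is_FI =
      if (nrow(valid)) mean(grepl("^FI", valid$best_onset)) else NA_real_,
    frac_recovery_best_is_FI_sb =
      if (nrow(valid)) mean(valid$best_recovery == "FI_sb") else NA_real_,
    frac_sinact_shift_beyond_5mV =
      if (any(!is.na(shift))) mean(shift[!is.na(shift)] < -5) else NA_real_)
  structure(list(records = records, summary = summary), class = "mc_study")
}

#' @export
print.mc_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<mc_study> %d sets, %d valid\n", s$n_sets, s$n_valid))
  cat("  most effective, onset  (SInact_t):",
      paste(names(s$best_onset), s$best_onset, collapse = ", "), "\n")
  cat("  most effective, recovery (Rec_t):",
      paste(names(s$best_recovery), s$best_recovery, collapse = ", "), "\n")
  cat(sprintf("  SInact_V shift beyond -5 mV in %.0f%% of valid sets\n",
              100 * s$frac_sinact_shift_beyond_5mV))
  invisible(x)
}
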