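#' Construct a voltage-clamp protocol
#'
#' A protocol is an ordered list of constant-voltage segments preceded by
#' equilibration at a holding potential, with exactly one swept dimension
#' (the voltage or the duration of one segment) and one designated test
#' pulse whose peak conducting occupancy is the availability readout.
#'
#' @param name Protocol label.
#' @param holding Holding potential for pre-protocol equilibration, mV.
#' @param segments Tibble/data frame with columns `voltage` (mV) and
#'   `duration` (s).
#' @param sweep List with elements `segment` (index into `segments`),
#'   `field` (`"voltage"` or `"duration"`) and `values` (strictly monotone
#'   grid).
#' @param test_index Index of the test-pulse segment; must come after the
#'   swept segment.
#' @return An object of class `protocol`.
#' @export
protocol <- function(name, holding, segments, sweep, test_index) {
  segments <- as_tibble(segments)
  stopifnot(all(c("voltage", "duration") %in% names(segments)),
            sweep$field %in% c("voltage", "duration"),
            sweep$segment >= 1, sweep$segment <= nrow(segments),
            test_index >= 1, test_index <= nrow(segments))
  if (test_index < sweep$segment) {
    stop("test pulse must come after the swept (conditioning) segment",
         call. = FALSE)
  }
  d <- diff(sweep$values)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("sweep grid must be strictly monotone", call. = FALSE)
  }
  structure(list(name = name, holding = holding, segments = segments,
                 sweep = sweep, test_index = test_index),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> %s: holding %g mV, %d segments, sweeping %s of segment %d (%d values), test pulse = segment %d\n",
              x$name, x$holding, nrow(x$segments), x$sweep$field,
              x$sweep$segment, length(x$sweep$values), x$test_index))
  invisible(x)
}

log_grid <- function(from, to, points_per_decade = 8) {
  10 ^ seq(log10(from), log10(to),
           length.out = max(2L, round(log10(to / from) * points_per_decade) + 1L))
}

#' Standard voltage protocols
#'
#' Builds the protocols used throughout the study. Durations are seconds,
#' voltages mV. The test pulse is a 10 ms depolarization to 0 mV in all
#' protocols; holding is -150 mV.
#'
#' \describe{
#'   \item{`FInact_V`}{"Steady-state fast inactivation": conditioning
#'     pre-pulse swept from -120 to -30 mV (5 mV steps), duration
#'     `pre_duration` (0.1 s by default, 2 s in the experimental variant),
#'     then the test pulse.}
#'   \item{`SInact_V`}{"Steady-state slow inactivation": 10 s pre-pulse with
#'     swept voltage, then a 10 ms hyperpolarizing gap at -150 mV that lets
#'     channels recover from fast (but not slow) inactivation, then the test
#'     pulse.}
#'   \item{`SInact_t`}{Onset of slow inactivation: depolarizing pre-pulse at
#'     -20 mV of swept duration (1 ms - 30 s, log-spaced), then the
#'     hyperpolarizing gap (default 10 ms at -150 mV; set `gap_duration` /
#'     `gap_voltage` for variants such as 5 ms at -120 mV), then the test
#'     pulse.}
#'   \item{`Rec_t`}{Recovery from inactivation: 5 s conditioning at -20 mV
#'     (driving both fast and slow inactivation), then a hyperpolarizing gap
#'     at -150 mV of swept duration (0.1 ms - 10 s, log-spaced), then the
#'     test pulse.}
#'   \item{`CR`}{Single test depolarization to 0 mV from the holding
#'     potential; used by [concentration_response()]. The "sweep" is the
#'     degenerate single test pulse.}
#' }
#'
#' @param name One of `"FInact_V"`, `"SInact_V"`, `"SInact_t"`, `"Rec_t"`,
#'   `"CR"`.
#' @param pre_duration `FInact_V` conditioning duration, s.
#' @param gap_duration,gap_voltage Hyperpolarizing-gap variants
#'   (`SInact_t`).
#' @param holding Holding potential, mV.
#' @param voltage_step Voltage-sweep step, mV.
#' @param points_per_decade Density of log-spaced duration grids.
#' @param test_voltage,test_duration Test-pulse definition.
#' @return A [protocol()] object.
#' @export
standard_protocol <- function(name,
                              pre_duration = 0.1,
                              gap_duration = 0.01,
                              gap_voltage = -150,
                              holding = -150,
                              voltage_step = 5,
                              points_per_decade = 8,
                              test_voltage = 0,
                              test_duration = 0.01) {
  name <- match.arg(name, c("FInact_V", "SInact_V", "SInact_t", "Rec_t",
                            "CR"))
  test <- c(voltage = test_voltage, duration = test_duration)
  switch(name,
    FInact_V = protocol(
      name, holding,
      tibble(voltage = c(-120, test[["voltage"]]),
             duration = c(pre_duration, test[["duration"]])),
      sweep = list(segment = 1L, field = "voltage",
                   values = seq(-120, -30, by = voltage_step)),
      test_index = 2L),
    SInact_V = protocol(
      name, holding,
      tibble(voltage = c(-120, gap_voltage, test[["voltage"]]),
             duration = c(10, gap_duration, test[["duration"]])),
      sweep = list(segment = 1L, field = "voltage",
                   values = seq(-120, 0, by = voltage_step)),
      test_index = 3L),
    SInact_t = protocol(
      name, holding,
      tibble(voltage = c(-20, gap_voltage, test[["voltage"]]),
             duration = c(1, gap_duration, test[["duration"]])),
      sweep = list(segment = 1L, field = "duration",
                   values = log_grid(1e-3, 30, points_per_decade)),
      test_index = 3L),
    Rec_t = protocol(
      name, holding,
      tibble(voltage = c(-20, -150, test[["voltage"]]),
             duration = c(5, 0.01, test[["duration"]])),
      sweep = list(segment = 2L, field = "duration",
                   values = log_grid(1e-4, 10, points_per_decade)),
      test_index = 3L),
    CR = protocol(
      name, holding,
      tibble(voltage = test[["voltage"]], duration = test[["duration"]]),
      sweep = list(segment = 1L, field = "voltage",
                   values = test[["voltage"]]),
      test_index = 1L))
}

# peak conducting occupancy during a constant-voltage test pulse
test_pulse_peak <- function(Pstep, occ, n_steps, cvec) {
  peak <- sum(cvec * occ)
  for (k in seq_len(n_steps)) {
    occ <- Pstep %*% occ
    val <- sum(cvec * occ)
    if (val > peak) peak <- val
  }
  peak
}

run_condition <- function(model, proto, test_dt) {
  st <- model$states
  cvec <- as.numeric(st$conducting)
  Qcache <- new.env(parent = emptyenv())
  getQ <- function(v) {
    key <- sprintf("%.10g", v)
    if (is.null(Qcache[[key]])) {
      Qcache[[key]] <- assemble_rate_matrix(model, voltage = v)
    }
    Qcache[[key]]
  }
  init <- equilibrium(getQ(proto$holding))
  test_seg <- proto$segments[proto$test_index, ]
  sweep_on_test <- proto$sweep$segment == proto$test_index
  Ptest <- NULL
  if (!sweep_on_test || proto$sweep$field == "duration") {
    Ptest <- as.matrix(Matrix::expm(getQ(test_seg$voltage) * test_dt))
  }
  vapply(proto$sweep$values, function(val) {
    segs <- proto$segments
    segs[[proto$sweep$field]][proto$sweep$segment] <- val
    occ <- init
    if (proto$test_index > 1L) {
      for (i in seq_len(proto$test_index - 1L)) {
        if (segs$duration[i] > 0) {
          occ <- solve_oracle(getQ(segs$voltage[i]), segs$duration[i], occ)
        }
      }
    }
    tv <- segs$voltage[proto$test_index]
    td <- segs$duration[proto$test_index]
    P <- if (!is.null(Ptest) && tv == test_seg$voltage) Ptest else
      as.matrix(Matrix::expm(getQ(tv) * test_dt))
    test_pulse_peak(P, occ, ceiling(td / test_dt), cvec)
  }, numeric(1))
}

#' Run a protocol sweep and extract the availability curve
#'
#' Initializes the channel population at equilibrium at the holding
#' potential (with the drug present, modeling continuous drug exposure),
#' integrates the voltage segments in order for every sweep value, and reads
#' out the maximum conducting occupancy during the test pulse. Currents are
#' normalized to the maximal value of the drug-free control sweep of the
#' same model, mirroring standard availability-curve practice; when a drug
#' is supplied the control sweep is computed alongside.
#'
#' @param model A drug-free `channel_model`.
#' @param protocol A [protocol()] / [standard_protocol()].
#' @param drug Optional [drug_spec()]; `NULL` gives the control curve only.
#' @param test_dt Readout time step within the test pulse, s.
#' @return A tibble of class `sweep_result` with columns `sweep_value`,
#'   `condition` (`"control"` and, if a drug is given, `"drug"`), `peak`
#'   (raw conducting occupancy) and `relative_current`. The normalization
#'   reference and protocol are stored as attributes.
#' @export
run_sweep <- function(model, protocol, drug = NULL, test_dt = 2.5e-5) {
  stopifnot(inherits(model, "channel_model"), inherits(protocol, "protocol"))
  if (!is.null(model$drug)) {
    stop("pass a drug-free model; supply the drug via `drug`", call. = FALSE)
  }
  ctrl <- run_condition(model, protocol, test_dt)
  ref <- max(ctrl)
  out <- tibble(sweep_value = protocol$sweep$values, condition = "control",
                peak = ctrl, relative_current = ctrl / ref)
  if (!is.null(drug)) {
    dmod <- if (drug$concentration > 0) extend_with_drug(model, drug) else model
    drg <- run_condition(dmod, protocol, test_dt)
    out <- dplyr::bind_rows(out, tibble(
      sweep_value = protocol$sweep$values, condition = "drug",
      peak = drg, relative_current = drg / ref))
  }
  structure(out, class = c("sweep_result", class(out)),
            protocol = protocol$name, sweep_field = protocol$sweep$field,
            normalization = ref,
            drug = if (!is.null(drug)) drug$name else NULL)
}

#' Concentration-response of peak-current inhibition
#'
#' Simulates single test depolarizations to 0 mV from a given holding
#' potential at a grid of drug concentrations and reports the fractional
#' inhibition of the peak test current relative to the drug-free condition.
#' The population is equilibrated with the drug at the holding potential
#' before the test pulse (continuous-presence assumption).
#'
#' @param model Drug-free `channel_model`.
#' @param drug [drug_spec()] template; its concentration field is replaced
#'   by each grid value.
#' @param holding Holding potential, mV.
#' @param concentrations Concentration grid, uM (>= 0).
#' @param test_dt Readout step, s.
#' @return Tibble with columns `concentration` and `inhibition` (in
#'   `[0, 1]`).
#' @export
concentration_response <- function(model, drug, holding = -90,
                                   concentrations, test_dt = 2.5e-5) {
  stopifnot(all(concentrations >= 0))
  proto <- standard_protocol("CR", holding = holding)
  ref <- run_condition(model, proto, test_dt)[1]
  inh <- vapply(concentrations, function(conc) {
    if (conc == 0) return(0)
    dmod <- extend_with_drug(model, at_concentration(drug, conc))
    1 - run_condition(dmod, proto, test_dt)[1] / ref
  }, numeric(1))
  tibble(concentration = concentrations, inhibition = inh)
}
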