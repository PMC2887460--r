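#' Voltage-dependent transition rate law
#'
#' A saturating (Boltzmann-type) sigmoid on the log-rate vs. voltage plot,
#' `rate(V) = A / (1 + exp(-s * (V - Vhalf) / r))`, where `s = +1` for a rate
#' that saturates at its limiting value `A` with depolarization
#' (`sense = "depol"`) and `s = -1` for a rate that saturates with
#' hyperpolarization (`sense = "hyper"`). The three free parameters are the
#' limiting rate `A` (1/s), the inflection voltage `Vhalf` (mV) and the slope
#' factor `r` (mV). Unlike a plain exponential, the rate is bounded by `A`,
#' which keeps stiff simulations stable at extreme membrane potentials.
#'
#' @param A Limiting rate, 1/s. Must be positive.
#' @param Vhalf Inflection voltage, mV.
#' @param r Slope factor, mV. Must be positive.
#' @param sense `"depol"` if the rate grows toward `A` with depolarization
#'   (e.g. activation opening, inactivation onset), `"hyper"` if it grows with
#'   hyperpolarization (e.g. deactivation, recovery from inactivation).
#' @return An object of class `rate_law`.
#' @examples
#' law <- rate_law(A = 1000, Vhalf = -50, r = 10, sense = "depol")
#' rate_law_eval(law, -50) # half of the limiting rate at the inflection point
#' @export
rate_law <- function(A, Vhalf, r, sense = c("depol", "hyper")) {
  sense <- match.arg(sense)
  stopifnot(is.finite(A), A > 0, is.finite(Vhalf), is.finite(r), r > 0)
  structure(list(A = A, Vhalf = Vhalf, r = r, sense = sense),
            class = "rate_law")
}

#' Evaluate a rate law at one or more membrane potentials
#'
#' @param law A [rate_law()] object.
#' @param voltage Membrane potential(s), mV. Must be finite.
#' @return Transition rate(s), 1/s; always in `(0, A)`.
#' @export
rate_law_eval <- function(law, voltage) {
  stopifnot(inherits(law, "rate_law"), all(is.finite(voltage)))
  s <- if (law$sense == "depol") 1 else -1
  law$A / (1 + exp(-s * (voltage - law$Vhalf) / law$r))
}

#' @export
print.rate_law <- function(x, ...) {
  cat(sprintf("<rate_law> A = %g 1/s, Vhalf = %g mV, r = %g mV, sense = %s\n",
              x$A, x$Vhalf, x$r, x$sense))
  invisible(x)
}

#' Specification of one gating particle
#'
#' A gate is a two-state (open/closed) particle with voltage-dependent opening
#' and closing rate laws. Three such gates (activation, fast inactivation,
#' slow inactivation), each with two three-parameter rate laws, give the 18
#' channel-specific parameters of the Hodgkin-Huxley-like model.
#'
#' @param name One of `"activation"`, `"fast_inactivation"`,
#'   `"slow_inactivation"`.
#' @param opening,closing [rate_law()] objects for the open- and close-ward
#'   transitions.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(name, opening, closing) {
  name <- match.arg(name,
                    c("activation", "fast_inactivation", "slow_inactivation"))
  stopifnot(inherits(opening, "rate_law"), inherits(closing, "rate_law"))
  structure(list(name = name, opening = opening, closing = closing),
            class = "gate_spec")
}

#' Equilibrium open probability of a single gate
#'
#' With independent gates the equilibrium open probability of a gate is the
#' two-state Boltzmann ratio `alpha / (alpha + beta)` of its opening and
#' closing rates. Used both to initialize calibration analytically and as the
#' closed-form oracle against the full model equilibrium.
#'
#' @param gate A [gate_spec()].
#' @param voltage Membrane potential(s), mV.
#' @return Open probability in `(0, 1)`.
#' @export
gate_open_prob <- function(gate, voltage) {
  a <- rate_law_eval(gate$opening, voltage)
  b <- rate_law_eval(gate$closing, voltage)
  a / (a + b)
}

#' Midpoint voltage of a gate's equilibrium curve
#'
#' Solves `opening(V) == closing(V)` numerically; at that voltage the
#' equilibrium open probability is 1/2.
#'
#' @param gate A [gate_spec()].
#' @param interval Search interval in mV.
#' @return Voltage (mV) at which the gate is half open, or `NA` if the rates
#'   do not cross within the interval.
#' @export
gate_vhalf <- function(gate, interval = c(-200, 100)) {
  f <- function(v) rate_law_eval(gate$opening, v) - rate_law_eval(gate$closing, v)
  if (f(interval[1]) * f(interval[2]) > 0) return(NA_real_)
  stats::uniroot(f, interval, tol = 1e-8)$root
}
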