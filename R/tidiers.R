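#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Boltzmann availability-curve fit
#'
#' @param x A `boltzmann_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble(term = c("Vhalf", "slope", "top", "bottom"),
         estimate = c(x$Vhalf, x$slope, x$top, x$bottom))
}

#' @rdname tidy.boltzmann_fit
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble(Vhalf = x$Vhalf, slope = x$slope, residual = x$residual,
         undefined = x$undefined, n = length(x$data$x))
}

#' Tidy a biexponential recovery fit
#'
#' @param x A `biexp_fit`.
#' @param ... Unused.
#' @return One row per parameter (`tau_fast` and `tau_slow` in seconds).
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble(term = c("tau_fast", "tau_slow", "amp_fast", "amp_slow"),
         estimate = c(x$tau_fast, x$tau_slow, x$amp_fast, x$amp_slow))
}

#' @rdname tidy.biexp_fit
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble(tau_fast = x$tau_fast, tau_slow = x$tau_slow,
         amp_fast = x$amp_fast, amp_slow = x$amp_slow,
         residual = x$residual,
         single_exponential = x$single_exponential,
         n = length(x$data$x))
}
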