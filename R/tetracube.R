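#' Eight-state Hodgkin-Huxley-like sodium-channel gating model
#'
#' Three independent two-state gates - activation (a), fast inactivation (f)
#' and slow inactivation (s) - each switch between open and closed with
#' voltage-dependent rates ([rate_law()]); their 2 x 2 x 2 combinations form
#' the eight vertices of a cube whose edges are single-gate transitions. The
#' channel conducts only when all three gates are open. Adding a
#' non-conducting drug-bound partner to every vertex
#' ([extend_with_drug()]) turns the cube into a four-dimensional hypercube
#' ("tetracube"/tesseract) of 16 states and 32 undirected edges.
#'
#' State names encode the configuration with one letter per gate, uppercase
#' meaning open (e.g. `"AFS"` is the conducting state, `"AfS"` is
#' fast-inactivated with activation and slow gates open); a trailing `*`
#' marks the drug-bound copy.
#'
#' @param activation,fast_inactivation,slow_inactivation [gate_spec()]
#'   objects (or a single `params` list, see [tetracube_params()]).
#' @return A `channel_model` with 8 states and 24 directed transitions.
#' @examples
#' m <- tetracube_model(params = default_tetracube_params())
#' n_states(m)
#' @export
tetracube_model <- function(activation = NULL, fast_inactivation = NULL,
                            slow_inactivation = NULL, params = NULL) {
  if (!is.null(params)) {
    gates <- gates_from_params(params)
  } else {
    gates <- list(activation = activation,
                  fast_inactivation = fast_inactivation,
                  slow_inactivation = slow_inactivation)
    stopifnot(!vapply(gates, is.null, logical(1)))
    params <- params_from_gates(gates)
  }
  cfg <- tidyr::expand_grid(act_open = c(TRUE, FALSE),
                            fast_open = c(TRUE, FALSE),
                            slow_open = c(TRUE, FALSE))
  letter <- function(open, up, lo) ifelse(open, up, lo)
  states <- tibble(
    state = paste0(letter(cfg$act_open, "A", "a"),
                   letter(cfg$fast_open, "F", "f"),
                   letter(cfg$slow_open, "S", "s")),
    conducting = cfg$act_open & cfg$fast_open & cfg$slow_open,
    act_open = cfg$act_open, fast_open = cfg$fast_open,
    slow_open = cfg$slow_open)

  gate_cols <- c(activation = "act_open", fast_inactivation = "fast_open",
                 slow_inactivation = "slow_open")
  tr <- purrr::map_dfr(names(gate_cols), function(g) {
    col <- gate_cols[[g]]
    other <- states
    other[[col]] <- !other[[col]]
    partner <- states$state[match(
      do.call(paste0, lapply(other[c("act_open", "fast_open", "slow_open")],
                             as.character)),
      do.call(paste0, lapply(states[c("act_open", "fast_open", "slow_open")],
                             as.character)))]
    tibble(from = states$state, to = partner, gate = g,
           dir = ifelse(states[[col]], "close", "open"),
           law = lapply(states[[col]], function(open) {
             if (open) gates[[g]]$closing else gates[[g]]$opening
           }),
           scale = 1)
  })
  new_channel_model("tetracube", states, tr,
                    c(params, list(gates = gates)))
}

#' Construct / flatten the 18 channel-specific tetracube parameters
#'
#' The tetracube is parameterized by six [rate_law()]s (three gates times
#' opening/closing), i.e. 18 numbers. The flat representation uses keys
#' `<gate>_<dir>_<field>` with gates `act`, `fast`, `slow`, directions
#' `open`, `close` and fields `A` (1/s), `Vhalf` (mV), `r` (mV); the fixed
#' saturation senses are: opening rates of inactivation gates and closing
#' rate of the activation gate saturate with hyperpolarization, the other
#' three with depolarization.
#'
#' @param x Named numeric vector or list of the 18 flat parameters.
#' @return For `tetracube_params()`, a validated parameter list; for
#'   [default_tetracube_params()], the calibrated parameter set shipped with
#'   the package.
#' @export
tetracube_params <- function(x) {
  x <- as.list(x)
  need <- param_names_tetracube()
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("missing tetracube parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x[need]
}

param_names_tetracube <- function() {
  as.vector(outer(c("act", "fast", "slow"),
                  outer(c("open", "close"), c("A", "Vhalf", "r"),
                        paste, sep = "_"),
                  paste, sep = "_"))
}

# which way each of the six rate laws saturates: opening of the activation
# gate and closing (onset) of the inactivation gates grow with
# depolarization; their reverses grow with hyperpolarization
tetracube_senses <- function() {
  list(act = c(open = "depol", close = "hyper"),
       fast = c(open = "hyper", close = "depol"),
       slow = c(open = "hyper", close = "depol"))
}

gates_from_params <- function(params) {
  params <- tetracube_params(params)
  senses <- tetracube_senses()
  mk <- function(g) {
    laws <- lapply(c(open = "open", close = "close"), function(d) {
      rate_law(A = params[[paste(g, d, "A", sep = "_")]],
               Vhalf = params[[paste(g, d, "Vhalf", sep = "_")]],
               r = params[[paste(g, d, "r", sep = "_")]],
               sense = senses[[g]][[d]])
    })
    laws
  }
  list(
    activation = gate_spec("activation", mk("act")$open, mk("act")$close),
    fast_inactivation = gate_spec("fast_inactivation", mk("fast")$open,
                                  mk("fast")$close),
    slow_inactivation = gate_spec("slow_inactivation", mk("slow")$open,
                                  mk("slow")$close))
}

params_from_gates <- function(gates) {
  short <- c(activation = "act", fast_inactivation = "fast",
             slow_inactivation = "slow")
  out <- list()
  for (g in names(short)) {
    for (d in c("open", "close")) {
      law <- if (d == "open") gates[[g]]$opening else gates[[g]]$closing
      for (f in c("A", "Vhalf", "r")) {
        out[[paste(short[[g]], d, f, sep = "_")]] <- law[[f]]
      }
    }
  }
  out
}

#' @rdname tetracube_params
#' @export
default_tetracube_params <- function() {
  path <- system.file("extdata", "tetracube_default.yaml",
                      package = "navblock")
  read_model_config(path)$params
}

#' Calibrated default tetracube model
#'
#' Convenience constructor for the shipped calibrated parameter set; see
#' [calibrate()] for how it was obtained.
#'
#' @return A drug-free `channel_model`.
#' @export
default_tetracube_model <- function() {
  tetracube_model(params = default_tetracube_params())
}

#' Marginal availability of the independent-gate model (closed form)
#'
#' Because the three gates move independently, the equilibrium occupancy of
#' the conducting state equals the product of the per-gate Boltzmann open
#' probabilities. Used as an analytic oracle for the full-model equilibrium.
#'
#' @param model A drug-free tetracube `channel_model`.
#' @param voltage Membrane potential(s), mV.
#' @return Equilibrium conducting-state occupancy.
#' @export
analytic_availability <- function(model, voltage) {
  gates <- model$params$gates
  vapply(voltage, function(v) {
    prod(vapply(gates, gate_open_prob, numeric(1), voltage = v))
  }, numeric(1))
}
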