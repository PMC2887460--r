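#' @importFrom rlang %||%
#' @importFrom tibble tibble as_tibble
NULL

new_channel_model <- function(type, states, transitions, params,
                              drug = NULL) {
  stopifnot(all(c("state", "conducting") %in% names(states)),
            all(c("from", "to", "gate", "dir", "law", "scale") %in%
                  names(transitions)))
  bad <- setdiff(c(transitions$from, transitions$to), states$state)
  if (length(bad)) {
    stop("unknown state reference in model graph: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  structure(list(type = type, states = states, transitions = transitions,
                 params = params, drug = drug),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("<channel_model> %s: %d states, %d directed transitions%s\n",
              x$type, nrow(x$states), nrow(x$transitions),
              if (!is.null(x$drug)) {
                sprintf(" (drug-bound layer: %s, %g uM)",
                        x$drug$name, x$drug$concentration)
              } else ""))
  invisible(x)
}

#' Number of states / directed transitions of a channel model
#'
#' @param model A `channel_model`.
#' @return Integer count.
#' @export
n_states <- function(model) nrow(model$states)

#' @rdname n_states
#' @export
n_transitions <- function(model) nrow(model$transitions)

transition_rates <- function(model, voltage) {
  tr <- model$transitions
  rate <- tr$scale
  has_law <- !vapply(tr$law, is.null, logical(1))
  if (any(has_law)) {
    rate[has_law] <- rate[has_law] *
      vapply(tr$law[has_law], rate_law_eval, numeric(1), voltage = voltage)
  }
  rate
}

#' Assemble the transition-rate matrix of a model at one voltage
#'
#' Builds the generator matrix `Q` of the master equation
#' `dS/dt = Q S`, with the convention that entry `(i, j)` for `i != j` is the
#' rate (1/s) of the transition from state `j` into state `i`, and each
#' diagonal entry is minus the sum of its column (so columns sum to zero and
#' total occupancy is conserved). If a `drug` is supplied and the model is
#' drug-free, the model is first extended with the drug-bound layer; binding
#' rates scale linearly with the drug concentration.
#'
#' @param model A `channel_model` (e.g. from [tetracube_model()]).
#' @param drug Optional [drug_spec()]; ignored if the model already carries
#'   its drug-bound layer.
#' @param voltage Membrane potential, mV (finite).
#' @return A square numeric matrix with state names as dimnames.
#' @export
assemble_rate_matrix <- function(model, drug = NULL, voltage) {
  stopifnot(inherits(model, "channel_model"), is.finite(voltage))
  if (!is.null(drug) && is.null(model$drug)) {
    model <- extend_with_drug(model, drug)
  }
  st <- model$states$state
  n <- length(st)
  Q <- matrix(0, n, n, dimnames = list(st, st))
  rate <- transition_rates(model, voltage)
  i <- match(model$transitions$to, st)
  j <- match(model$transitions$from, st)
  for (k in seq_along(rate)) Q[i[k], j[k]] <- Q[i[k], j[k]] + rate[k]
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' Validate a rate matrix
#'
#' Checks the generator-matrix invariants: non-negative off-diagonal entries
#' and columns summing to zero (conservation).
#'
#' @param Q A square numeric matrix.
#' @param tol Relative tolerance on the column sums.
#' @return `Q`, invisibly; errors if invalid.
#' @export
validate_rate_matrix <- function(Q, tol = 1e-10) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  off <- Q
  diag(off) <- 0
  if (any(off < 0)) stop("negative off-diagonal rate", call. = FALSE)
  scale <- max(abs(Q), 1)
  if (any(abs(colSums(Q)) > tol * scale)) {
    stop("columns of Q do not sum to zero", call. = FALSE)
  }
  invisible(Q)
}

#' Add a drug-bound layer to a gating model
#'
#' Duplicates every state of a drug-free model into a non-conducting
#' drug-bound copy and connects each free state to its bound partner
#' (modulated-receptor scheme: association to every state is possible, but
#' not with equal affinity). For a state in which the set `G` of gates is
#' closed, the association rate is `ka * concentration * prod(C_g, g in G)`
#' while the dissociation rate stays `kd` (guarded-receptor accessibility:
#' binding to the stabilized conformation is faster, not tighter per
#' collision). In the bound layer the closed/open equilibrium constant of
#' gate `g` is shifted by `C_g`; detailed balance fixes only the
#' equilibrium, so how the factor splits between the two directed rates is
#' a modeling choice exposed via `stabilization_split`:
#' \describe{
#'   \item{`"slow_recovery"` (default)}{the rate of opening the stabilized
#'     gate is divided by `C_g` - the bound drug delays recovery from the
#'     inactivated state, the classic modulated-receptor reading;}
#'   \item{`"fast_onset"`}{the closing rate is multiplied by `C_g`;}
#'   \item{`"sqrt"`}{the factor is split symmetrically (`sqrt(C_g)` both
#'     ways).}
#' }
#' Affinity and gating equilibria are shifted by the same factor under all
#' three splits and every square face of the extended state graph satisfies
#' microscopic reversibility exactly.
#'
#' @param model A drug-free `channel_model`.
#' @param drug A [drug_spec()].
#' @param stabilization_split How the stabilizing factor is divided between
#'   the bound-layer gating rates; see Details.
#' @return A `channel_model` with twice the number of states.
#' @export
extend_with_drug <- function(model, drug,
                             stabilization_split = c("slow_recovery",
                                                     "fast_onset",
                                                     "sqrt")) {
  stabilization_split <- match.arg(stabilization_split)
  stopifnot(inherits(model, "channel_model"), inherits(drug, "drug_spec"))
  if (!is.null(model$drug)) {
    stop("model already carries a drug-bound layer", call. = FALSE)
  }
  st <- model$states
  bound <- st
  bound$state <- paste0(st$state, "*")
  bound$conducting <- FALSE
  bound$bound <- TRUE
  st$bound <- FALSE

  factor_of <- c(activation = drug$CA, fast_inactivation = drug$CF,
                 slow_inactivation = drug$CS)
  tr <- model$transitions
  tr_bound <- tr
  tr_bound$from <- paste0(tr$from, "*")
  tr_bound$to <- paste0(tr$to, "*")
  gated <- tr_bound$gate %in% names(factor_of)
  fac <- unname(factor_of[tr_bound$gate])
  close_mult <- switch(stabilization_split,
                       slow_recovery = 1, fast_onset = fac, sqrt = sqrt(fac))
  open_mult <- switch(stabilization_split,
                      slow_recovery = 1 / fac, fast_onset = 1,
                      sqrt = 1 / sqrt(fac))
  cl <- gated & tr_bound$dir == "close"
  op <- gated & tr_bound$dir == "open"
  tr_bound$scale[cl] <- tr_bound$scale[cl] * rep(close_mult,
                                                 length.out = nrow(tr_bound))[cl]
  tr_bound$scale[op] <- tr_bound$scale[op] * rep(open_mult,
                                                 length.out = nrow(tr_bound))[op]

  # binding-affinity multiplier: product of C_g over closed gates of the state
  open_cols <- intersect(c("act_open", "fast_open", "slow_open"), names(st))
  gate_of <- c(act_open = "activation", fast_open = "fast_inactivation",
               slow_open = "slow_inactivation")
  mult <- rep(1, nrow(st))
  for (col in open_cols) {
    mult <- mult * ifelse(st[[col]], 1, factor_of[[gate_of[[col]]]])
  }
  tr_bind <- tibble(
    from = c(st$state, bound$state),
    to = c(bound$state, st$state),
    gate = "binding",
    dir = rep(c("bind", "unbind"), each = nrow(st)),
    law = rep(list(NULL), 2L * nrow(st)),
    scale = c(drug$ka * drug$concentration * mult,
              rep(drug$kd, nrow(st))))

  new_channel_model(model$type, dplyr::bind_rows(st, bound),
                    dplyr::bind_rows(tr, tr_bound, tr_bind),
                    model$params, drug = drug)
}

# all 4-cycles (square faces) of the undirected transition graph
model_faces <- function(model) {
  st <- model$states$state
  n <- length(st)
  A <- matrix(FALSE, n, n, dimnames = list(st, st))
  A[cbind(match(model$transitions$to, st),
          match(model$transitions$from, st))] <- TRUE
  A <- A | t(A)
  faces <- list()
  for (u in 1:(n - 1)) {
    for (w in u:n) {
      if (w == u) next
      common <- which(A[u, ] & A[w, ])
      common <- common[common > u & common != w]
      if (length(common) < 2) next
      pairs <- utils::combn(common, 2)
      for (p in seq_len(ncol(pairs))) {
        v1 <- pairs[1, p]; v2 <- pairs[2, p]
        if (A[u, w] && (v1 == u || v2 == u)) next
        faces[[length(faces) + 1L]] <- c(u, v1, w, v2)
      }
    }
  }
  unique(faces)
}

#' Microscopic-reversibility check over all square faces
#'
#' Enumerates every 4-cycle (square face) of the model's state graph and
#' computes the ratio of the clockwise to the counter-clockwise rate
#' products at the given voltages. Detailed balance requires all ratios to
#' equal 1; the faces generate the cycle space of the hypercube-like graphs
#' used here, so face balance implies balance of every closed loop.
#'
#' @param model A `channel_model`.
#' @param voltages Membrane potentials (mV) at which to evaluate the rates.
#' @return A tibble with one row per face and voltage: the four state names,
#'   the voltage and the rate-product `ratio`.
#' @export
detailed_balance <- function(model, voltages = c(-150, -90, -20, 0)) {
  faces <- model_faces(model)
  st <- model$states$state
  out <- purrr::map_dfr(voltages, function(v) {
    Q <- assemble_rate_matrix(model, voltage = v)
    purrr::map_dfr(faces, function(f) {
      cw <- Q[f[2], f[1]] * Q[f[3], f[2]] * Q[f[4], f[3]] * Q[f[1], f[4]]
      ccw <- Q[f[4], f[1]] * Q[f[3], f[4]] * Q[f[2], f[3]] * Q[f[1], f[2]]
      tibble(s1 = st[f[1]], s2 = st[f[2]], s3 = st[f[3]], s4 = st[f[4]],
             voltage = v, ratio = cw / ccw)
    })
  })
  out
}
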