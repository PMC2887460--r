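#' Tools for integrating the gating master equation
#'
#' Within a voltage-clamp segment the membrane potential, and therefore the
#' generator matrix `Q`, is constant, so the master equation `dS/dt = Q S` is
#' a linear constant-coefficient system. Two solvers are provided: a
#' fixed-step fourth-order Runge-Kutta integrator ([integrate_schedule()]
#' with `method = "rk4"`) and the piecewise matrix exponential
#' (`method = "expm"`), which is exact at the reported time points and is the
#' default for production runs. [solve_oracle()] exposes the one-shot matrix
#' exponential solution for cross-checks.
#'
#' @name markov_engine
NULL

new_trajectory <- function(times, occ, conducting_states,
                           conservation_tol = 1e-6) {
  tot <- rowSums(occ)
  if (any(abs(tot - 1) > conservation_tol)) {
    stop(sprintf("occupancy conservation violated (max drift %.3g)",
                 max(abs(tot - 1))), call. = FALSE)
  }
  structure(list(times = times, occupancies = occ,
                 conducting = rowSums(occ[, conducting_states, drop = FALSE])),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points over %g s, peak conducting %.4g\n",
              length(x$times), max(x$times) - min(x$times),
              max(x$conducting)))
  invisible(x)
}

#' @export
as_tibble.trajectory <- function(x, ...) {
  tibble(time = x$times, conducting = x$conducting,
         as_tibble(as.data.frame(x$occupancies)))
}

# clip tiny float negatives and renormalize; larger negatives are an error
clip_occupancy <- function(p, tol = 1e-9) {
  if (any(p < -tol)) {
    stop(sprintf("negative occupancy %.3g beyond tolerance", min(p)),
         call. = FALSE)
  }
  p[p < 0] <- 0
  p / sum(p)
}

#' Exact solution of the master equation for constant Q
#'
#' Computes `expm(Q * t) %*% initial`, the exact occupancy after time `t`
#' under a constant generator matrix. Serves both as the production
#' propagator for piecewise-constant voltage and as the independent oracle
#' against the Runge-Kutta path.
#'
#' @param Q Generator matrix (see [assemble_rate_matrix()]).
#' @param t Time, s (>= 0).
#' @param initial Occupancy vector (non-negative, summing to 1).
#' @return Occupancy vector after time `t`.
#' @export
solve_oracle <- function(Q, t, initial) {
  stopifnot(t >= 0, length(initial) == nrow(Q))
  if (t == 0) return(initial)
  p <- as.numeric(Matrix::expm(Q * t) %*% initial)
  names(p) <- rownames(Q)
  clip_occupancy(p)
}

#' Stationary (equilibrium) occupancy of a gating model
#'
#' Solves `Q p = 0` with `sum(p) = 1` by least squares. Used to initialize
#' protocols at the holding potential, where channels (and drug binding, when
#' present) are assumed fully equilibrated.
#'
#' @param Q Generator matrix; its transition graph must be strongly
#'   connected (irreducible), otherwise the stationary distribution is not
#'   unique and a structural error is raised.
#' @return Occupancy vector with non-negative entries summing to 1.
#' @export
equilibrium <- function(Q) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  n <- nrow(Q)
  A <- Q
  diag(A) <- 0
  adj <- A > 0
  reach <- function(adj) {
    seen <- rep(FALSE, n)
    seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- which(apply(adj[, frontier, drop = FALSE], 1, any) & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    seen
  }
  if (!all(reach(adj)) || !all(reach(t(adj)))) {
    stop("rate matrix is reducible: state graph is not strongly connected",
         call. = FALSE)
  }
  p <- qr.solve(rbind(Q, rep(1, n)), c(rep(0, n), 1))
  names(p) <- rownames(Q)
  clip_occupancy(p, tol = 1e-6)
}

rk4_segment <- function(Q, duration, p, step) {
  nsteps <- max(1L, ceiling(duration / step))
  h <- duration / nsteps
  out <- matrix(NA_real_, nsteps + 1L, nrow(Q))
  out[1L, ] <- p
  for (k in seq_len(nsteps)) {
    k1 <- Q %*% p
    k2 <- Q %*% (p + h / 2 * k1)
    k3 <- Q %*% (p + h / 2 * k2)
    k4 <- Q %*% (p + h * k3)
    p <- as.numeric(p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    p <- p / sum(p)
    out[k + 1L, ] <- p
  }
  list(times = seq(0, duration, length.out = nsteps + 1L), occ = out, p = p)
}

expm_segment <- function(Q, duration, p, step) {
  nsteps <- max(1L, ceiling(duration / step))
  h <- duration / nsteps
  P <- as.matrix(Matrix::expm(Q * h))
  out <- matrix(NA_real_, nsteps + 1L, nrow(Q))
  out[1L, ] <- p
  for (k in seq_len(nsteps)) {
    p <- as.numeric(P %*% p)
    out[k + 1L, ] <- p
  }
  list(times = seq(0, duration, length.out = nsteps + 1L), occ = out, p = p)
}

#' Integrate the master equation over a piecewise-constant voltage schedule
#'
#' @param schedule A list of segments, each a list with elements `Q`
#'   (generator matrix) and `duration` (s). All matrices must share the same
#'   state space. Zero-duration segments are skipped.
#' @param initial Initial occupancy vector.
#' @param conducting Logical vector (or state names) marking conducting
#'   states, used for the summed conducting occupancy of the trajectory.
#' @param step Output/integration time step, s. `NULL` chooses, per segment,
#'   `min(duration / 50, 0.1 / max |diag(Q)|)`, which keeps the stiffest rate
#'   resolved. An explicit step violating `max |diag(Q)| * step <= 0.1` under
#'   `method = "rk4"` raises a stability error with an advisory step size.
#' @param method `"expm"` (exact piecewise propagator, default) or `"rk4"`
#'   (classic fixed-step fourth-order Runge-Kutta).
#' @return A `trajectory` object: time grid, occupancy matrix (time by
#'   state) and summed conducting occupancy, continuous across segment
#'   boundaries.
#' @export
integrate_schedule <- function(schedule, initial, conducting = NULL,
                               step = NULL, method = c("expm", "rk4")) {
  method <- match.arg(method)
  stopifnot(length(schedule) >= 0)
  p <- clip_occupancy(initial)
  times <- 0
  occ <- matrix(p, 1L)
  t0 <- 0
  for (seg in schedule) {
    Q <- seg$Q
    if (seg$duration < 0) stop("segment duration must be >= 0", call. = FALSE)
    if (seg$duration == 0) next
    stiff <- max(abs(diag(Q)))
    h <- step %||% min(seg$duration / 50, 0.1 / stiff)
    if (method == "rk4" && stiff * h > 0.1 + 1e-12) {
      stop(sprintf(
        "step %.3g s unstable for stiffest rate %.3g 1/s; use step <= %.3g s",
        h, stiff, 0.1 / stiff), call. = FALSE)
    }
    res <- switch(method,
                  rk4 = rk4_segment(Q, seg$duration, p, h),
                  expm = expm_segment(Q, seg$duration, p, h))
    p <- res$p
    times <- c(times, t0 + res$times[-1L])
    occ <- rbind(occ, res$occ[-1L, , drop = FALSE])
    t0 <- t0 + seg$duration
  }
  if (is.null(conducting)) conducting <- rep(TRUE, length(p))
  if (is.character(conducting)) {
    conducting <- colnames(occ) %in% conducting
  }
  colnames(occ) <- names(initial) %||% rownames(schedule[[1]]$Q)
  new_trajectory(times, occ, conducting)
}
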