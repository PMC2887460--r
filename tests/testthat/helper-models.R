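# shared fixtures, all built in code

# minimal hand-built channel model with constant rates between two states
two_state_model <- function(k12, k21) {
  navblock:::new_channel_model(
    "toy",
    tibble::tibble(state = c("s1", "s2"), conducting = c(FALSE, TRUE)),
    tibble::tibble(from = c("s1", "s2"), to = c("s2", "s1"),
                   gate = "toy", dir = c("close", "open"),
                   law = list(NULL, NULL), scale = c(k12, k21)),
    params = list())
}

# random generator matrix on n states with a connected transition graph
random_Q <- function(n, rate_scale = 50) {
  Q <- matrix(stats::runif(n * n) * rate_scale, n, n)
  diag(Q) <- 0
  # thin some edges but keep a cycle through all states for irreducibility
  mask <- matrix(stats::runif(n * n) < 0.4, n, n)
  ring <- cbind(c(2:n, 1), 1:n)
  mask[ring] <- TRUE
  Q[!mask] <- 0
  diag(Q) <- -colSums(Q)
  dimnames(Q) <- list(paste0("s", 1:n), paste0("s", 1:n))
  Q
}

# fast analytic tetracube parameter set (no file access, no polish)
quick_params <- function() init_from_constraints()

quick_model <- function() tetracube_model(params = quick_params())

random_occupancy <- function(n) {
  p <- stats::runif(n)
  p / sum(p)
}
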