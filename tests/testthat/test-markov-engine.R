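test_that("rate matrix assembly: symmetric two-state toy model", {
  m <- two_state_model(5, 5)
  Q <- assemble_rate_matrix(m, voltage = -70)
  expect_equal(unname(Q), matrix(c(-5, 5, 5, -5), 2, 2))
  validate_rate_matrix(Q)
})

test_that("model construction rejects unknown state references", {
  expect_error(
    navblock:::new_channel_model(
      "bad",
      tibble::tibble(state = "s1", conducting = TRUE),
      tibble::tibble(from = "s1", to = "nowhere", gate = "g", dir = "open",
                     law = list(NULL), scale = 1),
      params = list()),
    "unknown state")
})

test_that("validate_rate_matrix flags broken generators", {
  Q <- matrix(c(-1, 1, -2, 2), 2, 2)  # negative off-diagonal
  expect_error(validate_rate_matrix(Q), "negative")
  Q2 <- matrix(c(-1, 0.5, 1, -1), 2, 2)  # column sum not zero
  expect_error(validate_rate_matrix(Q2), "sum")
})

test_that("oracle solution: identity at t = 0 and closed-form decay", {
  Q <- assemble_rate_matrix(two_state_model(1, 0), voltage = 0)
  # k12 = 1, k21 = 0, start in state 1: occupancy decays as exp(-t)
  expect_equal(solve_oracle(Q, 0, c(1, 0)), c(1, 0))
  expect_equal(unname(solve_oracle(Q, log(2), c(1, 0))), c(0.5, 0.5),
               tolerance = 1e-10)
})

test_that("equilibrium: detailed-balance two-state and definition check", {
  Q <- assemble_rate_matrix(two_state_model(2, 1), voltage = 0)
  eq <- equilibrium(Q)
  expect_equal(unname(eq), c(1, 2) / 3, tolerance = 1e-12)
  expect_lt(max(abs(Q %*% eq)), 1e-10)
  # long-time oracle solution converges to the equilibrium
  expect_equal(unname(solve_oracle(Q, 100, c(1, 0))), unname(eq),
               tolerance = 1e-10)
})

test_that("equilibrium rejects reducible (disconnected) models", {
  Q <- matrix(0, 4, 4)
  Q[2, 1] <- 1; Q[1, 2] <- 1; Q[4, 3] <- 1; Q[3, 4] <- 1
  diag(Q) <- -colSums(Q)
  expect_error(equilibrium(Q), "reducible")
})

test_that("integration: symmetric relaxation and empty schedules", {
  m <- two_state_model(5, 5)
  Q <- assemble_rate_matrix(m, voltage = 0)
  tr <- integrate_schedule(list(list(Q = Q, duration = 2)), c(1, 0),
                           conducting = c(FALSE, TRUE), method = "rk4")
  expect_equal(unname(tr$occupancies[nrow(tr$occupancies), ]), c(0.5, 0.5),
               tolerance = 1e-8)
  # zero-duration schedule returns the initial occupancy unchanged
  tr0 <- integrate_schedule(list(list(Q = Q, duration = 0)), c(0.3, 0.7))
  expect_equal(unname(tr0$occupancies[1, ]), c(0.3, 0.7))
  expect_length(tr0$times, 1L)
})

test_that("explicit steps violating the stiffness bound raise an error", {
  Q <- assemble_rate_matrix(two_state_model(1000, 1000), voltage = 0)
  expect_error(
    integrate_schedule(list(list(Q = Q, duration = 1)), c(1, 0),
                       step = 0.01, method = "rk4"),
    "step")
})

test_that("occupancy clipping tolerates float noise but not real negatives", {
  p <- c(1, -1e-12, 1e-12)
  out <- navblock:::clip_occupancy(p)
  expect_true(all(out >= 0))
  expect_equal(sum(out), 1)
  expect_error(navblock:::clip_occupancy(c(1, -1e-3)), "negative")
})

test_that("RK4 agrees with the matrix-exponential oracle on random models", {
  set.seed(421)
  for (i in 1:50) {
    n <- sample(3:6, 1)
    Q <- random_Q(n)
    p0 <- random_occupancy(n)
    t_end <- stats::runif(1, 0.01, 0.2)
    tr <- integrate_schedule(list(list(Q = Q, duration = t_end)), p0,
                             method = "rk4")
    expect_lt(max(abs(tr$occupancies[nrow(tr$occupancies), ] -
                        solve_oracle(Q, t_end, p0))), 1e-6)
    # conservation along the whole trajectory
    expect_lt(max(abs(rowSums(tr$occupancies) - 1)), 1e-6)
  }
})

test_that("stationarity: integrating from equilibrium changes nothing", {
  set.seed(77)
  for (i in 1:5) {
    Q <- random_Q(4)
    eq <- equilibrium(Q)
    tr <- integrate_schedule(list(list(Q = Q, duration = 0.5)), eq)
    expect_lt(max(abs(tr$occupancies[nrow(tr$occupancies), ] - eq)), 1e-8)
  }
})

test_that("piecewise schedules are continuous across segment boundaries", {
  set.seed(5)
  Q1 <- random_Q(4); Q2 <- random_Q(4)
  p0 <- random_occupancy(4)
  tr <- integrate_schedule(list(list(Q = Q1, duration = 0.05),
                                list(Q = Q2, duration = 0.05)), p0)
  expect_true(all(diff(tr$times) >= 0))
  ref <- solve_oracle(Q2, 0.05, solve_oracle(Q1, 0.05, p0))
  expect_equal(unname(tr$occupancies[nrow(tr$occupancies), ]), unname(ref),
               tolerance = 1e-8)
  expect_true(all(tr$conducting <= 1 + 1e-9))
})
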