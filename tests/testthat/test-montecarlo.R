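test_that("random draws respect bounds on every parameter", {
  cons <- parameter_constraints(quick_params())
  set.seed(2)
  for (i in 1:1000) {
    p <- unlist(random_model(cons))
    expect_true(all(p >= cons$low & p <= cons$high))
  }
})

test_that("draws are reproducible from a seed", {
  cons <- parameter_constraints(quick_params())
  expect_identical(random_model(cons, seed = 123),
                   random_model(cons, seed = 123))
  expect_false(identical(random_model(cons, seed = 123),
                         random_model(cons, seed = 124)))
})

test_that("log-scaled parameters are log-uniform (Kolmogorov-Smirnov)", {
  cons <- parameter_constraints(quick_params())
  i <- match("fast_open_A", cons$name)
  set.seed(31)
  draws <- replicate(10000,
                     unlist(random_model(cons), use.names = FALSE)[i])
  u <- (log(draws) - log(cons$low[i])) /
    (log(cons$high[i]) - log(cons$low[i]))
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
  # and a linearly sampled midpoint voltage is linear-uniform
  j <- match("fast_open_Vhalf", cons$name)
  set.seed(32)
  vdraws <- replicate(10000,
                      unlist(random_model(cons), use.names = FALSE)[j])
  uv <- (vdraws - cons$low[j]) / (cons$high[j] - cons$low[j])
  expect_gt(suppressWarnings(stats::ks.test(uv, "punif"))$p.value, 0.01)
})

test_that("constraint table flags invalid bounds", {
  cons <- parameter_constraints(quick_params())
  cons$low[1] <- cons$high[1] + 1
  expect_error(random_model(cons))
})

test_that("a small study is deterministic and accounts for every set", {
  mc1 <- run_mc_study(6, constraints = parameter_constraints(quick_params()),
                      seed = 5, points_per_decade = 3, voltage_step = 10)
  mc2 <- run_mc_study(6, constraints = parameter_constraints(quick_params()),
                      seed = 5, points_per_decade = 3, voltage_step = 10)
  expect_identical(mc1$records, mc2$records)
  s <- mc1$summary
  expect_equal(nrow(mc1$records), 6L)
  expect_equal(sum(s$best_onset), s$n_valid)
  expect_equal(sum(s$best_recovery), s$n_valid)
  fr <- c(s$frac_onset_best_is_FI, s$frac_recovery_best_is_FI_sb)
  fr <- fr[!is.na(fr)]
  expect_true(all(fr >= 0 & fr <= 1))
  # invalid sets carry a reason and no metrics
  bad <- mc1$records[!mc1$records$valid, ]
  if (nrow(bad)) expect_true(all(!is.na(bad$invalid_reason)))
})

test_that("closed-form equilibrium midpoints match simulated curves within 1 mV", {
  cons <- parameter_constraints(quick_params())
  found <- 0
  s <- 0
  while (found < 5 && s < 60) {
    s <- s + 1
    prm <- random_model(cons, seed = 400 + s)
    if (!is.na(navblock:::screen_random_model(prm))) next
    m <- tetracube_model(params = prm)
    gates <- m$params$gates
    vh_an <- gate_vhalf(gates$fast_inactivation)
    if (is.na(vh_an) || vh_an < -115 || vh_an > -5) next
    found <- found + 1
    v <- seq(-120, 0, by = 1)
    open_frac <- vapply(v, function(vv) {
      eq <- equilibrium(assemble_rate_matrix(m, voltage = vv))
      sum(eq[m$states$fast_open])
    }, numeric(1))
    k <- which(open_frac[-1] < 0.5 & open_frac[-length(open_frac)] >= 0.5)[1]
    vh_sim <- v[k] + (open_frac[k] - 0.5) /
      (open_frac[k] - open_frac[k + 1])
    expect_lt(abs(vh_sim - vh_an), 1)
  }
  expect_gte(found, 3)
})

test_that("gating screen catches unavailable and non-slow-inactivating sets", {
  p <- quick_params()
  expect_true(is.na(navblock:::screen_random_model(p)))
  # fast gate inactivated everywhere: availability lost at -120 mV
  p_bad <- p
  p_bad$fast_open_A <- 1e-3
  expect_match(navblock:::screen_random_model(p_bad), "availability")
  # slow gate essentially never closes: no slow inactivation
  p_ns <- p
  p_ns$slow_close_A <- 1e-6
  expect_match(navblock:::screen_random_model(p_ns), "slow inactivation")
})
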