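test_that("Boltzmann fit recovers noiseless parameters exactly", {
  v <- seq(-120, -30, by = 5)
  y <- 0 + (1 - 0) / (1 + exp((v + 60) / 6))
  fit <- fit_boltzmann(v, y)
  expect_false(fit$undefined)
  expect_equal(fit$Vhalf, -60, tolerance = 1e-6)
  expect_equal(fit$slope, 6, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
})

test_that("flat availability curves give an undefined midpoint", {
  v <- seq(-120, -30, by = 5)
  fit <- fit_boltzmann(v, rep(1, length(v)))
  expect_true(fit$undefined)
  expect_true(is.na(fit$Vhalf))
})

test_that("Boltzmann midpoint is recovered within 0.5 mV under 1% noise", {
  v <- seq(-120, -30, by = 2.5)
  clean <- 1 / (1 + exp((v + 65) / 7))
  set.seed(99)
  err <- replicate(100, {
    fit <- fit_boltzmann(v, clean + stats::rnorm(length(v), sd = 0.01))
    fit$Vhalf - (-65)
  })
  expect_lt(max(abs(err)), 0.5)
})

test_that("biexponential fit recovers synthetic recovery curves", {
  t <- 10 ^ seq(-4, 0.5, length.out = 40)
  y <- 1 - 0.5 * exp(-t / 2e-3) - 0.5 * exp(-t / 60e-3)
  fit <- fit_biexponential(t, y)
  expect_equal(fit$tau_fast, 2e-3, tolerance = 0.01)
  expect_equal(fit$tau_slow, 60e-3, tolerance = 0.01)
  expect_equal(fit$amp_fast, 0.5, tolerance = 0.01)
  expect_equal(fit$amp_slow, 0.5, tolerance = 0.01)
  expect_false(fit$single_exponential)
})

test_that("single-exponential data is flagged by a vanishing slow amplitude", {
  t <- 10 ^ seq(-4, 0, length.out = 30)
  y <- 1 - 0.8 * exp(-t / 5e-3)
  fit <- fit_biexponential(t, y)
  expect_true(fit$single_exponential)
  expect_equal(fit$tau_fast, 5e-3, tolerance = 0.01)
})

test_that("nSOD endpoints and hand-computed value", {
  # no effect
  expect_equal(nsod(c(1, 0.8, 0.5, 0.2), c(1, 0.8, 0.5, 0.2)), 0)
  # current completely abolished
  expect_equal(nsod(c(1, 0.8, 0.5, 0.2), c(0, 0, 0, 0)), 1)
  # defining formula by hand
  expect_equal(nsod(c(1, 1, 1, 1), c(1, 0.5, 0.5, 1)), 0.25)
  # invariant to uniform rescaling of both curves
  expect_equal(nsod(0.3 * c(1, 1, 1, 1), 0.3 * c(1, 0.5, 0.5, 1)), 0.25)
  # facilitation clips at zero
  expect_equal(nsod(c(1, 1), c(1.2, 1.3)), 0)
  expect_error(nsod(c(1, 1), c(1, 1, 1)), "length")
})

test_that("nSOD accepts sweep results and insists on matching grids", {
  m <- quick_model()
  res <- run_sweep(m, standard_protocol("SInact_t", points_per_decade = 3),
                   drug = prototype_drugs()$FI_fb)
  val <- nsod(res)
  expect_gte(val, 0)
  expect_lte(val, 1)
  broken <- res
  broken$sweep_value[broken$condition == "drug"] <-
    broken$sweep_value[broken$condition == "drug"] * 1.01
  expect_error(nsod(broken), "grids")
})

test_that("nSOD grows with drug concentration for the prototypes", {
  m <- quick_model()
  st <- standard_protocol("SInact_t", points_per_decade = 3)
  for (d in prototype_drugs()[c("FI_fb", "SI_sb")]) {
    vals <- vapply(c(10, 30, 100), function(conc) {
      nsod(run_sweep(m, st, drug = at_concentration(d, conc)))
    }, numeric(1))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("resting-state IC50 equals kd/ka in closed form", {
  m <- quick_model()
  # holding -150 mV: essentially no inactivation, pure resting block
  for (d in prototype_drugs()[c("FI_fb", "SI_sb")]) {
    expect_equal(ic50(m, d, holding = -150), d$kd / d$ka,
                 tolerance = 0.02)
  }
})

test_that("bisection agrees with a dense concentration scan within 2%", {
  m <- quick_model()
  d <- prototype_drugs()$FI_fb
  est <- ic50(m, d, holding = -60)
  conc <- 10 ^ seq(log10(est / 4), log10(est * 4), length.out = 60)
  cr <- concentration_response(m, d, holding = -60, concentrations = conc)
  brute <- stats::approx(cr$inhibition, cr$concentration, xout = 0.5)$y
  expect_equal(est, brute, tolerance = 0.02)
})

test_that("state-preferring drugs gain apparent affinity with depolarized holding", {
  m <- quick_model()
  for (d in prototype_drugs()[c("FI_fb", "SI_fb")]) {
    expect_lt(ic50(m, d, holding = -60), ic50(m, d, holding = -150))
  }
})

test_that("unbracketed IC50 raises an informative error", {
  m <- quick_model()
  d <- prototype_drugs()$FI_fb
  expect_error(ic50(m, d, holding = -150, interval = c(1e-3, 1)),
               "bracket")
})

test_that("gap-duration curve is null for an inert drug", {
  m <- quick_model()
  lazy <- drug_spec(ka = 0.0005, kd = 100, concentration = 1)
  g <- gap_duration_curve(m, lazy, gaps = c(0.001, 0.1, 1),
                          points_per_decade = 3)
  expect_true(all(g$nsod < 1e-3))
  expect_true(all(abs(g$sod) < 0.05))
})

test_that("loop orientation via the shoelace signed area", {
  # unit square traversed counter-clockwise: positive area
  expect_equal(loop_signed_area(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1)
  # clockwise: negative
  expect_equal(loop_signed_area(c(0, 0, 1, 1), c(0, 1, 1, 0)), -1)
})

test_that("hull classification distinguishes the four regions", {
  plane <- structure(list(
    points = tibble::tibble(),
    regions = list(FI = cbind(c(0, 0.6, 0.6, 0), c(0, 0, 0.4, 0.4)),
                   SI = cbind(c(0.3, 0.9, 0.9, 0.3), c(0.2, 0.2, 0.9, 0.9)))),
    class = "nsod_plane")
  pts <- tibble::tibble(nsod_onset = c(0.1, 0.5, 0.8, 0.95),
                        nsod_recovery = c(0.1, 0.3, 0.5, 0.95))
  out <- classify_nsod(plane, pts)
  expect_equal(out$region,
               c("fast-only", "overlap", "slow-only", "outside"))
})
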