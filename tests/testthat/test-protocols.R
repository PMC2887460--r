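test_that("standard protocols encode the published timings", {
  sv <- standard_protocol("SInact_V")
  expect_equal(sv$segments$duration[1], 10)
  expect_equal(sv$segments$voltage[2], -150)   # 10 ms hyperpolarizing gap
  expect_equal(sv$segments$duration[2], 0.01)
  rt <- standard_protocol("Rec_t")
  expect_equal(rt$segments$voltage[1], -20)    # 5 s conditioning
  expect_equal(rt$segments$duration[1], 5)
  fv <- standard_protocol("FInact_V", pre_duration = 2)
  expect_equal(fv$segments$duration[1], 2)
  expect_equal(range(fv$sweep$values), c(-120, -30))
  st <- standard_protocol("SInact_t", gap_duration = 0.005,
                          gap_voltage = -120)
  expect_equal(st$segments$voltage[2], -120)
  expect_equal(st$segments$duration[2], 0.005)
  expect_error(standard_protocol("nope"))
})

test_that("duration grids are log-even at the requested density", {
  st <- standard_protocol("SInact_t", points_per_decade = 8)
  lg <- diff(log10(st$sweep$values))
  expect_equal(max(lg) - min(lg), 0, tolerance = 1e-10)
  expect_equal(1 / lg[1], 8, tolerance = 0.2)
})

test_that("protocols round-trip through serialization", {
  for (nm in c("FInact_V", "SInact_V", "SInact_t", "Rec_t")) {
    p <- standard_protocol(nm)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_protocol_config(p, path)
    p2 <- read_protocol_config(path)
    expect_equal(p2$segments, p$segments)
    expect_identical(p2$sweep$values, p$sweep$values)
    expect_identical(p2$test_index, p$test_index)
  }
})

test_that("protocol invariants are enforced", {
  expect_error(protocol("x", -150,
                        tibble::tibble(voltage = c(0, -20),
                                       duration = c(0.01, 0.1)),
                        sweep = list(segment = 2, field = "voltage",
                                     values = c(-120, -100)),
                        test_index = 1),
               "after")
  expect_error(protocol("x", -150,
                        tibble::tibble(voltage = 0, duration = 0.01),
                        sweep = list(segment = 1, field = "voltage",
                                     values = c(-120, -100, -110)),
                        test_index = 1),
               "monotone")
})

test_that("drug-free availability curves behave physiologically", {
  m <- quick_model()
  res <- run_sweep(m, standard_protocol("FInact_V"))
  y <- res$relative_current
  # full availability at the most hyperpolarized pre-pulse
  expect_gt(y[1], 0.99)
  # monotone non-increasing with pre-pulse depolarization
  expect_true(all(diff(y) < 1e-6))
  # recovery is complete for very long gaps
  rec <- run_sweep(m, standard_protocol("Rec_t", points_per_decade = 4))
  expect_gt(dplyr::last(rec$relative_current), 0.999)
})

test_that("a negligibly binding neutral drug leaves the curve unchanged", {
  m <- quick_model()
  # Kd = 2e5 uM >> 1 uM applied: occupancy never exceeds ~5e-6
  lazy <- drug_spec(ka = 0.0005, kd = 100, CA = 1, CF = 1, CS = 1,
                    concentration = 1, name = "inert")
  res <- run_sweep(m, standard_protocol("FInact_V"), drug = lazy)
  ctrl <- res$relative_current[res$condition == "control"]
  drg <- res$relative_current[res$condition == "drug"]
  expect_lt(max(abs(ctrl - drg)), 1e-3)
})

test_that("holding equilibration is already stationary", {
  m <- quick_model()
  proto <- standard_protocol("FInact_V")
  Qh <- assemble_rate_matrix(m, voltage = proto$holding)
  eq <- equilibrium(Qh)
  aged <- solve_oracle(Qh, 10, eq)  # doubling equilibration time
  expect_lt(max(abs(aged - eq)), 1e-8)
})

test_that("sweep results are normalized to the control maximum", {
  m <- quick_model()
  res <- run_sweep(m, standard_protocol("FInact_V"),
                   drug = prototype_drugs()$FI_fb)
  expect_s3_class(res, "sweep_result")
  expect_true(all(res$relative_current <= 1 + 1e-6))
  ctrl <- res[res$condition == "control", ]
  expect_equal(max(ctrl$relative_current), 1)
  expect_equal(attr(res, "normalization"), max(ctrl$peak))
})

test_that("concentration-response saturates from zero block to full block", {
  m <- quick_model()
  d <- prototype_drugs()$SI_fb
  cr <- concentration_response(m, d, holding = -150,
                               concentrations = c(0, 200, 2e5))
  expect_equal(cr$inhibition[1], 0)
  # Kd = 200 uM at rest: half block at the dissociation constant
  expect_equal(cr$inhibition[2], 0.5, tolerance = 0.02)
  expect_gt(cr$inhibition[3], 0.99)
  expect_true(all(diff(cr$inhibition) > 0))
})
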