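test_that("drug-free cube topology: 8 states, 12 undirected edges", {
  m <- quick_model()
  expect_equal(n_states(m), 8L)
  expect_equal(n_transitions(m), 24L)  # 12 undirected edges
  expect_equal(sum(m$states$conducting), 1L)
  expect_equal(m$states$state[m$states$conducting], "AFS")
  # every transition toggles exactly one gate
  st <- m$states
  cols <- c("act_open", "fast_open", "slow_open")
  for (k in seq_len(nrow(m$transitions))) {
    a <- st[st$state == m$transitions$from[k], cols]
    b <- st[st$state == m$transitions$to[k], cols]
    expect_equal(sum(unlist(a) != unlist(b)), 1L)
  }
})

test_that("the 18 flat parameters round-trip through the model", {
  p <- quick_params()
  expect_length(navblock:::param_names_tetracube(), 18L)
  m <- tetracube_model(params = p)
  p2 <- navblock:::params_from_gates(m$params$gates)
  expect_equal(p2[names(p)], p)
  expect_error(tetracube_params(p[-1]), "missing")
})

test_that("gate independence: model equilibrium equals the analytic product", {
  m <- quick_model()
  for (v in c(-120, -80, -40)) {
    eq <- equilibrium(assemble_rate_matrix(m, voltage = v))
    expect_equal(unname(eq[m$states$conducting]),
                 analytic_availability(m, v), tolerance = 1e-9)
  }
})

test_that("strong hyperpolarization leaves the channel available", {
  m <- quick_model()
  eq <- equilibrium(assemble_rate_matrix(m, voltage = -150))
  avail <- sum(eq[m$states$fast_open & m$states$slow_open])
  expect_gt(avail, 0.95)
})

test_that("drug extension builds the 16-state tesseract", {
  m <- quick_model()
  d <- prototype_drugs()$FI_fb
  md <- extend_with_drug(m, d)
  expect_equal(n_states(md), 16L)
  expect_equal(n_transitions(md), 64L)  # 32 undirected edges
  expect_false(any(md$states$conducting[md$states$bound]))
  expect_error(extend_with_drug(md, d), "already")
})

test_that("resting association rate scales with ka and concentration", {
  m <- quick_model()
  # fast-kinetics prototype at 30 uM: 0.5 * 30 = 15 1/s into the resting state
  Q <- assemble_rate_matrix(m, drug = prototype_drugs()$FI_fb,
                            voltage = -150)
  expect_equal(Q["aFS*", "aFS"], 15)
  expect_equal(Q["AFS*", "AFS"], 15)  # CA = 1: activation state irrelevant
  # fast-inactivated configuration: enhanced by CF = 10
  expect_equal(Q["AfS*", "AfS"], 150)
  # dissociation unchanged everywhere
  expect_equal(unname(Q["AfS", "AfS*"]), 100)
})

test_that("binding rates are linear in concentration and vanish at zero", {
  m <- quick_model()
  d <- prototype_drugs()$SI_fb
  Q1 <- assemble_rate_matrix(m, drug = at_concentration(d, 10),
                             voltage = -90)
  Q2 <- assemble_rate_matrix(m, drug = at_concentration(d, 20),
                             voltage = -90)
  md <- extend_with_drug(m, d)
  bind <- md$transitions$dir == "bind"
  from <- md$transitions$from[bind]; to <- md$transitions$to[bind]
  expect_equal(Q2[cbind(to, from)], 2 * Q1[cbind(to, from)])
  Q0 <- assemble_rate_matrix(m, drug = at_concentration(d, 0),
                             voltage = -90)
  expect_true(all(Q0[cbind(to, from)] == 0))
  expect_equal(unname(Q0[cbind(from, to)]), rep(d$kd, sum(bind)))
})

test_that("every tesseract face satisfies microscopic reversibility", {
  m <- quick_model()
  for (d in prototype_drugs()) {
    for (split in c("slow_recovery", "fast_onset", "sqrt")) {
      md <- extend_with_drug(m, d, stabilization_split = split)
      db <- detailed_balance(md, voltages = c(-150, -90, -20, 0))
      expect_equal(nrow(db) / 4, 24)  # 24 square faces of the tesseract
      expect_lt(max(abs(db$ratio - 1)), 1e-8)
    }
  }
})

test_that("stabilization_shift reports the per-gate equilibrium factor", {
  d <- prototype_drugs()
  expect_equal(stabilization_shift(d$FI_fb, "fast_inactivation"), 10)
  expect_equal(stabilization_shift(d$FI_fb, "slow_inactivation"), 1)
  expect_equal(stabilization_shift(d$SI_fb, "slow_inactivation"), 10)
  neutral <- drug_spec(ka = 1, kd = 200, concentration = 1)
  for (g in c("activation", "fast_inactivation", "slow_inactivation")) {
    expect_equal(stabilization_shift(neutral, g), 1)
  }
  expect_error(stabilization_shift(d$FI_fb, "nonsense"))
})

test_that("a neutral drug's bound layer mirrors the free layer exactly", {
  m <- quick_model()
  neutral <- drug_spec(ka = 0.5, kd = 100, CA = 1, CF = 1, CS = 1,
                       concentration = 30, name = "neutral")
  md <- extend_with_drug(m, neutral)
  Q <- assemble_rate_matrix(md, voltage = -60)
  free <- m$states$state
  bound <- paste0(free, "*")
  # gating block of the bound layer identical to the free layer
  expect_equal(Q[bound, bound] - diag(diag(Q[bound, bound])),
               matrix(Q[free, free] - diag(diag(Q[free, free])),
                      dimnames = list(bound, bound), nrow = 8))
  # binding rates identical for all configurations
  expect_equal(unname(Q[cbind(bound, free)]), rep(15, 8))
  # marginal gating dynamics (bound + unbound per configuration) match the
  # drug-free model
  eq <- equilibrium(assemble_rate_matrix(md, voltage = -150))
  Qd <- assemble_rate_matrix(md, voltage = -20)
  occ <- solve_oracle(Qd, 0.05, eq)
  marg <- occ[free] + occ[bound]
  free_occ <- solve_oracle(assemble_rate_matrix(m, voltage = -20), 0.05,
                           equilibrium(assemble_rate_matrix(m, voltage = -150)))
  expect_equal(unname(marg), unname(free_occ), tolerance = 1e-9)
})

test_that("the equilibrium affinity to fast-inactivated states scales with CF", {
  m <- quick_model()
  d <- prototype_drugs()$FI_fb  # CF = 10
  md <- extend_with_drug(m, d)
  Q <- assemble_rate_matrix(md, voltage = -20)
  # ratio of association/dissociation for a fast-inactivated configuration
  # is CF times the resting ratio
  k_rest <- Q["aFS*", "aFS"] / Q["aFS", "aFS*"]
  k_fi <- Q["afS*", "afS"] / Q["afS", "afS*"]
  expect_equal(k_fi / k_rest, 10)
})

test_that("increasing CF increases steady-state bound fast-inactivated occupancy", {
  m <- quick_model()
  occ_fi_bound <- vapply(c(1, 3, 10, 30), function(cf) {
    d <- drug_spec(ka = 0.5, kd = 100, CF = cf, concentration = 30)
    md <- extend_with_drug(m, d)
    eq <- equilibrium(assemble_rate_matrix(md, voltage = -20))
    sum(eq[md$states$bound & !md$states$fast_open])
  }, numeric(1))
  expect_true(all(diff(occ_fi_bound) > 0))
})
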