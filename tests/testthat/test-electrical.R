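# Channel machinery, calcium shell, synapses, and the compartmental
# integrator against analytic oracles.

test_that("Boltzmann steady state takes its characteristic values", {
  expect_equal(boltzmann_inf(-25, -25, 10), 0.5)
  expect_equal(boltzmann_inf(1e4, -25, 10), 1, tolerance = 1e-12)
  expect_equal(boltzmann_inf(-1e4, -25, 10), 0, tolerance = 1e-12)
  expect_equal(boltzmann_inf(-15, -25, 10), 0.7310586, tolerance = 1e-6)
  # inactivation gates use a negative slope
  expect_equal(boltzmann_inf(-15, -25, -10), 0.2689414, tolerance = 1e-6)
  expect_error(boltzmann_inf(0, 0, 0), "nonzero")
})

test_that("channel current vanishes at zero conductance and at reversal", {
  spec <- channel_spec("k", gbar = 0.01, erev = -90, x = 2, y = 1,
                       m_vh = -30, m_k = 10, h_vh = -60, h_k = -8)
  g <- list(m = 0.4, h = 0.7)
  expect_equal(channel_current(channel_spec("z", 0, -90, x = 1,
                                            m_vh = 0, m_k = 10), list(m = 1), 0), 0)
  expect_equal(channel_current(spec, g, -90), 0)
  # a = 1 reduces the modified form to plain Hodgkin-Huxley
  spec_a1 <- spec; spec_a1$a <- 1
  manual <- 0.01 * 0.4^2 * 0.7 * (-50 - (-90)) * 1e-3
  expect_equal(channel_current(spec_a1, g, -50), manual)
  # a < 1 shallows inactivation: h_eff = a h + (1 - a) > h
  spec_a <- spec; spec_a$a <- 0.2
  expect_gt(channel_current(spec_a, g, -50), channel_current(spec_a1, g, -50))
})

test_that("gate relaxation is the exact exponential update", {
  spec <- channel_spec("m", gbar = 1, erev = 0, x = 1, y = 0,
                       m_vh = -30, m_k = 8, m_tau = 5)
  minf <- boltzmann_inf(-50, -30, 8)
  # fixed point
  g <- step_gates(spec, list(m = minf), -50, 1)
  expect_equal(g$m, minf, tolerance = 1e-12)
  # saturation for dt >> tau
  g <- step_gates(spec, list(m = 0.9), -50, 200)
  expect_equal(g$m, minf, tolerance = 1e-6)
  # the gap halves after dt = tau ln 2
  g <- step_gates(spec, list(m = 0.9), -50, 5 * log(2))
  expect_equal(g$m - minf, (0.9 - minf) / 2, tolerance = 1e-10)
})

test_that("tabulated time constants interpolate piecewise-linearly", {
  tab <- data.frame(v = c(-80, -40, 0), tau = c(2, 6, 3))
  spec <- channel_spec("t", gbar = 1, erev = 0, x = 1, y = 0,
                       m_vh = -30, m_k = 8, m_tau = tab)
  # midpoint of the first segment and clamped ends
  expect_equal(spinesync:::tau_at(tab, -60), 4)
  expect_equal(spinesync:::tau_at(tab, -200), 2)
  expect_equal(spinesync:::tau_at(tab, 50), 3)
  expect_error(channel_spec("bad", 1, 0, m_vh = 0, m_k = 5,
                            m_tau = data.frame(v = 0, tau = -1)),
               "positive")
})

test_that("calcium shell obeys its closed forms", {
  # equilibrium: zero current, zero pump, at rest concentration
  sh <- calcium_shell(ca = 5e-5, pump_vmax = 0)
  sh2 <- shell_calcium_step(sh, 0, 1e-8, 10)
  expect_equal(sh2$ca, 5e-5, tolerance = 1e-12)

  # pure diffusive relaxation with tau_r = 43 ms
  sh <- calcium_shell(ca = 1e-3, pump_vmax = 0)
  tot <- 0
  for (i in 1:20) { sh <- shell_calcium_step(sh, 0, 1e-8, 5); tot <- tot + 5 }
  expect_equal(sh$ca - 5e-5, (1e-3 - 5e-5) * exp(-tot / 43), tolerance = 1e-3)

  # constant inward current with pump and relaxation off accumulates
  # linearly at |I| / (2 F depth)
  area <- 5.86e-8
  sh <- calcium_shell(ca = 0, ca_inf = 0, pump_vmax = 0, tau_r = 1e12)
  I <- -1e-3   # nA, inward
  sh <- shell_calcium_step(sh, I, area, 10)
  dens <- abs(I) * 1e-6 / area
  expect_equal(sh$ca, 10 * dens / (2 * 96.489 * 0.1) * 10, tolerance = 1e-9)

  # outward current from an empty shell clamps at zero with a warning
  sh <- calcium_shell(ca = 0, ca_inf = 0, pump_vmax = 0)
  expect_warning(shell_calcium_step(sh, 1e-3, area, 1), "clamped")
})

test_that("synaptic conductance peaks where the double exponential says", {
  syn <- synapse_state("AMPA", tau_r = 0.5, tau_d = 3, gpeak = 0.5)
  expect_equal(synapse_conductance(syn, c(0, 5, 100)), c(0, 0, 0))
  syn <- synapse_state("AMPA", tau_r = 0.5, tau_d = 3, gpeak = 0.5,
                       weight = 1.4, events = 10)
  expect_equal(synapse_conductance(syn, 10), 0)    # zero at onset
  tp <- synapse_peak_time(0.5, 3)
  expect_equal(tp, 0.5 * 3 / 2.5 * log(6))
  # peak value equals weight * gpeak, and is the maximum
  g_at <- function(t) synapse_conductance(syn, t)
  expect_equal(g_at(10 + tp), 1.4 * 0.5, tolerance = 1e-9)
  expect_lt(g_at(10 + tp - 0.05), g_at(10 + tp))
  expect_lt(g_at(10 + tp + 0.05), g_at(10 + tp))
  expect_error(synapse_state("AMPA", tau_r = 3, tau_d = 1, gpeak = 1),
               "tau_d > tau_r")
})

passive_one_comp <- function(gl = 1e-4) {
  mor <- data.frame(id = "c1", type = "soma", parent = NA, diameter_um = 10,
                    length_um = 10, ra_ohm_cm = 100, cm_uF_cm2 = 1,
                    gl_S_cm2 = gl, el_mV = -70)
  build_electrical_model(morphology = mor, passive = TRUE, v_init = -70)
}

test_that("a passive compartment charges like its RC closed form", {
  m <- passive_one_comp()
  h <- electrical_handle(m, record_dt = 0.5)
  handle_set(h, "iinj_c1", 0.01)
  handle_step(h, 50)
  tr <- electrical_traces(m)
  area <- pi * 10 * 10 * 1e-8
  gl <- 1e-4 * area * 1e6          # uS
  tau <- area * 1e3 / gl           # nF / uS = ms
  v_inf <- -70 + 0.01 / gl
  pred <- v_inf + (-70 - v_inf) * exp(-tr$time_ms / tau)
  expect_lt(max(abs(tr$V_soma - pred)) / (v_inf + 70), 0.005)
})

test_that("a passive two-compartment cable matches the analytic attenuation", {
  mor <- data.frame(
    id = c("c1", "c2"), type = c("soma", "proximal"),
    parent = c(NA, "c1"), diameter_um = c(10, 2), length_um = c(10, 50),
    ra_ohm_cm = 100, cm_uF_cm2 = 1, gl_S_cm2 = 1e-4, el_mV = -70)
  m <- build_electrical_model(morphology = mor, passive = TRUE, v_init = -70)
  h <- electrical_handle(m, record_dt = 0)
  handle_set(h, "iinj_c1", 0.02)
  handle_step(h, 400)   # settle to steady state
  v <- m$pack$v_mV
  # steady state of the resistive network: solve the 2x2 system
  g1 <- 1e-4 * pi * 10 * 10 * 1e-8 * 1e6
  g2 <- 1e-4 * pi * 2 * 50 * 1e-8 * 1e6
  ga <- m$pack$gax_uS[2]
  A <- matrix(c(g1 + ga, -ga, -ga, g2 + ga), 2, 2, byrow = TRUE)
  b <- c(g1 * -70 + 0.02, g2 * -70)
  v_star <- solve(A, b)
  expect_lt(max(abs(v - v_star)) / abs(v_star[1] + 70), 0.01)
})

test_that("the full channel set settles to a stable resting state", {
  m <- build_electrical_model(morphology = msn_morphology(),
                              spines = data.frame(id = "s1",
                                                  segment = "dend1_1_1"))
  h <- electrical_handle(m, record_dt = 1)
  handle_step(h, 500)
  tr <- electrical_traces(m)
  dv <- diff(utils::tail(tr$V_soma, 20))
  expect_lt(max(abs(dv)), 0.01)                 # mV per ms
  expect_lt(tr$V_soma[nrow(tr)], -70)           # hyperpolarized rest
  expect_gt(tr$V_soma[nrow(tr)], -95)
  # gates stay in [0, 1] and shell calcium non-negative
  expect_true(all(m$pack$gate_m >= 0 & m$pack$gate_m <= 1))
  expect_true(all(m$pack$gate_h >= 0 & m$pack$gate_h <= 1))
  expect_true(all(m$pack$ca_mM >= 0))
})

test_that("spine channel placement honors the construction rules", {
  m <- build_electrical_model(morphology = msn_morphology(),
                              spines = data.frame(id = "s1",
                                                  segment = "dend1_1_1"))
  expect_true(isTRUE(audit_channel_placement(m)))
  # negative control: a placement without the inward rectifier in the neck
  pl <- default_channel_placement()
  pl$neck <- character(0)
  m2 <- build_electrical_model(morphology = msn_morphology(),
                               spines = data.frame(id = "s1",
                                                   segment = "dend1_1_1"),
                               placement = pl)
  bad <- audit_channel_placement(m2)
  expect_false(isTRUE(bad))
  expect_match(bad, "neck")
})

test_that("with all conductances removed the model is a passive cable", {
  m <- build_electrical_model(morphology = msn_morphology(), passive = TRUE,
                              v_init = -75)
  expect_identical(length(m$pack$ch_comp), 0L)
  h <- electrical_handle(m, record_dt = 0)
  handle_step(h, 100)
  expect_equal(m$pack$v_mV, rep(-75, nrow(m$comp_table)), tolerance = 1e-9)
})

test_that("gates and calcium stay bounded through a stimulated run", {
  m <- build_electrical_model(morphology = msn_morphology(),
                              spines = data.frame(id = "s1",
                                                  segment = "dend1_1_1"))
  h <- electrical_handle(m, record_dt = 1)
  handle_step(h, 300)
  for (t in seq(300, 800, by = 125)) {
    handle_step(h, t)
    handle_deliver(h, sync_event(t, "s1", "both"))
  }
  handle_step(h, 1200)
  expect_true(all(m$pack$gate_m >= 0 & m$pack$gate_m <= 1))
  expect_true(all(m$pack$gate_h >= 0 & m$pack$gate_h <= 1))
  expect_true(all(m$pack$ca_mM >= 0))
  tr <- electrical_traces(m)
  expect_true(all(abs(tr$V_head_s1) < 200))
})

test_that("halving the integration step changes the head peak by < 1%", {
  peak_with_dt <- function(dt) {
    m <- build_electrical_model(morphology = msn_morphology(),
                                spines = data.frame(id = "s1",
                                                    segment = "dend1_1_1"),
                                dt_elec = dt)
    h <- electrical_handle(m, record_dt = 0.5)
    handle_step(h, 200)
    handle_deliver(h, sync_event(200, "s1", "both"))
    handle_step(h, 300)
    tr <- electrical_traces(m)
    seg <- tr[tr$time_ms > 200, ]
    max(seg$V_head_s1) - tr$V_head_s1[which.min(abs(tr$time_ms - 200))]
  }
  p1 <- peak_with_dt(0.025)
  p2 <- peak_with_dt(0.0125)
  expect_lt(abs(p1 - p2) / abs(p2), 0.01)
})

test_that("the integrator aborts on numerical blow-up with a diagnostic", {
  m <- passive_one_comp(gl = 1e-6)
  h <- electrical_handle(m, record_dt = 0)
  handle_set(h, "iinj_c1", 50)   # enormous current into a tiny compartment
  expect_error(handle_step(h, 200), "blow-up")
})
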