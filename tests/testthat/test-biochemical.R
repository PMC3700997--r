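# The kinetic plasticity network: construction audits, conservation,
# equilibration, the calcium-level switch, and solver robustness.

test_that("Michaelis-Menten rates take their characteristic values", {
  expect_equal(mm_rate(2, 1e-6, 1e-7, 1e-6), 2 * 1e-7 / 2)
  expect_equal(mm_rate(2, 1e-6, 1e-7, 0), 0)
  expect_equal(mm_rate(2, 1e-6, 1e-7, 1e-3), 2e-7, tolerance = 0.01)
  expect_error(mm_rate(1, 0, 1, 1), "positive")
})

test_that("moiety totals at construction equal the configured totals", {
  net <- build_network()
  tot <- moiety_totals(net)
  conc <- default_initial_concentrations()
  expect_equal(tot[["calmodulin"]], conc[["CaM"]])
  expect_equal(tot[["camkii"]], conc[["CaMKII"]])
  expect_equal(tot[["darpp32"]], conc[["DARPP32"]])
  expect_equal(tot[["pp1"]], conc[["PP1"]])
  expect_equal(tot[["ampar"]], conc[["AMPAR"]])
})

test_that("the phospho-receptor pool is wired to exactly two branches", {
  net <- build_network()
  S <- net$stoich
  producers <- colnames(S)[S["AMPAR_P", ] > 0]
  consumers <- colnames(S)[S["AMPAR_P", ] < 0]
  expect_identical(producers, "AMPAR_phos")
  expect_identical(consumers, "AMPAR_dephos")
  rx <- net$reactions[[which(vapply(net$reactions, `[[`, "", "name") == "AMPAR_phos")]]
  expect_setequal(rx$pars$enzyme, c("CaMKII_CaM", "CaMKII_CaM_P"))
  rx2 <- net$reactions[[which(vapply(net$reactions, `[[`, "", "name") == "AMPAR_dephos")]]
  expect_identical(rx2$pars$enzyme, "PP1")
})

test_that("missing configuration keys are rejected by name", {
  p <- default_biochem_params()
  p$table7$pump_vmax <- NULL
  expect_error(build_network(p), "table7.pump_vmax")
  conc <- default_initial_concentrations()
  expect_error(build_network(concentrations = conc[names(conc) != "PP1"]),
               "table8.PP1")
})

test_that("the influx process integrates linearly on a bare calcium pool", {
  # all protein machinery and calcium housekeeping off: only the influx acts
  p <- default_biochem_params()
  p$table7$pump_vmax <- 0
  p$table7$ca_leak <- 0
  conc <- default_initial_concentrations()
  conc[c("CaM", "CaMKII", "CaN", "PKA", "PP1", "DARPP32", "AMPAR")] <- 0
  net <- build_network(p, conc)
  net <- set_calcium_influx(net, 1e-6)
  net <- step_biochemical(net, 1)
  expect_equal(net$species[["Ca"]], 1e-7 + 1e-6, tolerance = 1e-6)
  # a large negative flux floors free calcium at zero
  net <- set_calcium_influx(net, -1)
  net <- step_biochemical(net, 2)
  expect_gte(net$species[["Ca"]], 0)
  expect_lt(net$species[["Ca"]], 1e-9)
})

test_that("equilibrate converges, is idempotent, and recovers from perturbation", {
  net <- eq_network()
  expect_true(net$equilibrated)
  expect_gt(net$ampar_p_eq, 0)
  expect_lt(net$ampar_p_eq, moiety_totals(net)[["ampar"]])
  # already-equilibrated state returns without integrating further
  t_before <- net$time_s
  net2 <- equilibrate(net)
  expect_equal(net2$time_s, t_before)
  # doubling free calcium relaxes back to the same fixed point
  pert <- net
  pert$species[["Ca"]] <- 2 * pert$species[["Ca"]]
  pert <- equilibrate(pert)
  rel <- abs(pert$species - net$species) / pmax(net$species, 1e-12)
  expect_lt(max(rel[net$species > 1e-12]), 1e-3)
})

test_that("equilibration from distinct perturbed starts is consistent", {
  net <- eq_network()
  a <- net; a$species[["Ca"]] <- 3 * a$species[["Ca"]]
  b <- net
  b$species[["CaMT0"]] <- b$species[["CaMT0"]] - 1e-6
  b$species[["CaMT1"]] <- b$species[["CaMT1"]] + 1e-6
  a <- equilibrate(a); b <- equilibrate(b)
  rel <- abs(a$species - b$species) / pmax(b$species, 1e-12)
  expect_lt(max(rel[b$species > 1e-12]), 1e-3)
})

test_that("an equilibrated network stays put for 100 s", {
  net <- eq_network()
  net2 <- step_biochemical(net, net$time_s + 100)
  rel <- abs(net2$species - net$species) / pmax(net$species, 1e-12)
  expect_lt(max(rel[net$species > 1e-12]), 1e-3)
})

test_that("conserved moieties survive a strong stimulation protocol", {
  net <- eq_network()
  tot0 <- moiety_totals(net)
  n <- set_calcium_influx(net, 5e-4)
  n <- step_biochemical(n, net$time_s + 2)
  n <- set_calcium_influx(n, 0)
  n <- step_biochemical(n, n$time_s + 18)
  expect_equal(moiety_totals(n), tot0, tolerance = 1e-6)
})

test_that("a brief weak influx leaves the phospho-receptor pool unchanged", {
  net <- eq_network()
  n <- set_calcium_influx(net, 2e-6)
  n <- step_biochemical(n, net$time_s + 0.05)
  n <- set_calcium_influx(n, 0)
  n <- step_biochemical(n, n$time_s + 60)
  change <- abs(n$species[["AMPAR_P"]] - net$ampar_p_eq)
  expect_lt(change / moiety_totals(net)[["ampar"]], 0.01)
})

test_that("sustained strong influx drives phosphorylation above equilibrium", {
  net <- eq_network()
  n <- set_calcium_influx(net, 1e-5)
  n <- step_biochemical(n, net$time_s + 30)
  expect_gt(n$species[["AMPAR_P"]], 1.5 * net$ampar_p_eq)
})

test_that("the calcium level selects the kinase or phosphatase branch", {
  net <- eq_network()
  net_flux <- function(n) {
    y <- n$species; p <- n$params$table7
    mm_rate(p$camkii_ampar_kcat, p$camkii_ampar_km,
            y[["CaMKII_CaM"]] + y[["CaMKII_CaM_P"]], y[["AMPAR"]]) -
      mm_rate(p$pp1_ampar_kcat, p$pp1_ampar_km, y[["PP1"]], y[["AMPAR_P"]])
  }
  # sustained low influx: calcineurin releases PP1, dephosphorylation wins
  low <- set_calcium_influx(net, 2e-6)
  low <- step_biochemical(low, net$time_s + 600)
  expect_gt(low$species[["PP1"]], 3 * net$species[["PP1"]])
  expect_lt(net_flux(low), 0)
  # and the phospho-receptor pool falls below its equilibrium
  low2 <- step_biochemical(low, low$time_s + 1800)
  expect_lt(low2$species[["AMPAR_P"]], 0.9 * net$ampar_p_eq)

  # sustained high influx: the CaMKII branch dominates
  high <- set_calcium_influx(net, 1e-5)
  high <- step_biochemical(high, net$time_s + 30)
  expect_gt(net_flux(high), 0)
  expect_gt(high$species[["AMPAR_P"]], net$ampar_p_eq)
})

test_that("halving solver tolerances barely moves the trajectory", {
  run_with <- function(rtol) {
    net <- build_network(rtol = rtol)
    net <- equilibrate(net)
    net$time_s <- 0
    n <- set_calcium_influx(net, 5e-6)
    n <- step_biochemical(n, 10)
    n$species[["AMPAR_P"]]
  }
  a <- run_with(1e-8)
  b <- run_with(5e-9)
  expect_lt(abs(a - b) / b, 0.005)
})

test_that("the concerted-switching variant builds and conserves", {
  net <- build_network(cam_switching = "endpoints")
  expect_lt(length(net$reactions), length(build_network()$reactions))
  tot0 <- moiety_totals(net)
  net <- step_biochemical(net, 5)
  expect_equal(moiety_totals(net), tot0, tolerance = 1e-6)
})

test_that("time runs forward only and handles convert between clocks", {
  net <- eq_network()
  expect_error(step_biochemical(net, net$time_s - 1), "backwards")
  h <- biochemical_handle(net, volume_fl = 1.0843, time = 0)
  handle_step(h, 100)                     # ms on the handle clock
  expect_equal(h$network$time_s, 0.1)     # seconds internally
  expect_equal(handle_get(h, "AMPAR_P_count"),
               conc_to_count(handle_get(h, "AMPAR_P"), 1.0843))
  handle_set(h, "k_flux", 2e-4)
  expect_equal(handle_get(h, "k_flux"), 2e-4)
  expect_error(handle_set(h, "AMPAR_P", 1), "read-only")
})

test_that("parameter configurations round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_biochem_config(default_biochem_params(),
                       default_initial_concentrations(), path)
  back <- read_biochem_config(path)
  expect_equal(back$params$table6$koff_t,
               default_biochem_params()$table6$koff_t)
  expect_equal(back$concentrations, default_initial_concentrations())
  net <- build_network(back$params, back$concentrations)
  expect_s3_class(net, "reaction_network")
})
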