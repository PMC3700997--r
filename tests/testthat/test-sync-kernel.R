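# Event-driven meta-simulator: queue handling, four-phase cycle ordering,
# fixed-step baseline, on-demand variant, toy-simulator oracles.

test_that("toy simulators follow their closed forms", {
  h <- make_toy_simulator("exponential_decay", list(lambda = 1e-3, x0 = 1))
  handle_step(h, 1000)
  expect_equal(handle_get(h, "x"), exp(-1), tolerance = 1e-12)

  h2 <- make_toy_simulator("constant", list(c = 5))
  handle_step(h2, 1234.5)
  expect_identical(handle_get(h2, "x"), 5)

  h3 <- make_toy_simulator("ramp", list(slope = 2))
  handle_step(h3, 3)
  expect_equal(handle_get(h3, "x"), 6)

  expect_error(make_toy_simulator("exponential_decay", list(x0 = 1)), "lambda")
  expect_error(handle_step(h, 500), "backwards")
  # get after set returns the written value; step to current time is a no-op
  handle_set(h, "x", 0.25)
  expect_identical(handle_get(h, "x"), 0.25)
  handle_step(h, handle_time(h))
  expect_identical(handle_get(h, "x"), 0.25)
})

test_that("run_event_driven with no events advances both simulators to t_stop", {
  p <- toy_pair()
  log <- run_event_driven(p$fast, p$slow, list(), sync_schedule(t_stop = 100))
  expect_equal(handle_time(p$fast), 100)
  expect_equal(handle_time(p$slow), 100)
  expect_identical(log$n_exchange_cycles, 0L)
  expect_identical(nrow(log$delivered), 0L)
})

test_that("one event forces a synchronization window of window/delta cycles", {
  p <- toy_pair()
  log <- run_event_driven(p$fast, p$slow, list(sync_event(1000)),
                          sync_schedule(t_stop = 2000, delta_exchange = 1,
                                        window_length = 10))
  expect_identical(log$n_exchange_cycles, 10L)
  expect_equal(log$delivered$time, 1000)
  expect_equal(log$delivered$delivery_time, 1000)
  expect_equal(log$windows$start, 1000)
  expect_equal(log$windows$end, 1010)
  expect_equal(handle_time(p$fast), 2000)
})

test_that("event queues are validated", {
  p <- toy_pair()
  sched <- sync_schedule(t_stop = 100)
  expect_error(run_event_driven(p$fast, p$slow,
                                list(sync_event(50), sync_event(10)), sched),
               "sorted")
  expect_error(run_event_driven(p$fast, p$slow, list(sync_event(150)), sched),
               "beyond t_stop")
  expect_error(sync_event(-1), "non-negative")
  expect_error(sync_schedule(t_stop = 100, delta_exchange = 20,
                             window_length = 10), "delta_exchange")
})

test_that("the four-phase cycle reads the slow simulator first", {
  fast <- make_toy_simulator("constant", list(c = 1))
  slow <- make_toy_simulator("constant", list(c = 5))
  ex <- coupling_spec(list(coupling_map(1L, "x", "x"),
                           coupling_map(3L, "x", "x")))
  le <- spinesync:::new_sync_log_env("test")
  synchronize_cycle(fast, slow, 2, ex, .log = le)
  log <- spinesync:::finalize_sync_log(le, 2)
  # phase 1 before phase 3; fast receives the slow value before advancing,
  # then the slow side receives what fast holds afterwards
  expect_identical(log$exchanges$phase, c(1L, 3L))
  expect_equal(log$exchanges$raw, c(5, 5))
  expect_equal(handle_get(fast, "x"), 5)
  expect_equal(handle_get(slow, "x"), 5)
  expect_equal(handle_time(fast), 2)
  expect_equal(handle_time(slow), 2)
})

test_that("cycles reject misaligned start times", {
  fast <- make_toy_simulator("constant", list(c = 1))
  slow <- make_toy_simulator("constant", list(c = 2))
  handle_step(fast, 5)
  expect_error(synchronize_cycle(fast, slow, 1), "time-consistency")
})

test_that("two 1 ms cycles equal one 2 ms window at 1 ms cadence", {
  mk <- function() list(f = make_toy_simulator("exponential_decay",
                                               list(lambda = 2e-3, x0 = 1)),
                        s = make_toy_simulator("ramp", list(slope = 0.1)))
  ex <- gain_coupling(0.02)
  a <- mk()
  le <- spinesync:::new_sync_log_env("manual")
  synchronize_cycle(a$f, a$s, 1, ex, .log = le)
  synchronize_cycle(a$f, a$s, 1, ex, .log = le)
  manual <- spinesync:::finalize_sync_log(le, 2)

  b <- mk()
  win <- run_event_driven(b$f, b$s, list(sync_event(0)),
                          sync_schedule(t_stop = 2, delta_exchange = 1,
                                        window_length = 2),
                          gain_coupling(0.02))
  expect_equal(win$exchanges, manual$exchanges)
  expect_equal(handle_get(a$f, "x"), handle_get(b$f, "x"))
  expect_equal(handle_get(a$s, "x"), handle_get(b$s, "x"))
})

test_that("times stay exactly aligned through arbitrary cycle sequences", {
  p <- toy_pair()
  set.seed(7)
  deltas <- sample(c(0.25, 0.5, 1, 2), 40, replace = TRUE)
  for (d in deltas) {
    synchronize_cycle(p$fast, p$slow, d, gain_coupling(0.01))
    expect_identical(handle_time(p$fast), handle_time(p$slow))
  }
})

test_that("fixed-step synchronization misses exactly the off-grid events", {
  mk <- function() list(make_toy_simulator("constant", list(c = 1)),
                        make_toy_simulator("constant", list(c = 2)))
  # all on grid
  p <- mk()
  log <- run_fixed_step(p[[1]], p[[2]],
                        list(sync_event(100), sync_event(200)), 100, 300)
  expect_identical(nrow(log$missed), 0L)
  expect_identical(nrow(log$delivered), 2L)

  # the 240-event, 50 ms spacing fixture
  p <- mk()
  log100 <- run_fixed_step(p[[1]], p[[2]], table1_events(), 100, 12000)
  expect_identical(nrow(log100$missed), 120L)
  expect_equal(summary(log100)$pct_missed, 50)
  p <- mk()
  log10 <- run_fixed_step(p[[1]], p[[2]], table1_events(), 10, 12000)
  expect_identical(nrow(log10$missed), 0L)

  # event-driven never misses, any spacing
  p <- mk()
  loge <- run_event_driven(p[[1]], p[[2]], table1_events(),
                           sync_schedule(t_stop = 12000))
  expect_identical(nrow(loge$missed), 0L)
  expect_identical(nrow(loge$delivered), 240L)
})

test_that("grid-miss law holds for arbitrary event times", {
  set.seed(11)
  for (rep in 1:5) {
    dt <- sample(c(5, 10, 25), 1)
    times <- sort(round(runif(30, 1, 990), 1))
    times <- unique(times)
    on_grid <- abs(times / dt - round(times / dt)) < 1e-9
    p <- list(make_toy_simulator("constant", list(c = 0)),
              make_toy_simulator("constant", list(c = 0)))
    log <- run_fixed_step(p[[1]], p[[2]], lapply(times, sync_event), dt, 1000)
    expect_identical(nrow(log$delivered), sum(on_grid))
    expect_identical(nrow(log$missed), sum(!on_grid))
    expect_setequal(log$missed$time, times[!on_grid])
  }
})

test_that("exchange-cycle count scales with events, not with t_stop", {
  count_cycles <- function(n_events, t_stop) {
    evs <- lapply(seq(100, by = 100, length.out = n_events), sync_event)
    p <- toy_pair()
    run_event_driven(p$fast, p$slow, evs,
                     sync_schedule(t_stop, 1, 10))$n_exchange_cycles
  }
  expect_identical(count_cycles(5, 1000), 50L)
  expect_identical(count_cycles(5, 50000), 50L)   # independent of t_stop
  expect_identical(count_cycles(8, 1000), 80L)    # proportional to events
})

test_that("events inside an open window extend it and are delivered on time", {
  p <- toy_pair()
  # second event lands 4 ms into the first 10 ms window
  log <- run_event_driven(p$fast, p$slow,
                          list(sync_event(100), sync_event(104)),
                          sync_schedule(t_stop = 200))
  expect_equal(log$delivered$delivery_time, c(100, 104))
  expect_identical(nrow(log$windows), 1L)          # one merged window
  expect_equal(log$windows$end, 114)               # extended, not nested
  expect_identical(log$n_exchange_cycles, 14L)
})

test_that("on-demand synchronization reproduces the a-priori event run", {
  f1 <- make_toy_simulator("exponential_decay",
                           list(lambda = 2e-3, x0 = 1, emit_at = 500))
  s1 <- make_toy_simulator("ramp", list(slope = 0.01))
  lod <- run_on_demand(f1, s1, sync_schedule(t_stop = 1000),
                       gain_coupling(0.01), tstep = 1)
  f2 <- make_toy_simulator("exponential_decay", list(lambda = 2e-3, x0 = 1))
  s2 <- make_toy_simulator("ramp", list(slope = 0.01))
  led <- run_event_driven(f2, s2, list(sync_event(500)),
                          sync_schedule(t_stop = 1000), gain_coupling(0.01))
  expect_equal(lod$exchanges, led$exchanges)
  expect_equal(lod$delivered$delivery_time, led$delivered$delivery_time)
  expect_equal(handle_get(f1, "x"), handle_get(f2, "x"), tolerance = 1e-12)
  expect_equal(handle_get(s1, "x"), handle_get(s2, "x"), tolerance = 1e-12)
})

test_that("on-demand without events equals two independent runs", {
  f <- make_toy_simulator("exponential_decay",
                          list(lambda = 1e-3, x0 = 1, emit_at = numeric(0)))
  s <- make_toy_simulator("ramp", list(slope = 0.5))
  log <- run_on_demand(f, s, sync_schedule(t_stop = 700), gain_coupling(0.1))
  expect_identical(log$n_exchange_cycles, 0L)
  expect_equal(handle_get(f, "x"), exp(-0.7), tolerance = 1e-12)
  expect_equal(handle_get(s, "x"), 350)
})

test_that("on-demand rejects an event-emitting slow simulator and truncates at t_stop", {
  f <- make_toy_simulator("constant", list(c = 1))
  s <- make_toy_simulator("constant", list(c = 2, emit_at = 100))
  expect_error(run_on_demand(f, s, sync_schedule(t_stop = 500)), "unsupported")

  # event in the final step: window truncated at t_stop
  f2 <- make_toy_simulator("constant", list(c = 1, emit_at = 497))
  s2 <- make_toy_simulator("constant", list(c = 2))
  log <- run_on_demand(f2, s2, sync_schedule(t_stop = 500), tstep = 1)
  expect_equal(log$t_end, 500)
  expect_lte(max(log$windows$end), 500)
  expect_identical(log$n_exchange_cycles, 3L)
})

test_that("event-driven equals a dense fixed-step run when windows tile the run", {
  # one event at t = 0 with window_length = t_stop makes the event-driven
  # strategy exchange on the same 1 ms grid as the dense fixed-step baseline
  a <- toy_pair()
  run_event_driven(a$fast, a$slow, list(sync_event(0)),
                   sync_schedule(t_stop = 100, delta_exchange = 1,
                                 window_length = 100),
                   gain_coupling(0.05))
  b <- toy_pair()
  run_fixed_step(b$fast, b$slow, list(sync_event(0)), 1, 100,
                 gain_coupling(0.05))
  expect_equal(handle_get(a$fast, "x"), handle_get(b$fast, "x"),
               tolerance = 1e-6)
  expect_equal(handle_get(a$slow, "x"), handle_get(b$slow, "x"),
               tolerance = 1e-6)

  # decoupled simulators match their closed forms exactly
  c1 <- toy_pair()
  run_event_driven(c1$fast, c1$slow, list(sync_event(0)),
                   sync_schedule(t_stop = 100, window_length = 100),
                   gain_coupling(0))
  expect_equal(handle_get(c1$fast, "x"), exp(-0.1), tolerance = 1e-6)
  expect_equal(handle_get(c1$slow, "x"), 2 * exp(-0.05), tolerance = 1e-6)
})

test_that("sync logs serialize to CSV", {
  p <- toy_pair()
  log <- run_event_driven(p$fast, p$slow, list(sync_event(10)),
                          sync_schedule(t_stop = 50), gain_coupling(0.01))
  dir <- withr::local_tempdir()
  write_sync_log(log, dir)
  expect_true(all(file.exists(file.path(dir, c("events.csv", "missed.csv",
                                               "exchanges.csv", "timings.csv")))))
  ev <- read.csv(file.path(dir, "events.csv"))
  expect_equal(ev$time, 10)
})
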