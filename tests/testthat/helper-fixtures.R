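# Shared fixtures, memoized so expensive co-simulations run once per suite.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# equilibrated default biochemical network (clock rebased to 0)
eq_network <- function() {
  memo("eq_network", function() {
    net <- equilibrate(build_network())
    net$time_s <- 0
    net
  })
}

# the desk-scale double-train protocol: one spine, 8 Hz trains of 20 inputs
# at 2000 and 15000 ms
double_train_config <- function(biochem_enabled = TRUE) {
  experiment_config(
    trains = list(build_train(8, 20, start = 2000, targets = "s1"),
                  build_train(8, 20, start = 15000, targets = "s1")),
    t_stop = 18000,
    biochem_enabled = biochem_enabled)
}

double_train_archive <- function(biochem_enabled = TRUE) {
  key <- paste0("double_train_", biochem_enabled)
  memo(key, function() run_experiment(double_train_config(biochem_enabled)))
}

# single-pulse protocol with a long forced window and 1 ms biochemical
# recording, for calcium shape-following checks
pulse_archive <- function() {
  memo("pulse_archive", function() {
    cfg <- experiment_config(
      trains = list(build_train(8, 1, start = 500, targets = "s1")),
      t_stop = 1200, window_length = 300, record_dt_biochem = 1)
    run_experiment(cfg)
  })
}

# 240 events spaced 50 ms apart starting at 50 ms (the missed-event fixture)
table1_events <- function(n = 240, spacing = 50) {
  lapply(seq(spacing, by = spacing, length.out = n), sync_event)
}

toy_pair <- function() {
  list(fast = make_toy_simulator("exponential_decay",
                                 list(lambda = 1e-3, x0 = 1)),
       slow = make_toy_simulator("exponential_decay",
                                 list(lambda = 5e-4, x0 = 2)))
}
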