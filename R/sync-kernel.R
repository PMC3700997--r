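#' Stimulation event
#'
#' A timed stimulus aimed at the synapse of one spine.  Queues of events
#' handed to the synchronization strategies must be sorted by time.
#'
#' @param time event time (ms), non-negative.
#' @param target_id spine identifier (integer-like or character).
#' @param synapse_kind which co-localized receptor population receives the
#'   stimulus: `"AMPA"`, `"NMDA"` or `"both"`.
#' @return list of class `"sync_event"`.
#' @export
sync_event <- function(time, target_id = 1L, synapse_kind = c("both", "AMPA", "NMDA")) {
  synapse_kind <- match.arg(synapse_kind)
  if (!is.numeric(time) || length(time) != 1 || is.na(time) || time < 0) {
    stop("event time must be a single non-negative number (ms)")
  }
  structure(list(time = as.numeric(time), target_id = target_id,
                 synapse_kind = synapse_kind),
            class = "sync_event")
}

#' @export
print.sync_event <- function(x, ...) {
  cat(sprintf("<event t=%g ms, target=%s, %s>\n", x$time, x$target_id, x$synapse_kind))
  invisible(x)
}

#' Synchronization schedule
#'
#' Timing parameters of the event-driven strategy: after every event the two
#' simulators are forced to synchronize for `window_length` ms, exchanging
#' variables every `delta_exchange` ms; outside these windows they run
#' independently until the next event or `t_stop`.
#'
#' @param t_stop end of simulation (ms), positive.
#' @param delta_exchange exchange cadence inside a window (ms, default 1).
#' @param window_length duration of forced synchronization after an event
#'   (ms, default 10).
#' @return list of class `"sync_schedule"`.
#' @export
sync_schedule <- function(t_stop, delta_exchange = 1, window_length = 10) {
  if (!(t_stop > 0)) stop("t_stop must be positive")
  if (!(delta_exchange > 0 && delta_exchange <= window_length)) {
    stop("need 0 < delta_exchange <= window_length")
  }
  structure(list(delta_exchange = delta_exchange,
                 window_length = window_length,
                 t_stop = t_stop),
            class = "sync_schedule")
}

# --- internal log accumulator -------------------------------------------------

new_sync_log_env <- function(strategy) {
  e <- new.env(parent = emptyenv())
  e$strategy <- strategy
  e$delivered <- list()
  e$missed <- list()
  e$exchanges <- list()
  e$windows <- list()
  e$n_cycles <- 0L
  e
}

log_delivery <- function(le, event, delivery_time) {
  le$delivered[[length(le$delivered) + 1L]] <-
    list(time = event$time, target_id = event$target_id,
         synapse_kind = event$synapse_kind, delivery_time = delivery_time)
}

log_miss <- function(le, event) {
  le$missed[[length(le$missed) + 1L]] <-
    list(time = event$time, target_id = event$target_id,
         synapse_kind = event$synapse_kind)
}

log_exchange <- function(le, time, phase, var_from, var_to, raw, transformed) {
  le$exchanges[[length(le$exchanges) + 1L]] <-
    list(time = time, phase = phase, var_from = var_from, var_to = var_to,
         raw = raw, transformed = transformed)
}

finalize_sync_log <- function(le, t_end) {
  bind <- function(rows, cols) {
    if (length(rows) == 0) {
      as.data.frame(cols, stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    }
  }
  structure(list(
    strategy = le$strategy,
    delivered = bind(le$delivered, list(time = numeric(0), target_id = character(0),
                                        synapse_kind = character(0), delivery_time = numeric(0))),
    missed = bind(le$missed, list(time = numeric(0), target_id = character(0),
                                  synapse_kind = character(0))),
    exchanges = bind(le$exchanges, list(time = numeric(0), phase = integer(0),
                                        var_from = character(0), var_to = character(0),
                                        raw = numeric(0), transformed = numeric(0))),
    windows = bind(le$windows, list(start = numeric(0), end = numeric(0),
                                    n_cycles = integer(0), wall_s = numeric(0))),
    n_exchange_cycles = le$n_cycles,
    t_end = t_end
  ), class = "sync_log")
}

#' @export
print.sync_log <- function(x, ...) {
  cat(sprintf("<sync_log: %s strategy>\n", x$strategy))
  cat(sprintf("  events delivered: %d   missed: %d\n",
              nrow(x$delivered), nrow(x$missed)))
  cat(sprintf("  exchange cycles:  %d\n", x$n_exchange_cycles))
  cat(sprintf("  simulated to:     %g ms\n", x$t_end))
  invisible(x)
}

#' @export
summary.sync_log <- function(object, ...) {
  n_tot <- nrow(object$delivered) + nrow(object$missed)
  out <- data.frame(
    strategy = object$strategy,
    events_total = n_tot,
    events_delivered = nrow(object$delivered),
    events_missed = nrow(object$missed),
    pct_missed = if (n_tot > 0) 100 * nrow(object$missed) / n_tot else 0,
    exchange_cycles = object$n_exchange_cycles,
    t_end = object$t_end
  )
  class(out) <- c("summary.sync_log", "data.frame")
  out
}

#' Write a synchronization log to a directory of CSV files
#'
#' Layout mirrors the hierarchical store used for full experiment archives:
#' `events.csv` (delivered), `missed.csv`, `exchanges.csv`, `timings.csv`.
#'
#' @param log a `sync_log`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sync_log <- function(log, dir) {
  stopifnot(inherits(log, "sync_log"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(log$delivered, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(log$missed, file.path(dir, "missed.csv"), row.names = FALSE)
  utils::write.csv(log$exchanges, file.path(dir, "exchanges.csv"), row.names = FALSE)
  utils::write.csv(log$windows, file.path(dir, "timings.csv"), row.names = FALSE)
  invisible(dir)
}

# --- validation ---------------------------------------------------------------

validate_events <- function(events, t_stop) {
  if (length(events) == 0) return(invisible(NULL))
  times <- vapply(events, function(e) e$time, numeric(1))
  if (is.unsorted(times)) stop("events must be sorted non-decreasing by time")
  late <- times > t_stop + 1e-9
  if (any(late)) {
    stop(sprintf("event at %g ms lies beyond t_stop = %g ms", times[late][1], t_stop))
  }
  invisible(NULL)
}

check_aligned <- function(fast, slow) {
  if (abs(fast$time - slow$time) > 1e-9) {
    stop(sprintf("time-consistency violation: fast at %g ms, slow at %g ms",
                 fast$time, slow$time))
  }
}

# --- the four-phase cycle -----------------------------------------------------

#' One four-phase synchronization cycle
#'
#' The fixed ordering implements the model hierarchy: the simulator with the
#' slower timescale is read first, so the fast simulator holds up-to-date
#' slow-side values before it advances.
#'
#' 1. read mapped variables from `slow`, transform, set into `fast`;
#' 2. advance `fast` by `delta`;
#' 3. read mapped variables from `fast`, transform, set into `slow`;
#' 4. advance `slow` by the same `delta`.
#'
#' Both handles must start at the same time and end `delta` later.
#'
#' @param fast,slow [sim_handle()]s at equal current times.
#' @param delta cycle length (ms).
#' @param exchange a [coupling_spec()] describing the variable mappings.
#' @param .log internal log accumulator (used by the strategy drivers).
#' @return the common end time, invisibly.
#' @export
synchronize_cycle <- function(fast, slow, delta, exchange = coupling_none(),
                              .log = NULL) {
  check_aligned(fast, slow)
  t0 <- fast$time
  if (is.environment(exchange$runtime)) {
    exchange$runtime$t_start <- t0
    exchange$runtime$delta <- delta
  }
  apply_phase <- function(phase, from, to) {
    for (m in exchange$mappings) {
      if (m$phase != phase) next
      raw <- handle_get(from, m$var_from)
      cur <- handle_get(to, m$var_to)
      val <- if (is.null(m$transform)) raw else m$transform(raw, cur)
      handle_set(to, m$var_to, val)
      if (!is.null(.log)) {
        log_exchange(.log, t0, phase, m$var_from, m$var_to, raw, val)
      }
    }
  }
  apply_phase(1L, from = slow, to = fast)
  handle_step(fast, t0 + delta)
  apply_phase(3L, from = fast, to = slow)
  handle_step(slow, t0 + delta)
  if (!is.null(.log)) .log$n_cycles <- .log$n_cycles + 1L
  invisible(t0 + delta)
}

# run the forced-synchronization window that follows event delivery; handles
# events that land inside a still-open window by delivering them at their
# exact times and extending the window (single-timeline semantics).
# Returns the index of the next unprocessed event.
run_sync_window <- function(fast, slow, events, i_next, window_end,
                            schedule, exchange, le) {
  tol <- 1e-9
  t <- fast$time
  window_end <- min(window_end, schedule$t_stop)
  t_wall <- proc.time()[["elapsed"]]
  w_start <- t
  n0 <- le$n_cycles
  while (t < window_end - tol) {
    te <- if (i_next <= length(events)) events[[i_next]]$time else Inf
    step_end <- min(t + schedule$delta_exchange, window_end)
    if (te < step_end - tol && te > t + tol) step_end <- te
    synchronize_cycle(fast, slow, step_end - t, exchange, .log = le)
    t <- step_end
    while (i_next <= length(events) && abs(events[[i_next]]$time - t) <= tol) {
      ev <- events[[i_next]]
      if (!is.null(exchange$before_deliver)) exchange$before_deliver(fast, slow, ev)
      handle_deliver(fast, ev)
      log_delivery(le, ev, t)
      window_end <- min(max(window_end, t + schedule$window_length), schedule$t_stop)
      i_next <- i_next + 1L
    }
  }
  if (!is.null(exchange$on_window_end)) exchange$on_window_end(fast, slow)
  le$windows[[length(le$windows) + 1L]] <-
    list(start = w_start, end = t, n_cycles = le$n_cycles - n0,
         wall_s = proc.time()[["elapsed"]] - t_wall)
  i_next
}

#' Event-driven co-simulation
#'
#' The meta-simulator at the heart of the package.  Events are popped from a
#' chronologically sorted queue; before each event both simulators are
#' advanced independently to the event time, the event is delivered at its
#' exact time, and the two simulators are then forced through four-phase
#' synchronization cycles every `delta_exchange` ms for `window_length` ms.
#' When the queue is empty both simulators run independently to `t_stop`.
#' Every queued event is delivered exactly once at its exact time; events
#' falling inside a still-open window extend the window.
#'
#' @param fast,slow [sim_handle()]s at the same current time; `fast` receives
#'   the events.
#' @param events list of [sync_event()]s sorted by time, none beyond
#'   `t_stop`.
#' @param schedule a [sync_schedule()].
#' @param exchange a [coupling_spec()] (default: no exchange).
#' @return a `sync_log`.
#' @examples
#' fast <- make_toy_simulator("exponential_decay", list(lambda = 1e-3, x0 = 1))
#' slow <- make_toy_simulator("constant", list(c = 5))
#' log <- run_event_driven(fast, slow, list(sync_event(1000)),
#'                         sync_schedule(t_stop = 2000))
#' summary(log)
#' @export
run_event_driven <- function(fast, slow, events, schedule,
                             exchange = coupling_none()) {
  stopifnot(inherits(schedule, "sync_schedule"))
  check_aligned(fast, slow)
  validate_events(events, schedule$t_stop)
  le <- new_sync_log_env("event")
  tol <- 1e-9
  i <- 1L
  while (i <= length(events)) {
    ev <- events[[i]]
    if (ev$time > fast$time + tol) {
      handle_step(fast, ev$time)
      handle_step(slow, ev$time)
    }
    if (!is.null(exchange$before_deliver)) exchange$before_deliver(fast, slow, ev)
    handle_deliver(fast, ev)
    log_delivery(le, ev, fast$time)
    if (!is.null(exchange$on_window_start)) exchange$on_window_start(fast, slow)
    i <- run_sync_window(fast, slow, events, i + 1L,
                         ev$time + schedule$window_length,
                         schedule, exchange, le)
  }
  if (fast$time < schedule$t_stop - tol) {
    handle_step(fast, schedule$t_stop)
    handle_step(slow, schedule$t_stop)
  }
  finalize_sync_log(le, fast$time)
}

#' Fixed-step (while-loop) synchronization baseline
#'
#' Synchronizes the two simulators at every multiple of `dt_sync`,
#' regardless of the event times.  An event is delivered only if its time
#' coincides with a synchronization point (absolute tolerance `1e-9` ms);
#' events falling between grid points are recorded as missed.  This is the
#' classical baseline the event-driven strategy is compared against: with a
#' coarse grid half the off-grid events are lost, with a fine grid none are,
#' at the price of many more synchronizations.
#'
#' @param fast,slow [sim_handle()]s at the same current time.
#' @param events sorted list of [sync_event()]s.
#' @param dt_sync synchronization step (ms), positive.
#' @param t_stop end of simulation (ms).
#' @param exchange a [coupling_spec()] (default: no exchange).
#' @return a `sync_log` with both delivered and missed events.
#' @export
run_fixed_step <- function(fast, slow, events, dt_sync, t_stop,
                           exchange = coupling_none()) {
  if (!(dt_sync > 0)) stop("dt_sync must be positive")
  check_aligned(fast, slow)
  validate_events(events, t_stop)
  le <- new_sync_log_env("fixed")
  tol <- 1e-9
  i <- 1L
  t <- fast$time
  repeat {
    # deliver events coinciding with the current grid point; miss the ones
    # strictly inside the previous interval
    while (i <= length(events) && events[[i]]$time <= t + tol) {
      ev <- events[[i]]
      if (abs(ev$time - t) <= tol) {
        if (!is.null(exchange$before_deliver)) exchange$before_deliver(fast, slow, ev)
        handle_deliver(fast, ev)
        log_delivery(le, ev, t)
      } else {
        log_miss(le, ev)
      }
      i <- i + 1L
    }
    if (t >= t_stop - tol) break
    delta <- min(dt_sync, t_stop - t)
    synchronize_cycle(fast, slow, delta, exchange, .log = le)
    t <- fast$time
  }
  # anything left in the queue was passed without landing on the grid
  while (i <= length(events)) {
    log_miss(le, events[[i]])
    i <- i + 1L
  }
  finalize_sync_log(le, fast$time)
}

#' On-demand synchronization for events unknown before the run
#'
#' Variant of the event-driven strategy for simulations in which events
#' emerge at run time.  The fast simulator is always advanced first, by
#' `tstep`, then the slow simulator; when the fast simulator reports an
#' event from its last step, the event is delivered and a forced
#' synchronization window is run exactly as in [run_event_driven()].  Only
#' the fast simulator may report events.
#'
#' @param fast a [sim_handle()] able to report events (see `emitted` in
#'   [sim_handle()]); `slow` must not report events.
#' @param slow a [sim_handle()].
#' @param schedule a [sync_schedule()].
#' @param exchange a [coupling_spec()].
#' @param tstep scan step for the free-running phase (ms); defaults to the
#'   schedule's exchange cadence.
#' @return a `sync_log`.
#' @export
run_on_demand <- function(fast, slow, schedule, exchange = coupling_none(),
                          tstep = schedule$delta_exchange) {
  stopifnot(inherits(schedule, "sync_schedule"))
  check_aligned(fast, slow)
  if (handle_emits(slow)) {
    stop("slow simulator reporting events is unsupported in on-demand mode")
  }
  le <- new_sync_log_env("on-demand")
  tol <- 1e-9
  while (fast$time < schedule$t_stop - tol) {
    step_end <- min(fast$time + tstep, schedule$t_stop)
    handle_step(fast, step_end)
    evs <- handle_emitted(fast)
    handle_step(slow, step_end)
    for (ev in evs) {
      if (!is.null(exchange$before_deliver)) exchange$before_deliver(fast, slow, ev)
      handle_deliver(fast, ev)
      log_delivery(le, ev, fast$time)
      if (!is.null(exchange$on_window_start)) exchange$on_window_start(fast, slow)
      run_sync_window(fast, slow, list(), 1L,
                      fast$time + schedule$window_length,
                      schedule, exchange, le)
    }
  }
  finalize_sync_log(le, fast$time)
}
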